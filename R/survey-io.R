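#' @include AllClasses.R
NULL

#' Genotype-table dialect configuration
#'
#' Explicit dialect for the two-columns-per-locus genotype tables used in
#' field reports: delimiter, the token marking a missing call, and the token
#' separating candidate alleles of an ambiguous cell. No format sniffing is
#' performed.
#'
#' @param delim field delimiter.
#' @param missing token for a missing call (empty cells are also missing).
#' @param slash token separating candidate alleles inside one cell.
#' @return A named list used by [readGenotypeTable()] and
#'   [writeGenotypeTable()].
#' @export
genotypeDialect <- function(delim = ",", missing = "-", slash = "/") {
  list(delim = delim, missing = missing, slash = slash)
}

.parse_cell <- function(c1, c2, locus, sample_id, dialect) {
  toks <- function(x) {
    x <- trimws(x)
    if (is.na(x) || x == "" || x == dialect$missing) return(NULL)
    parts <- trimws(strsplit(x, dialect$slash, fixed = TRUE)[[1]])
    if (!length(parts) || !all(grepl("^[0-9]+$", parts)))
      stop(sprintf("malformed allele token '%s' at sample %s, locus %s",
                   x, sample_id, locus), call. = FALSE)
    as.integer(parts)
  }
  t1 <- toks(c1); t2 <- toks(c2)
  if (is.null(t1) && is.null(t2))
    return(LocusGenotype(locus, status = "MISSING"))
  # a slash in either column, or a one-sided cell, leaves the genotype
  # unconfirmed: keep the full candidate set, never resolve silently
  if (length(t1) > 1L || length(t2) > 1L || is.null(t1) || is.null(t2))
    return(LocusGenotype(locus, status = "AMBIGUOUS",
                         candidates = c(t1, t2)))
  LocusGenotype(locus, alleles = c(t1, t2))
}

#' Read a two-columns-per-locus genotype table
#'
#' Parses a CSV/TSV genotype table in the field-report dialect: metadata
#' columns \code{sample_id}, \code{site}, \code{region}, \code{year} followed
#' by two allele columns per locus named \code{<locus>_1} and
#' \code{<locus>_2}. A cell equal to the missing token (default \code{"-"})
#' or empty is MISSING; a cell containing the slash token (e.g.
#' \code{"101/103"}) marks an AMBIGUOUS call whose candidate set is the union
#' of all alleles seen in both columns; otherwise the two columns give the
#' allele pair (a homozygote repeats the allele in both columns).
#'
#' @param path file path.
#' @param dialect a [genotypeDialect()] list.
#' @param loci locus panel; inferred from paired \code{_1}/\code{_2} headers
#'   when NULL.
#' @return A [GenotypeTable-class].
#' @examples
#' gt <- readGenotypeTable(scatidExample("survey_genotypes.csv"))
#' gt
#' @export
readGenotypeTable <- function(path, dialect = genotypeDialect(), loci = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = dialect$delim,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  meta <- c("sample_id", "site", "region", "year")
  if (!all(meta %in% names(df)))
    stop("genotype table must have columns ", paste(meta, collapse = ", "))
  if (is.null(loci)) {
    a1 <- sub("_1$", "", grep("_1$", names(df), value = TRUE))
    a2 <- sub("_2$", "", grep("_2$", names(df), value = TRUE))
    loci <- intersect(a1, a2)
  }
  if (!length(loci)) stop("no locus column pairs found in header")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  calls <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    stats::setNames(lapply(loci, function(L)
      .parse_cell(row[[paste0(L, "_1")]], row[[paste0(L, "_2")]],
                  L, row$sample_id, dialect)), loci)
  })
  samples <- data.frame(sample_id = df$sample_id, site = df$site,
                        region = df$region, year = as.integer(df$year),
                        stringsAsFactors = FALSE)
  new("GenotypeTable", samples = samples, loci = loci, calls = calls)
}

.format_cell <- function(g, dialect) {
  switch(g@status,
    OK = as.character(g@alleles),
    AMBIGUOUS = rep(paste(g@candidates, collapse = dialect$slash), 2L),
    MISSING = rep(dialect$missing, 2L))
}

#' Write a genotype table in the two-columns-per-locus dialect
#'
#' Inverse of [readGenotypeTable()]: OK cells round-trip exactly; AMBIGUOUS
#' cells are written as their slash-joined candidate set in both columns;
#' MISSING cells as the missing token.
#'
#' @param x a [GenotypeTable-class].
#' @param path output file path.
#' @param dialect a [genotypeDialect()] list.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeTable <- function(x, path, dialect = genotypeDialect()) {
  stopifnot(is(x, "GenotypeTable"))
  out <- x@samples
  for (L in x@loci) {
    cells <- vapply(x@calls, function(cl) .format_cell(cl[[L]], dialect),
                    character(2))
    out[[paste0(L, "_1")]] <- cells[1L, ]
    out[[paste0(L, "_2")]] <- cells[2L, ]
  }
  utils::write.table(out, path, sep = dialect$delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a genotype table in GenAlEx codominant layout
#'
#' Writes the standard GenAlEx two-column codominant CSV: three header rows
#' (counts; title and population names; column labels), then one row per
#' sample with the site as population and two numeric allele columns per
#' locus. MISSING and AMBIGUOUS calls are emitted as the missing code 0, so
#' only confirmed (OK) genotypes enter downstream GenAlEx analyses.
#'
#' @param x a [GenotypeTable-class].
#' @param path output file path.
#' @param title dataset title placed in the second header row.
#' @return \code{path}, invisibly.
#' @export
writeGenAlex <- function(x, path, title = "scatID export") {
  stopifnot(is(x, "GenotypeTable"))
  pops <- unique(x@samples$site)
  nl <- length(x@loci); ns <- nrow(x@samples)
  ncol_total <- 2L + 2L * nl
  pad <- function(v) c(v, rep("", ncol_total - length(v)))
  h1 <- pad(c(nl, ns, length(pops),
              as.vector(table(factor(x@samples$site, levels = pops)))))
  h2 <- pad(c(title, "", "", pops))
  h3 <- pad(c("Sample", "Pop",
              as.vector(rbind(x@loci, rep("", nl)))))
  rows <- lapply(seq_len(ns), function(i) {
    al <- unlist(lapply(x@calls[[i]], function(g)
      if (g@status == "OK") g@alleles else c(0L, 0L)), use.names = FALSE)
    c(x@samples$sample_id[i], x@samples$site[i], al)
  })
  m <- do.call(rbind, c(list(h1, h2, h3), rows))
  utils::write.table(m, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a replicate-level assay sample sheet
#'
#' One row per sample x assay x replicate with logical columns \code{band},
#' \code{pos_ctrl_ok}, \code{neg_ctrl_ok} plus sample metadata. Returns one
#' [SampleRecord-class] per sample, carrying every assay's replicate table.
#'
#' @param path CSV file path.
#' @param delim field delimiter.
#' @return Named list of [SampleRecord-class] objects, in first-appearance
#'   order.
#' @examples
#' sheet <- readSampleSheet(scatidExample("survey_sample_sheet.csv"))
#' length(sheet)
#' @export
readSampleSheet <- function(path, delim = ",") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("sample_id", "site", "region", "year", "assay", "replicate",
            "band", "pos_ctrl_ok", "neg_ctrl_ok")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  for (cc in c("band", "pos_ctrl_ok", "neg_ctrl_ok"))
    df[[cc]] <- as.logical(df[[cc]])
  ids <- unique(df$sample_id)
  recs <- lapply(ids, function(id) {
    sub <- df[df$sample_id == id, ]
    assays <- lapply(split(sub, sub$assay), function(a) {
      a <- a[order(a$replicate), ]
      data.frame(band = a$band, pos_ctrl_ok = a$pos_ctrl_ok,
                 neg_ctrl_ok = a$neg_ctrl_ok)
    })
    new("SampleRecord", sample_id = id, site = sub$site[1L],
        region = sub$region[1L], year = as.integer(sub$year[1L]),
        assays = assays, genotypes = list())
  })
  stats::setNames(recs, ids)
}

#' Read replicate-level microsatellite observations
#'
#' CSV with columns \code{sample_id}, \code{locus}, \code{replicate},
#' \code{allele1}, \code{allele2}; blank alleles mark an amplification
#' failure for that replicate.
#'
#' @param path CSV file path.
#' @param delim field delimiter.
#' @return Nested named list: sample_id -> locus -> list of integer vectors
#'   (one 0-2 allele vector per replicate), suitable for
#'   [consensusLocus()] / [consensusSample()].
#' @export
readGenotypeReplicates <- function(path, delim = ",") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = "character")
  need <- c("sample_id", "locus", "replicate", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("replicate table must have columns ", paste(need, collapse = ", "))
  lapply(split(df, df$sample_id)[unique(df$sample_id)], function(s)
    lapply(split(s, s$locus)[unique(s$locus)], function(l) {
      l <- l[order(as.integer(l$replicate)), ]
      lapply(seq_len(nrow(l)), function(i) {
        a <- c(l$allele1[i], l$allele2[i])
        a <- a[!is.na(a) & a != ""]
        unique(as.integer(a))
      })
    }))
}

#' Attach replicate genotype observations to sample records
#'
#' @param samples named list of [SampleRecord-class] (from
#'   [readSampleSheet()]).
#' @param replicates nested list from [readGenotypeReplicates()].
#' @return The sample list with \code{genotypes} slots filled where replicate
#'   data exist.
#' @export
attachGenotypeReplicates <- function(samples, replicates) {
  for (id in intersect(names(samples), names(replicates)))
    samples[[id]]@genotypes <- replicates[[id]]
  samples
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's \code{extdata}; lists available
#'   files when missing.
#' @return File path (or vector of file names).
#' @export
scatidExample <- function(file) {
  if (missing(file))
    return(dir(system.file("extdata", package = "scatID")))
  p <- system.file("extdata", file, package = "scatID")
  if (p == "") stop("no packaged file named ", file)
  p
}
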
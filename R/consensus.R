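#' @include AllClasses.R
NULL

#' Consensus genotype at one locus from replicate PCRs
#'
#' Multiple-tubes consensus: an allele is confirmed when observed in at least
#' \code{min_support} replicates. Two confirmed alleles give an OK
#' heterozygote; one confirmed allele with no other allele ever observed
#' gives an OK homozygote; one confirmed allele alongside unconfirmed ones
#' (possible dropout of the partner allele) or observations with nothing
#' confirmed yield AMBIGUOUS with the full candidate set; replicates that all
#' failed yield MISSING. More than two confirmed alleles (a scoring fault or
#' mixed sample upstream) is also reported AMBIGUOUS rather than forced into
#' a pair.
#'
#' @param observations list of replicate observations, each an integer
#'   vector of 0-2 distinct alleles (length 0 = amplification failure).
#' @param locus locus name attached to the call.
#' @param min_support replicates required to confirm an allele (default 2,
#'   the classic 2-of-3 rule).
#' @return A [LocusGenotype-class] with per-allele \code{support} counts.
#' @examples
#' consensusLocus(list(c(90, 96), c(90, 96), 90), "PUN124")      # OK 90/96
#' consensusLocus(list(90, 90, 96), "PUN124")   # AMBIGUOUS {90,96}
#' consensusLocus(list(integer(), integer(), integer()), "PUN124") # MISSING
#' @export
consensusLocus <- function(observations, locus = NA_character_,
                           min_support = 2L) {
  stopifnot(length(observations) >= 1L)
  observations <- lapply(observations, function(o) unique(as.integer(o)))
  nal <- lengths(observations)
  if (any(nal > 2L))
    stop("replicate observation with >2 alleles at ", locus,
         ": scoring fault or mixed sample")
  seen <- unlist(observations, use.names = FALSE)
  if (!length(seen))
    return(LocusGenotype(locus, status = "MISSING"))
  support <- vapply(sort(unique(seen)), function(a)
    sum(vapply(observations, function(o) a %in% o, logical(1))), integer(1))
  names(support) <- sort(unique(seen))
  confirmed <- as.integer(names(support)[support >= min_support])
  unconfirmed <- as.integer(names(support)[support < min_support])
  g <- if (length(confirmed) == 2L && !length(unconfirmed))
    LocusGenotype(locus, alleles = confirmed)
  else if (length(confirmed) == 2L)
    # two confirmed plus extra unconfirmed observations: keep everything
    LocusGenotype(locus, status = "AMBIGUOUS",
                  candidates = c(confirmed, unconfirmed))
  else if (length(confirmed) == 1L && !length(unconfirmed))
    LocusGenotype(locus, alleles = rep(confirmed, 2L))
  else
    LocusGenotype(locus, status = "AMBIGUOUS",
                  candidates = c(confirmed, unconfirmed))
  g@support <- support
  g
}

#' Composite consensus genotype for one sample
#'
#' Applies [consensusLocus()] across a locus panel. Loci with no replicate
#' data are MISSING. The composite is flagged complete when every panel
#' locus is OK.
#'
#' @param sample a [SampleRecord-class], or a named list locus -> list of
#'   replicate allele vectors (one element of
#'   [readGenotypeReplicates()] output).
#' @param loci locus panel (default: the loci present in the sample).
#' @param min_support as in [consensusLocus()].
#' @return list with \code{genotypes} (named list of [LocusGenotype-class]
#'   over \code{loci}) and \code{complete} (logical).
#' @export
consensusSample <- function(sample, loci = NULL, min_support = 2L) {
  reps <- if (is(sample, "SampleRecord")) sample@genotypes else sample
  if (is.null(loci)) loci <- names(reps)
  stopifnot(length(loci) >= 1L)
  genotypes <- stats::setNames(lapply(loci, function(L) {
    if (is.null(reps[[L]]) || !length(reps[[L]]))
      LocusGenotype(L, status = "MISSING")
    else consensusLocus(reps[[L]], L, min_support)
  }), loci)
  statuses <- vapply(genotypes, gtStatus, character(1))
  list(genotypes = genotypes, complete = all(statuses == "OK"))
}

#' Build a GenotypeTable of consensus composites
#'
#' Convenience wrapper running [consensusSample()] over a list of sample
#' records and assembling the results into a [GenotypeTable-class].
#'
#' @param samples named list of [SampleRecord-class] with replicate genotype
#'   data.
#' @param loci locus panel.
#' @param min_support as in [consensusLocus()].
#' @return A [GenotypeTable-class].
#' @export
consensusTable <- function(samples, loci, min_support = 2L) {
  calls <- lapply(samples, function(s)
    consensusSample(s, loci, min_support)$genotypes)
  meta <- data.frame(
    sample_id = vapply(samples, slot, character(1), "sample_id"),
    site = vapply(samples, slot, character(1), "site"),
    region = vapply(samples, slot, character(1), "region"),
    year = vapply(samples, slot, integer(1), "year"),
    stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  new("GenotypeTable", samples = meta, loci = loci,
      calls = unname(calls))
}

#' Genotyping success rate across a panel
#'
#' Fraction of samples counted as successfully genotyped. A sample counts as
#' successful when it was scored (OK or AMBIGUOUS; a retained candidate set
#' is still a scored locus) at no fewer than \code{min_scored} loci. The
#' default allows one unscored locus, the near-complete criterion under
#' which a sample missing a single locus but informative at the rest is
#' still carried into individual identification.
#'
#' @param composites list of composite genotypes (named lists of
#'   [LocusGenotype-class]), e.g. \code{composites(gt)}, over the samples in
#'   the denominator (typically the species-positive samples; samples with no
#'   genotype data at all enter as all-MISSING composites).
#' @param loci locus panel.
#' @param min_scored minimum scored loci to count as successful (default
#'   \code{length(loci) - 1}).
#' @return list with \code{n_success}, \code{n_total}, \code{rate}.
#' @export
genotypingSuccessRate <- function(composites, loci,
                                  min_scored = length(loci) - 1L) {
  scored <- vapply(composites, function(cl)
    sum(vapply(loci, function(L) {
      g <- cl[[L]]
      !is.null(g) && gtStatus(g) != "MISSING"
    }, logical(1))), integer(1))
  n_success <- sum(scored >= min_scored)
  n_total <- length(composites)
  list(n_success = n_success, n_total = n_total,
       rate = if (n_total) n_success / n_total else 0)
}
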
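#' @include AllClasses.R
NULL

.aln_matrix <- function(aln) {
  if (is(aln, "DNAMultipleAlignment"))
    aln <- as(aln, "DNAStringSet")
  if (is(aln, "DNAStringSet") || is(aln, "XStringSet"))
    aln <- stats::setNames(as.character(aln), names(aln))
  stopifnot(is.character(aln), !is.null(names(aln)), length(aln) >= 2L)
  w <- unique(nchar(aln))
  if (length(w) != 1L)
    stop("aligned sequences must all have equal length")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("alignment alphabet must be {A,C,G,T,N,-}; found ",
         paste(bad, collapse = ","))
  m
}

#' Read a multi-species alignment from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the named
#' character representation used by [scanDiagnosticSites()].
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return Named character vector of aligned sequences.
#' @export
readAlignmentFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

.rolling_sum <- function(v, k) {
  cs <- c(0, cumsum(v))
  cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]
}

.scan_one_strand <- function(m, target, k, window3, min3, min_total, strand) {
  tgt <- m[target, ]
  off <- m[setdiff(rownames(m), target), , drop = FALSE]
  L <- ncol(m)
  # per off-target per column mismatch; N in the off-target is treated as
  # compatible (not a mismatch), gaps as mismatches
  mm <- sweep(off, 2L, tgt, FUN = function(o, t) (o != t) & (o != "N"))
  storage.mode(mm) <- "integer"
  starts <- 1:(L - k + 1L)
  total_by_off <- t(apply(mm, 1L, .rolling_sum, k = k))
  if (strand == "forward") {
    w3_by_off <- t(apply(mm, 1L, function(v)
      .rolling_sum(v, window3)[starts + (k - window3)]))
  } else {
    # the reverse primer is the reverse complement of the window, so its
    # 3'-terminal bases map to the leftmost alignment columns of the window
    w3_by_off <- t(apply(mm, 1L, function(v) .rolling_sum(v, window3)[starts]))
  }
  if (nrow(off) == 1L) {
    total_by_off <- matrix(total_by_off, nrow = 1L)
    w3_by_off <- matrix(w3_by_off, nrow = 1L)
  }
  min_total_v <- apply(total_by_off, 2L, min)
  min_w3_v <- apply(w3_by_off, 2L, min)
  clean <- vapply(starts, function(s)
    !any(tgt[s:(s + k - 1L)] %in% c("-", "N")), logical(1))
  hit <- clean & if (strand == "forward") min_w3_v >= min3
                 else min_total_v >= min_total
  data.frame(start = starts[hit] - 1L, strand = rep(strand, sum(hit)),
             k = rep(k, sum(hit)),
             min_3prime_mismatches = min_w3_v[hit],
             min_total_mismatches = min_total_v[hit])
}

#' Scan an alignment for species-diagnostic primer sites
#'
#' Slides a k-base window over a multi-species alignment and reports windows
#' where the target sequence is discriminable from every off-target species
#' by primer-annealing mismatches, the design logic of allele- and
#' species-specific PCR. A forward site requires at least \code{min3}
#' mismatches versus every off-target within the \code{window3} 3'-terminal
#' bases of the primer; a reverse site requires at least \code{min_total}
#' mismatches anywhere in the window. Reverse-strand primers are the reverse
#' complement of the window, so their 3' end maps to the window's left edge.
#' Windows containing a gap or N in the target are disqualified
#' (un-synthesizable primer). Coordinates are 0-based alignment columns,
#' half-open windows \code{[start, start + k)}.
#'
#' @param aln named character vector / DNAStringSet / DNAMultipleAlignment of
#'   equal-length aligned sequences.
#' @param target name of the target species sequence.
#' @param k primer length (default 20).
#' @param window3 number of 3'-terminal bases inspected for the forward
#'   criterion (default 5).
#' @param min3 minimum 3'-window mismatches vs the worst off-target for a
#'   forward site (default 2).
#' @param min_total minimum whole-window mismatches vs the worst off-target
#'   for a reverse site (default 5, i.e. strictly more than 4).
#' @param strand \code{"forward"}, \code{"reverse"} or \code{"both"}.
#' @return data.frame with columns \code{start}, \code{strand}, \code{k},
#'   \code{min_3prime_mismatches}, \code{min_total_mismatches} (both minima
#'   taken over off-target species).
#' @examples
#' aln <- c(target = "ACGTACGTACGTACGTACGTGG",
#'          other  = "ACGTACGTACGTACGTACGTAA")
#' scanDiagnosticSites(aln, "target", k = 10, window3 = 5, min3 = 2,
#'                     strand = "forward")
#' @export
scanDiagnosticSites <- function(aln, target, k = 20L, window3 = 5L,
                                min3 = 2L, min_total = 5L,
                                strand = c("both", "forward", "reverse")) {
  strand <- match.arg(strand)
  m <- .aln_matrix(aln)
  if (!target %in% rownames(m)) stop("target id absent from alignment: ", target)
  if (k > ncol(m)) stop("primer length k exceeds alignment length")
  stopifnot(window3 <= k)
  strands <- if (strand == "both") c("forward", "reverse") else strand
  out <- do.call(rbind, lapply(strands, function(sdir)
    .scan_one_strand(m, target, as.integer(k), as.integer(window3),
                     min3, min_total, sdir)))
  rownames(out) <- NULL
  out
}

#' Amplicon length for a primer pair on the target
#'
#' Ungapped target length spanned by a forward/reverse primer pair, from the
#' first base of the forward primer to the last base of the reverse primer
#' inclusive. Alignment gaps in the target do not count toward the length.
#'
#' @param aln alignment as in [scanDiagnosticSites()].
#' @param target target species id.
#' @param fwd,rev one-row data.frames (or lists) with \code{start} (0-based)
#'   and \code{k}; \code{fwd} must lie strictly upstream of \code{rev} with
#'   no overlap.
#' @return Integer amplicon length in bp.
#' @examples
#' aln <- c(t = paste(rep("ACGT", 40), collapse = ""),
#'          o = paste(rep("TGCA", 40), collapse = ""))
#' ampliconForPair(aln, "t", list(start = 0, k = 20),
#'                 list(start = 140, k = 20))
#' @export
ampliconForPair <- function(aln, target, fwd, rev) {
  m <- .aln_matrix(aln)
  if (!target %in% rownames(m)) stop("target id absent from alignment")
  f0 <- as.integer(fwd$start); fk <- as.integer(fwd$k)
  r0 <- as.integer(rev$start); rk <- as.integer(rev$k)
  if (f0 + fk > r0)
    stop("primer pair overlapping or inverted (forward must end before reverse starts)")
  cols <- (f0 + 1L):(r0 + rk)            # 1-based alignment columns
  if (max(cols) > ncol(m)) stop("reverse primer extends past alignment end")
  sum(m[target, cols] != "-")
}
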
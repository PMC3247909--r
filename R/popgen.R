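#' @include AllClasses.R
NULL

#' Allele frequencies from unique individuals
#'
#' Estimates per-locus allele frequencies from the unique composite
#' genotypes observed — each recovered individual contributes exactly two
#' allele copies per locus, so duplicate scats never inflate a frequency.
#' Per locus, only confirmed (OK) genotypes contribute; AMBIGUOUS and
#' MISSING calls are excluded entirely, which is why the per-locus sample
#' size N varies across the panel.
#'
#' @param x an [IndividualClusters-class] (duplicates already collapsed), a
#'   [GenotypeTable-class] whose rows are already unique individuals, or a
#'   list of composite genotypes.
#' @param loci locus panel (default: taken from \code{x}).
#' @return An [AlleleFreqTable-class]. Loci with no OK genotype are present
#'   with N = 0 and empty frequencies.
#' @examples
#' gt <- readGenotypeTable(scatidExample("survey_genotypes.csv"))
#' af <- alleleFrequencies(clusterIndividuals(gt))
#' alleleFreqs(af, "PUN894")
#' @export
alleleFrequencies <- function(x, loci = NULL) {
  comps <- if (is(x, "IndividualClusters")) composites(x)
           else if (is(x, "GenotypeTable")) composites(x)
           else x
  if (is.null(loci))
    loci <- if (is(x, "GenotypeTable")) x@loci else names(comps[[1L]])
  N <- integer(0); freqs <- list(); het <- integer(0)
  for (L in loci) {
    gs <- Filter(function(g) !is.null(g) && gtStatus(g) == "OK",
                 lapply(comps, `[[`, L))
    N[[L]] <- length(gs)
    if (!length(gs)) { freqs[[L]] <- numeric(); het[[L]] <- 0L; next }
    copies <- unlist(lapply(gs, gtAlleles), use.names = FALSE)
    tab <- table(copies)
    freqs[[L]] <- stats::setNames(as.numeric(tab) / length(copies),
                                  names(tab))
    het[[L]] <- sum(vapply(gs, function(g) {
      a <- gtAlleles(g); a[1L] != a[2L]
    }, logical(1)))
  }
  new("AlleleFreqTable", loci = loci, N = N, freqs = freqs, het = het)
}

#' Probability of identity at one locus
#'
#' Probability that two individuals drawn from a Hardy-Weinberg population
#' share their genotype at this locus by chance, for unrelated individuals
#' and for full siblings (the conservative bound used to justify uniting
#' samples into one individual):
#' \deqn{PID_{unrel} = 2(\sum_i p_i^2)^2 - \sum_i p_i^4}
#' \deqn{PID_{sib} = 0.25 + 0.5\sum_i p_i^2 + 0.5(\sum_i p_i^2)^2
#'   - 0.25\sum_i p_i^4}
#'
#' @param p numeric vector of allele frequencies summing to 1.
#' @return Named numeric: \code{pid_u}, \code{pid_sib}.
#' @examples
#' pidLocus(c(0.5, 0.5))   # 0.375, 0.59375
#' @export
pidLocus <- function(p) {
  if (abs(sum(p) - 1) > 1e-9)
    stop("allele frequencies must sum to 1 (got ", format(sum(p)), ")")
  s2 <- sum(p^2); s4 <- sum(p^4)
  c(pid_u = 2 * s2^2 - s4,
    pid_sib = 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4)
}

#' Per-locus diversity and identity statistics
#'
#' Computes, at full floating precision, the standard codominant-marker
#' summaries for one locus: observed allele count Na, effective allele
#' count \eqn{Ne = 1/\sum p_i^2}, observed heterozygosity Ho (heterozygote
#' fraction of typed individuals), expected heterozygosity
#' \eqn{He = 1 - \sum p_i^2}, its small-sample unbiased version
#' \eqn{UHe = \frac{2N}{2N-1} He}, and both probabilities of identity from
#' [pidLocus()]. Rounding happens only at presentation (see
#' [formatSummaryTable()]).
#'
#' @param p named numeric allele frequencies (summing to 1).
#' @param N number of typed individuals.
#' @param n_het observed heterozygote count among the N individuals.
#' @param locus locus name carried into the output.
#' @return One-row data.frame with columns locus, N, Na, Ne, Ho, He, UHe,
#'   pid_u, pid_sib. With N = 0 the statistics are NA (undefined, never
#'   zero-filled).
#' @export
locusStats <- function(p, N, n_het, locus = NA_character_) {
  if (N < 1L || !length(p))
    return(data.frame(locus = locus, N = 0L, Na = NA_integer_, Ne = NA_real_,
                      Ho = NA_real_, He = NA_real_, UHe = NA_real_,
                      pid_u = NA_real_, pid_sib = NA_real_))
  s2 <- sum(p^2)
  pid <- pidLocus(p)
  data.frame(locus = locus, N = as.integer(N), Na = length(p), Ne = 1 / s2,
             Ho = n_het / N, He = 1 - s2,
             UHe = (2 * N) / (2 * N - 1) * (1 - s2),
             pid_u = unname(pid["pid_u"]), pid_sib = unname(pid["pid_sib"]))
}

#' Diversity statistics for every locus of a frequency table
#'
#' @param af an [AlleleFreqTable-class].
#' @return data.frame with one [locusStats()] row per locus, in panel order.
#' @export
locusStatsTable <- function(af) {
  stopifnot(is(af, "AlleleFreqTable"))
  do.call(rbind, lapply(af@loci, function(L)
    locusStats(af@freqs[[L]], af@N[[L]], af@het[[L]], L)))
}

#' Cumulative probability of identity across loci
#'
#' Product of per-locus PID values over the panel: the probability that two
#' individuals (unrelated, or full siblings) share the whole composite
#' genotype by chance. Order-invariant and non-increasing as loci are added.
#'
#' @param per_locus data.frame with columns \code{pid_u} and \code{pid_sib}
#'   (e.g. from [locusStatsTable()]), or a list of [pidLocus()] results.
#' @return Named numeric: \code{pid_u}, \code{pid_sib}.
#' @export
cumulativePID <- function(per_locus) {
  if (is.list(per_locus) && !is.data.frame(per_locus))
    per_locus <- as.data.frame(do.call(rbind, per_locus))
  if (!nrow(per_locus)) stop("cumulative PID needs at least one locus")
  c(pid_u = prod(per_locus$pid_u, na.rm = FALSE),
    pid_sib = prod(per_locus$pid_sib, na.rm = FALSE))
}

#' Panel summary with overall means
#'
#' Assembles the per-locus statistics into the conventional summary report:
#' one row per locus plus unweighted across-locus means of Ho and He (each
#' locus weighted equally regardless of its N).
#'
#' @param stats data.frame from [locusStatsTable()].
#' @return list with \code{per_locus} (the input, panel order preserved),
#'   \code{overall} (named numeric: mean Ho, mean He across loci), and
#'   \code{cumulative_pid} (from [cumulativePID()]).
#' @export
summaryTable <- function(stats) {
  stopifnot(is.data.frame(stats), nrow(stats) >= 1L)
  list(per_locus = stats,
       overall = c(Ho = mean(stats$Ho, na.rm = TRUE),
                   He = mean(stats$He, na.rm = TRUE)),
       cumulative_pid = cumulativePID(stats))
}

#' Presentation rounding for the panel summary
#'
#' Applies the conventional report rounding — Ne to 1 decimal; Ho, He, UHe
#' to 3 — to a [locusStatsTable()] data.frame. Internal arithmetic is never
#' rounded; this is display-only.
#'
#' @param stats data.frame from [locusStatsTable()].
#' @param pid also include rounded PID columns (4 significant digits).
#' @return data.frame of formatted character/numeric columns.
#' @export
formatSummaryTable <- function(stats, pid = FALSE) {
  out <- data.frame(Locus = stats$locus, N = stats$N, Na = stats$Na,
                    Ne = round(stats$Ne, 1), Ho = round(stats$Ho, 3),
                    He = round(stats$He, 3), UHe = round(stats$UHe, 3))
  if (pid) {
    out$PID_unrelated <- signif(stats$pid_u, 4)
    out$PID_sibling <- signif(stats$pid_sib, 4)
  }
  out
}

#' Full diversity pipeline on a genotype table
#'
#' Clusters samples into individuals, estimates allele frequencies from the
#' unique individuals, and computes the per-locus and cumulative summary
#' statistics.
#'
#' @param gt a [GenotypeTable-class].
#' @param min_shared matching threshold for [clusterIndividuals()].
#' @return list with \code{clusters}, \code{freqs}, \code{stats} (per-locus
#'   data.frame), \code{overall}, \code{cumulative_pid}.
#' @export
surveyStats <- function(gt, min_shared = 4L) {
  cl <- clusterIndividuals(gt, min_shared = min_shared)
  af <- alleleFrequencies(cl, loci = loci(gt))
  st <- locusStatsTable(af)
  sm <- summaryTable(st)
  list(clusters = cl, freqs = af, stats = st,
       overall = sm$overall, cumulative_pid = sm$cumulative_pid)
}
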
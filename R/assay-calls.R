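#' @include AllClasses.R
NULL

.valid_reps <- function(replicates) {
  if (is.data.frame(replicates)) {
    stopifnot(all(c("band", "pos_ctrl_ok", "neg_ctrl_ok") %in%
                    names(replicates)))
    if (nrow(replicates) < 1L) stop("empty replicate list")
    return(replicates)
  }
  stop("replicates must be a data.frame with band/pos_ctrl_ok/neg_ctrl_ok")
}

#' Call a presence/absence PCR assay from replicates
#'
#' Implements the replicated (multiple-tubes) call rule for a
#' presence/absence PCR assay run with a positive and a no-template negative
#' control per replicate. A replicate with any failed control is excluded
#' from the call. The sample is POSITIVE when at least \code{min_positive}
#' valid replicates show the band, NEGATIVE when at least \code{min_valid}
#' valid replicates exist and fewer than \code{min_positive} show the band,
#' and INVALID otherwise (too few interpretable replicates). The defaults
#' (2 of 3) guard symmetrically against single-replicate contamination and
#' single-replicate dropout.
#'
#' @param replicates data.frame with one row per replicate and logical
#'   columns \code{band}, \code{pos_ctrl_ok}, \code{neg_ctrl_ok}.
#' @param min_valid minimum number of control-valid replicates for a
#'   non-INVALID call.
#' @param min_positive minimum band-positive valid replicates for POSITIVE.
#' @return list with elements \code{call} ("POSITIVE", "NEGATIVE",
#'   "INVALID"), \code{n_valid}, \code{n_positive}.
#' @examples
#' reps <- data.frame(band = c(TRUE, TRUE, FALSE),
#'                    pos_ctrl_ok = TRUE, neg_ctrl_ok = TRUE)
#' callAssay(reps)$call
#' @export
callAssay <- function(replicates, min_valid = 2L, min_positive = 2L) {
  replicates <- .valid_reps(replicates)
  valid <- replicates$pos_ctrl_ok & replicates$neg_ctrl_ok
  n_valid <- sum(valid)
  n_positive <- sum(replicates$band & valid)
  call <- if (n_positive >= min_positive) "POSITIVE"
          else if (n_valid >= min_valid) "NEGATIVE"
          else "INVALID"
  list(call = call, n_valid = n_valid, n_positive = n_positive)
}

#' Call sex from the Y-chromosome presence/absence assay
#'
#' Sex is read from a Y-specific (AMELY-intron) amplification: males yield
#' the ~200 bp fragment, females show reproducible absence. Absence is only
#' interpretable when the sample is confirmed target species with amplifiable
#' DNA, so the species call must be POSITIVE. MALE requires at least
#' \code{min_positive} valid band-positive replicates; FEMALE requires at
#' least \code{min_valid} valid replicates, all band-negative; anything else
#' (e.g. a single band among three valid replicates, where dropout and
#' contamination are indistinguishable) is UNKNOWN.
#'
#' @param replicates replicate data.frame as in [callAssay()].
#' @param species_call the sample's species assay call; must be
#'   \code{"POSITIVE"}.
#' @param min_valid,min_positive thresholds as in [callAssay()].
#' @return "MALE", "FEMALE" or "UNKNOWN".
#' @export
callSex <- function(replicates, species_call = "POSITIVE",
                    min_valid = 2L, min_positive = 2L) {
  if (!identical(species_call, "POSITIVE"))
    stop("sex assay uninterpretable: species call is not POSITIVE")
  ac <- callAssay(replicates, min_valid = min_valid,
                  min_positive = min_positive)
  if (ac$call == "POSITIVE") "MALE"
  else if (ac$call == "NEGATIVE" && ac$n_positive == 0L) "FEMALE"
  else "UNKNOWN"
}

.sample_call <- function(rec, assay, ...) {
  if (!assay %in% names(rec@assays))
    return(list(call = "INVALID", n_valid = 0L, n_positive = 0L))
  callAssay(rec@assays[[assay]], ...)
}

#' Species-vs-carnivore assay congruence table
#'
#' Cross-tabulates the species-specific and carnivore-generic assay calls
#' over a survey, the standard consistency check that every scat identified
#' to the target species also verifies as carnivore. INVALID calls are
#' tallied separately, never forced into the 2x2.
#'
#' @param samples list of [SampleRecord-class] with \code{carnivore} and
#'   \code{species} assays.
#' @param ... thresholds passed to [callAssay()].
#' @return list with \code{table} (2x2 matrix, species x carnivore),
#'   \code{n_invalid}, \code{total}, and \code{congruence} (fraction of
#'   species-positive samples that are carnivore-positive; NA when there are
#'   none).
#' @export
congruenceTable <- function(samples, ...) {
  sp <- vapply(samples, function(r) .sample_call(r, "species", ...)$call,
               character(1))
  ca <- vapply(samples, function(r) .sample_call(r, "carnivore", ...)$call,
               character(1))
  ok <- sp != "INVALID" & ca != "INVALID"
  tab <- table(factor(sp[ok], levels = c("POSITIVE", "NEGATIVE")),
               factor(ca[ok], levels = c("POSITIVE", "NEGATIVE")),
               dnn = c("species", "carnivore"))
  n_sp_pos <- sum(tab["POSITIVE", ])
  list(table = unclass(tab),
       n_invalid = sum(!ok),
       total = length(samples),
       congruence = if (n_sp_pos > 0) tab["POSITIVE", "POSITIVE"] / n_sp_pos
                    else NA_real_)
}

#' Survey-level attrition summary
#'
#' Tallies each stage of a noninvasive survey on the denominators
#' conventionally reported: scats collected, carnivore-positive (of
#' collected), species-positive (of collected), successfully genotyped (of
#' species-positive) and unique individuals (of species-positive).
#'
#' @param samples list of [SampleRecord-class].
#' @param n_genotyped number of species-positive samples successfully
#'   genotyped (optional; see [genotypingSuccessRate()]).
#' @param n_individuals number of unique individuals recovered (optional).
#' @param ... thresholds passed to [callAssay()].
#' @return data.frame with columns stage, count, denominator, percent.
#' @export
surveySummary <- function(samples, n_genotyped = NA_integer_,
                          n_individuals = NA_integer_, ...) {
  ca <- vapply(samples, function(r) .sample_call(r, "carnivore", ...)$call,
               character(1))
  sp <- vapply(samples, function(r) .sample_call(r, "species", ...)$call,
               character(1))
  n <- length(samples)
  n_ca <- sum(ca == "POSITIVE")
  n_sp <- sum(sp == "POSITIVE")
  out <- data.frame(
    stage = c("collected", "carnivore_positive", "species_positive",
              "genotyped", "unique_individuals"),
    count = c(n, n_ca, n_sp, n_genotyped, n_individuals),
    denominator = c(NA_integer_, n, n, n_sp, n_sp))
  out$percent <- 100 * out$count / out$denominator
  out
}
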
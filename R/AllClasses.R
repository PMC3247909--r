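#' @import methods
NULL

.GT_STATUS <- c("OK", "AMBIGUOUS", "MISSING")

#' Single-locus microsatellite genotype call
#'
#' One sample x one locus call. Alleles are PCR fragment sizes in base pairs
#' (exact integer identity; no binning tolerance). A call is \code{OK} when
#' two alleles are confirmed (a homozygote carries the same allele twice),
#' \code{AMBIGUOUS} when the observations admit more than one genotype (the
#' candidate allele set is retained, never silently resolved), and
#' \code{MISSING} when nothing amplified.
#'
#' @slot locus locus name.
#' @slot alleles integer vector: length 2 for \code{OK}, length 0 otherwise.
#' @slot status one of \code{"OK"}, \code{"AMBIGUOUS"}, \code{"MISSING"}.
#' @slot candidates integer vector of candidate alleles; non-empty iff
#'   \code{AMBIGUOUS}.
#' @slot support named integer vector of per-allele replicate counts (may be
#'   empty when the call was read from a consensus table rather than built
#'   from replicates).
#'
#' @seealso [consensusLocus()] which builds these from replicate
#'   observations, [readGenotypeTable()] which parses them from tables.
#' @export
setClass("LocusGenotype",
  representation(
    locus = "character",
    alleles = "integer",
    status = "character",
    candidates = "integer",
    support = "integer"
  ),
  prototype(locus = NA_character_, alleles = integer(), status = "MISSING",
            candidates = integer(), support = integer())
)

setValidity("LocusGenotype", function(object) {
  msg <- character()
  if (length(object@status) != 1L || !object@status %in% .GT_STATUS)
    msg <- c(msg, "status must be one of OK, AMBIGUOUS, MISSING")
  else {
    if (object@status == "OK" && length(object@alleles) != 2L)
      msg <- c(msg, "OK call must carry exactly 2 alleles")
    if (object@status != "OK" && length(object@alleles) != 0L)
      msg <- c(msg, "non-OK call must carry no alleles")
    if (object@status == "AMBIGUOUS" && length(object@candidates) < 1L)
      msg <- c(msg, "AMBIGUOUS call must carry a non-empty candidate set")
    if (object@status != "AMBIGUOUS" && length(object@candidates) != 0L)
      msg <- c(msg, "candidates only allowed for AMBIGUOUS calls")
  }
  if (any(c(object@alleles, object@candidates) <= 0L, na.rm = TRUE))
    msg <- c(msg, "allele sizes (bp) must be positive integers")
  if (length(msg)) msg else TRUE
})

#' Construct a LocusGenotype
#'
#' @param locus locus name.
#' @param alleles integer vector of length 2 (OK calls) or 0.
#' @param status call status; inferred as \code{"OK"} when two alleles are
#'   given and \code{"MISSING"} when none are.
#' @param candidates candidate alleles for AMBIGUOUS calls.
#' @param support named integer vector of per-allele replicate counts.
#' @return A [LocusGenotype-class] object.
#' @examples
#' LocusGenotype("PUN124", c(90L, 96L))
#' LocusGenotype("PUN1157", status = "AMBIGUOUS", candidates = c(101L, 103L))
#' @export
LocusGenotype <- function(locus, alleles = integer(), status = NULL,
                          candidates = integer(), support = integer()) {
  alleles <- as.integer(alleles)
  if (is.null(status))
    status <- if (length(alleles) == 2L) "OK" else "MISSING"
  new("LocusGenotype", locus = as.character(locus),
      alleles = sort(alleles), status = status,
      candidates = sort(unique(as.integer(candidates))),
      support = support)
}

setMethod("show", "LocusGenotype", function(object) {
  body <- switch(object@status,
    OK = paste(object@alleles, collapse = "/"),
    AMBIGUOUS = paste0("{", paste(object@candidates, collapse = ","), "}?"),
    MISSING = "-")
  cat(sprintf("LocusGenotype %s [%s] %s\n", object@locus, object@status, body))
})

#' Multilocus genotype table
#'
#' Container for a sample x locus table of microsatellite genotype calls, the
#' central object of the individual-identification pipeline. Every sample row
#' has an entry (possibly MISSING) for every locus of the panel. Rows usually
#' come from [readGenotypeTable()] or from [consensusSample()] applied to
#' replicate observations.
#'
#' @slot samples data.frame with columns \code{sample_id}, \code{site},
#'   \code{region}, \code{year} (one row per sample; \code{sample_id} unique).
#' @slot loci ordered character vector of locus names.
#' @slot calls list parallel to \code{samples} rows; each element is a named
#'   list of [LocusGenotype-class] objects over \code{loci}.
#'
#' @seealso [readGenotypeTable()], [writeGenotypeTable()], [writeGenAlex()],
#'   [clusterIndividuals()]
#' @export
setClass("GenotypeTable",
  representation(samples = "data.frame", loci = "character", calls = "list")
)

setValidity("GenotypeTable", function(object) {
  msg <- character()
  s <- object@samples
  need <- c("sample_id", "site", "region", "year")
  if (!all(need %in% names(s)))
    msg <- c(msg, sprintf("samples must have columns %s",
                          paste(need, collapse = ", ")))
  else if (anyDuplicated(s$sample_id))
    msg <- c(msg, "duplicate sample_id in survey")
  if (length(object@calls) != nrow(s))
    msg <- c(msg, "one calls entry required per sample row")
  ok <- vapply(object@calls, function(cl)
    identical(names(cl), object@loci) &&
      all(vapply(cl, is, logical(1), "LocusGenotype")), logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "every row must hold one LocusGenotype per panel locus")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf("GenotypeTable: %d samples x %d loci (%s)\n",
              nrow(object@samples), length(object@loci),
              paste(object@loci, collapse = ", ")))
  st <- table(factor(unlist(lapply(object@calls, function(cl)
    vapply(cl, slot, character(1), "status"))), levels = .GT_STATUS))
  cat(sprintf("calls: %d OK, %d AMBIGUOUS, %d MISSING\n",
              st[["OK"]], st[["AMBIGUOUS"]], st[["MISSING"]]))
})

#' One scat sample with replicate-level observations
#'
#' A field-collected sample carrying its replicate PCR assay outcomes
#' (carnivore / species / sex presence-absence tests with controls) and its
#' replicate microsatellite observations, prior to any consensus calling.
#'
#' @slot sample_id sample identifier, unique within a survey.
#' @slot site protected area code (e.g. SPNP, KCA).
#' @slot region region within site (e.g. Shey, Dho, Ghunsa, Yagma).
#' @slot year collection year.
#' @slot assays named list (assay name -> data.frame with logical columns
#'   \code{band}, \code{pos_ctrl_ok}, \code{neg_ctrl_ok}, one row per
#'   replicate).
#' @slot genotypes named list (locus -> list of integer vectors, one vector
#'   of 0-2 observed alleles per replicate; length 0 = amplification failure).
#' @export
setClass("SampleRecord",
  representation(sample_id = "character", site = "character",
                 region = "character", year = "integer",
                 assays = "list", genotypes = "list")
)

setValidity("SampleRecord", function(object) {
  msg <- character()
  for (a in names(object@assays)) {
    df <- object@assays[[a]]
    if (!is.data.frame(df) ||
        !all(c("band", "pos_ctrl_ok", "neg_ctrl_ok") %in% names(df)) ||
        nrow(df) < 1L)
      msg <- c(msg, sprintf("assay '%s' needs >=1 replicate row with band/pos_ctrl_ok/neg_ctrl_ok", a))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SampleRecord", function(object) {
  cat(sprintf("SampleRecord %s (%s/%s %d): assays [%s], %d genotyped loci\n",
              object@sample_id, object@site, object@region, object@year,
              paste(names(object@assays), collapse = ", "),
              length(object@genotypes)))
})

#' Individuals recovered by composite-genotype clustering
#'
#' Result of [clusterIndividuals()]: a partition of samples into putative
#' individuals, each cluster carrying its consensus composite genotype, a sex
#' call (once [attachSex()] has run), the set of collection sites, and an
#' audit of non-transitive match conflicts.
#'
#' @slot clusters list; each element a list with fields \code{individual_id},
#'   \code{members} (sample ids), \code{composite} (named list of
#'   [LocusGenotype-class]), \code{sex}, \code{sites} (data.frame),
#'   \code{unresolved} (logical: isolated only because too few loci were
#'   comparable).
#' @slot min_shared minimum co-typed loci used for a MATCH.
#' @slot conflicts data.frame of non-transitive MATCH triples (empty when the
#'   match relation was transitive on this input).
#' @export
setClass("IndividualClusters",
  representation(clusters = "list", min_shared = "integer",
                 conflicts = "data.frame")
)

setMethod("show", "IndividualClusters", function(object) {
  n <- length(object@clusters)
  sizes <- vapply(object@clusters, function(cl) length(cl$members), integer(1))
  cat(sprintf("IndividualClusters: %d individuals from %d samples (min_shared=%d)\n",
              n, sum(sizes), object@min_shared))
  multi <- sum(sizes > 1L)
  if (multi) cat(sprintf("  %d cluster(s) with >1 member (recaptures)\n", multi))
  if (nrow(object@conflicts))
    cat(sprintf("  WARNING: %d non-transitive match conflict(s)\n",
                nrow(object@conflicts)))
})

#' Per-locus allele frequencies over unique individuals
#'
#' Allele frequencies estimated from the unique composite genotypes observed
#' (duplicate scats collapsed to one genotype per individual). Per locus only
#' OK genotypes contribute; AMBIGUOUS and MISSING calls are excluded
#' entirely, and each contributing individual adds two allele copies.
#'
#' @slot loci locus names.
#' @slot N named integer: contributing individuals per locus.
#' @slot freqs named list: per locus a named numeric vector allele -> p_i
#'   summing to 1 (empty when N = 0).
#' @slot het named integer: observed heterozygote count per locus.
#' @export
setClass("AlleleFreqTable",
  representation(loci = "character", N = "integer", freqs = "list",
                 het = "integer")
)

setValidity("AlleleFreqTable", function(object) {
  msg <- character()
  for (L in object@loci) {
    p <- object@freqs[[L]]
    if (length(p)) {
      if (abs(sum(p) - 1) > 1e-12)
        msg <- c(msg, sprintf("frequencies at %s do not sum to 1", L))
      if (any(p <= 0))
        msg <- c(msg, sprintf("zero-frequency allele retained at %s", L))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlleleFreqTable", function(object) {
  cat(sprintf("AlleleFreqTable: %d loci\n", length(object@loci)))
  for (L in object@loci)
    cat(sprintf("  %s: N=%d, %d alleles\n", L, object@N[[L]],
                length(object@freqs[[L]])))
})

#' Parameters of the synthetic scat-survey simulator
#'
#' Defaults reproduce the statistical structure of a small Himalayan
#' snow-leopard survey: 9 individuals genotyped at a 6-locus microsatellite
#' panel with observed allele counts (6,4,4,3,4,2), scats collected with a
#' high off-target (non-target-species) fraction, and triplicate PCR with
#' amplification failure, allelic dropout and occasional false alleles
#' typical of degraded fecal DNA.
#'
#' @slot n_individuals number of individuals in the population.
#' @slot sex_ratio probability an individual is male.
#' @slot n_loci number of microsatellite loci.
#' @slot alleles_per_locus integer vector (recycled to \code{n_loci}).
#' @slot freq_concentration symmetric Dirichlet concentration for allele
#'   frequencies.
#' @slot scats_per_individual Poisson mean number of scats deposited per
#'   individual (used when \code{n_scats} is NA).
#' @slot n_scats fixed total number of collected scats, or NA to draw
#'   per-individual Poisson counts.
#' @slot offtarget_fraction probability a collected scat is from a non-target
#'   species.
#' @slot offtarget_carnivore_p probability an off-target scat is from another
#'   carnivore (amplifies in the carnivore assay).
#' @slot dropout_rate per-allele per-replicate dropout probability.
#' @slot false_allele_rate per-replicate probability of inserting a false
#'   allele.
#' @slot failure_rate per-replicate wholesale amplification-failure
#'   probability.
#' @slot n_replicates PCR replicates per assay and per locus.
#' @slot seed RNG seed; identical seed implies identical output.
#' @seealso [simulatePopulation()], [simulateScats()], [recoveryExperiment()]
#' @export
setClass("SimParams",
  representation(
    n_individuals = "integer", sex_ratio = "numeric", n_loci = "integer",
    alleles_per_locus = "integer", freq_concentration = "numeric",
    scats_per_individual = "numeric", n_scats = "integer",
    offtarget_fraction = "numeric", offtarget_carnivore_p = "numeric",
    dropout_rate = "numeric", false_allele_rate = "numeric",
    failure_rate = "numeric", n_replicates = "integer", seed = "integer"
  ),
  prototype(
    n_individuals = 9L, sex_ratio = 0.5, n_loci = 6L,
    alleles_per_locus = c(6L, 4L, 4L, 3L, 4L, 2L), freq_concentration = 1.0,
    scats_per_individual = 2.1, n_scats = NA_integer_,
    offtarget_fraction = 0.73, offtarget_carnivore_p = 30 / 52,
    dropout_rate = 0.2, false_allele_rate = 0.05, failure_rate = 0.3,
    n_replicates = 3L, seed = 1L
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  pr <- c(sex_ratio = object@sex_ratio,
          offtarget_fraction = object@offtarget_fraction,
          offtarget_carnivore_p = object@offtarget_carnivore_p,
          dropout_rate = object@dropout_rate,
          false_allele_rate = object@false_allele_rate,
          failure_rate = object@failure_rate)
  bad <- names(pr)[pr < 0 | pr > 1]
  if (length(bad))
    msg <- c(msg, sprintf("probabilities outside [0,1]: %s",
                          paste(bad, collapse = ", ")))
  if (object@n_individuals < 1L) msg <- c(msg, "n_individuals must be >= 1")
  if (object@n_loci < 1L) msg <- c(msg, "n_loci must be >= 1")
  if (any(object@alleles_per_locus < 1L))
    msg <- c(msg, "alleles_per_locus must be >= 1")
  if (object@n_replicates < 1L) msg <- c(msg, "n_replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct simulator parameters
#'
#' @param ... slot values overriding the defaults documented in
#'   [SimParams-class].
#' @return A validated [SimParams-class] object.
#' @examples
#' SimParams(n_individuals = 10, n_scats = 30, offtarget_fraction = 0,
#'           dropout_rate = 0, failure_rate = 0, false_allele_rate = 0)
#' @export
SimParams <- function(...) {
  args <- list(...)
  int_slots <- c("n_individuals", "n_loci", "alleles_per_locus", "n_scats",
                 "n_replicates", "seed")
  for (s in intersect(names(args), int_slots))
    args[[s]] <- as.integer(args[[s]])
  do.call(new, c("SimParams", args))
}

setMethod("show", "SimParams", function(object) {
  cat(sprintf(paste0(
    "SimParams: %d individuals, %d loci (Na: %s), Dirichlet conc %.2g\n",
    "  scats: %s, off-target %.2f; errors: dropout %.2f, failure %.2f, ",
    "false allele %.2f; %d replicates; seed %d\n"),
    object@n_individuals, object@n_loci,
    paste(object@alleles_per_locus, collapse = ","),
    object@freq_concentration,
    if (is.na(object@n_scats)) sprintf("Pois(%.2g)/individual",
                                       object@scats_per_individual)
    else sprintf("%d total", object@n_scats),
    object@offtarget_fraction, object@dropout_rate, object@failure_rate,
    object@false_allele_rate, object@n_replicates, object@seed))
})
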
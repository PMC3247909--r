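#' @include AllClasses.R
NULL

#' Simulate a target population with known genotypes
#'
#' Draws the ground truth of a synthetic survey: per-locus allele
#' frequencies from a symmetric Dirichlet, multilocus genotypes per
#' individual independently under Hardy-Weinberg equilibrium (loci
#' independent, no null alleles), and sexes as Bernoulli draws. Allele sizes
#' are spaced 2 bp apart per locus, mimicking dinucleotide microsatellites.
#' Deterministic under \code{params@seed}.
#'
#' @param params a [SimParams-class].
#' @return list with \code{individuals} (data.frame id, sex), \code{loci},
#'   \code{freqs} (named list of named frequency vectors), \code{genotypes}
#'   (named list: per locus an n x 2 integer allele matrix), \code{params}.
#' @export
simulatePopulation <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  set.seed(params@seed)
  n <- params@n_individuals
  na <- rep(params@alleles_per_locus, length.out = params@n_loci)
  loci <- sprintf("L%02d", seq_len(params@n_loci))
  freqs <- stats::setNames(lapply(seq_along(loci), function(i) {
    sizes <- 100L + 2L * (seq_len(na[i]) - 1L)
    g <- stats::rgamma(na[i], shape = params@freq_concentration)
    if (sum(g) == 0) g <- rep(1, na[i])
    stats::setNames(g / sum(g), sizes)
  }), loci)
  genotypes <- stats::setNames(lapply(loci, function(L) {
    p <- freqs[[L]]
    sizes <- as.integer(names(p))
    matrix(sample(sizes, 2L * n, replace = TRUE, prob = p), ncol = 2L)
  }), loci)
  individuals <- data.frame(
    id = sprintf("I%03d", seq_len(n)),
    sex = ifelse(stats::rbinom(n, 1L, params@sex_ratio) == 1L,
                 "MALE", "FEMALE"),
    stringsAsFactors = FALSE)
  list(individuals = individuals, loci = loci, freqs = freqs,
       genotypes = genotypes, params = params)
}

.sim_replicate_obs <- function(true_pair, amp_ok, locus_sizes, params) {
  if (!amp_ok) return(integer())
  kept <- true_pair[stats::runif(2L) >= params@dropout_rate]
  kept <- unique(kept)
  if (stats::runif(1L) < params@false_allele_rate) {
    # false alleles arise near real alleles (+-2 bp), stressing exact-match
    # clustering realistically
    pool <- unique(c(locus_sizes, locus_sizes + 2L, locus_sizes - 2L))
    fa <- sample(pool, 1L)
    obs <- unique(c(kept, fa))
    # a gel/trace is scored as at most two alleles; a false peak can mask a
    # true one
    if (length(obs) > 2L) obs <- sample(obs, 2L)
    return(sort(obs))
  }
  sort(kept)
}

#' Simulate scat collection and replicate-level observations
#'
#' Deposits scats over the simulated population and generates the
#' replicate-level data the laboratory would see. Each collected scat is
#' off-target (non-target species) with probability
#' \code{offtarget_fraction}, otherwise it is assigned to an individual.
#' Template amplifiability is drawn once per scat and replicate and shared
#' by all assays of that replicate, so a species-positive scat is always
#' carnivore-positive (the species target is nested within carnivores).
#' Off-target scats amplify in the carnivore assay with probability
#' \code{offtarget_carnivore_p} (per amplifiable replicate) and never in the
#' species assay. The Y assay yields a band on amplifiable male replicates
#' with probability \code{1 - dropout_rate}; females never yield it.
#' Microsatellite replicates of target scats suffer wholesale amplification
#' failure, per-allele dropout and occasional false alleles; off-target
#' scats are not genotyped.
#'
#' @param truth output of [simulatePopulation()].
#' @param params the same [SimParams-class].
#' @return list with \code{samples} (named list of [SampleRecord-class]) and
#'   \code{truth_map} (data.frame: sample_id, owner, is_target,
#'   is_carnivore, sex).
#' @export
simulateScats <- function(truth, params) {
  stopifnot(is(params, "SimParams"))
  set.seed(params@seed + 1L)
  n_ind <- params@n_individuals
  f <- params@offtarget_fraction
  if (!is.na(params@n_scats)) {
    n_scats <- params@n_scats
    off <- stats::runif(n_scats) < f
    owner <- ifelse(off, NA_integer_,
                    sample.int(n_ind, n_scats, replace = TRUE))
  } else {
    stopifnot(f < 1)
    per_ind <- stats::rpois(n_ind, params@scats_per_individual)
    owner <- rep(seq_len(n_ind), per_ind)
    n_off <- stats::rpois(1L, sum(per_ind) * f / (1 - f))
    owner <- c(owner, rep(NA_integer_, n_off))
    n_scats <- length(owner)
    off <- is.na(owner)
  }
  nrep <- params@n_replicates
  ids <- sprintf("S%04d", seq_len(n_scats))
  is_carn <- ifelse(off, stats::runif(n_scats) < params@offtarget_carnivore_p,
                    TRUE)
  samples <- vector("list", n_scats)
  for (s in seq_len(n_scats)) {
    amp <- stats::runif(nrep) >= params@failure_rate
    target <- !off[s]
    sexs <- if (target) truth$individuals$sex[owner[s]] else NA_character_
    ctrl <- rep(TRUE, nrep)
    assays <- list(
      carnivore = data.frame(band = amp & is_carn[s],
                             pos_ctrl_ok = ctrl, neg_ctrl_ok = ctrl),
      species = data.frame(band = amp & target,
                           pos_ctrl_ok = ctrl, neg_ctrl_ok = ctrl),
      sex = data.frame(
        band = if (target && identical(sexs, "MALE"))
          amp & (stats::runif(nrep) >= params@dropout_rate)
        else rep(FALSE, nrep),
        pos_ctrl_ok = ctrl, neg_ctrl_ok = ctrl))
    genotypes <- list()
    if (target) {
      genotypes <- stats::setNames(lapply(truth$loci, function(L) {
        pair <- truth$genotypes[[L]][owner[s], ]
        sizes <- as.integer(names(truth$freqs[[L]]))
        g_amp <- stats::runif(nrep) >= params@failure_rate
        lapply(seq_len(nrep), function(r)
          .sim_replicate_obs(pair, g_amp[r], sizes, params))
      }), truth$loci)
    }
    samples[[s]] <- new("SampleRecord", sample_id = ids[s], site = "SIM",
                        region = "SIM", year = 2009L,
                        assays = assays, genotypes = genotypes)
  }
  truth_map <- data.frame(
    sample_id = ids,
    owner = ifelse(off, NA_character_, truth$individuals$id[owner]),
    is_target = !off, is_carnivore = is_carn,
    sex = ifelse(off, NA_character_, truth$individuals$sex[owner]),
    stringsAsFactors = FALSE)
  list(samples = stats::setNames(samples, ids), truth_map = truth_map)
}

#' Write a simulated survey in the pipeline's CSV formats
#'
#' Emits the replicate-level assay sample sheet and microsatellite replicate
#' table exactly as [readSampleSheet()] and [readGenotypeReplicates()]
#' expect, plus a ground-truth JSON for scoring.
#'
#' @param sim output of [simulateScats()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
writeSurveyCSV <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- do.call(rbind, lapply(sim$samples, function(s)
    do.call(rbind, lapply(names(s@assays), function(a) {
      df <- s@assays[[a]]
      data.frame(sample_id = s@sample_id, site = s@site, region = s@region,
                 year = s@year, assay = a, replicate = seq_len(nrow(df)),
                 band = df$band, pos_ctrl_ok = df$pos_ctrl_ok,
                 neg_ctrl_ok = df$neg_ctrl_ok)
    }))))
  reps <- do.call(rbind, lapply(sim$samples, function(s) {
    if (!length(s@genotypes)) return(NULL)
    do.call(rbind, lapply(names(s@genotypes), function(L) {
      obs <- s@genotypes[[L]]
      data.frame(sample_id = s@sample_id, locus = L,
                 replicate = seq_along(obs),
                 allele1 = vapply(obs, function(o)
                   if (length(o) >= 1L) as.character(o[1L]) else "",
                   character(1)),
                 allele2 = vapply(obs, function(o)
                   if (length(o) == 2L) as.character(o[2L])
                   else if (length(o) == 1L) as.character(o[1L]) else "",
                   character(1)))
    }))
  }))
  paths <- c(sample_sheet = file.path(dir, "sample_sheet.csv"),
             genotype_replicates = file.path(dir, "genotype_replicates.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(sheet, paths[["sample_sheet"]], row.names = FALSE)
  utils::write.csv(reps, paths[["genotype_replicates"]], row.names = FALSE)
  jsonlite::write_json(sim$truth_map, paths[["truth"]], dataframe = "rows")
  invisible(paths)
}

#' Recovery experiment: how well does the pipeline recover known truth?
#'
#' Runs the full pipeline (species calls, consensus genotyping, clustering)
#' over repeated simulated surveys and scores recovery against ground truth.
#' The recovered individual count includes only clusters supported by
#' evidence (unresolved singletons — isolated merely for lack of comparable
#' loci — are withheld), and is compared against the number of distinct
#' individuals that actually deposited a species-positive scat (an
#' individual leaving no scat is undetectable by any method). A false merge
#' is a cluster mixing two true individuals; a false split is a true
#' individual spread over several clusters.
#'
#' @param params a [SimParams-class]; per-run seeds are derived from
#'   \code{params@seed}.
#' @param n_runs number of independent surveys.
#' @param min_support consensus threshold ([consensusLocus()]).
#' @param min_shared matching threshold ([clusterIndividuals()]).
#' @return list with \code{runs} (per-run data.frame: detected, recovered,
#'   false_merge, false_split) and \code{summary} (mean recovered vs
#'   detected, bias, RMSE, exact-recovery fraction, false-merge and
#'   false-split rates).
#' @export
recoveryExperiment <- function(params, n_runs, min_support = 2L,
                               min_shared = 4L) {
  stopifnot(is(params, "SimParams"))
  if (n_runs < 1L) stop("n_runs must be >= 1")
  one <- function(r) {
    p <- params
    p@seed <- params@seed + 2L * r
    truth <- simulatePopulation(p)
    sim <- simulateScats(truth, p)
    sp_pos <- vapply(sim$samples, function(s)
      callAssay(s@assays$species)$call == "POSITIVE", logical(1))
    det <- length(unique(stats::na.omit(sim$truth_map$owner[sp_pos])))
    if (!any(sp_pos))
      return(data.frame(detected = 0L, recovered = 0L,
                        false_merge = FALSE, false_split = FALSE))
    gt <- consensusTable(sim$samples[sp_pos], truth$loci, min_support)
    cl <- suppressWarnings(clusterIndividuals(gt, min_shared = min_shared))
    owners <- stats::setNames(sim$truth_map$owner, sim$truth_map$sample_id)
    counted <- Filter(function(c1) !isTRUE(c1$unresolved), cl@clusters)
    rec <- length(counted)
    fmerge <- any(vapply(cl@clusters, function(c1)
      length(unique(stats::na.omit(owners[c1$members]))) > 1L, logical(1)))
    memb_cl <- rep(seq_along(cl@clusters),
                   vapply(cl@clusters, function(c1) length(c1$members),
                          integer(1)))
    memb_owner <- owners[unlist(lapply(cl@clusters, `[[`, "members"))]
    fsplit <- any(vapply(split(memb_cl, memb_owner),
                         function(v) length(unique(v)) > 1L, logical(1)))
    data.frame(detected = det, recovered = rec,
               false_merge = fmerge, false_split = fsplit)
  }
  runs <- do.call(rbind, lapply(seq_len(n_runs), one))
  list(runs = runs,
       summary = list(
         mean_detected = mean(runs$detected),
         mean_recovered = mean(runs$recovered),
         bias = mean(runs$recovered - runs$detected),
         rmse = sqrt(mean((runs$recovered - runs$detected)^2)),
         exact_fraction = mean(runs$recovered == runs$detected),
         false_merge_rate = mean(runs$false_merge),
         false_split_rate = mean(runs$false_split)))
}
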
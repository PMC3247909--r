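test_that("simulation is byte-deterministic under a fixed seed", {
  p <- SimParams(seed = 123L, n_individuals = 5L, n_scats = 20L)
  t1 <- simulatePopulation(p); t2 <- simulatePopulation(p)
  expect_identical(t1, t2)
  s1 <- simulateScats(t1, p); s2 <- simulateScats(t2, p)
  expect_identical(s1, s2)
  r1 <- recoveryExperiment(p, n_runs = 2L)
  r2 <- recoveryExperiment(p, n_runs = 2L)
  expect_identical(r1, r2)
})

test_that("parameter validation rejects impossible settings", {
  expect_error(SimParams(dropout_rate = 1.5), "probabilities")
  expect_error(SimParams(alleles_per_locus = 0), "alleles_per_locus")
  expect_error(recoveryExperiment(SimParams(), n_runs = 0L), "n_runs")
})

test_that("a huge Dirichlet concentration gives near-equifrequent alleles", {
  p <- SimParams(n_loci = 1L, alleles_per_locus = 2L,
                 freq_concentration = 1e7, seed = 4L)
  truth <- simulatePopulation(p)
  expect_equal(unname(truth$freqs$L01), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("with every error rate at zero the pipeline recovers truth exactly", {
  p <- SimParams(n_individuals = 8L, n_scats = 25L, offtarget_fraction = 0,
                 dropout_rate = 0, failure_rate = 0, false_allele_rate = 0,
                 seed = 77L)
  truth <- simulatePopulation(p)
  sim <- simulateScats(truth, p)
  gt <- consensusTable(sim$samples, truth$loci)
  # every consensus composite equals the owner's true genotype
  comps <- composites(gt)
  for (id in names(comps)) {
    owner <- match(sim$truth_map$owner[sim$truth_map$sample_id == id],
                   truth$individuals$id)
    for (L in truth$loci) {
      expect_equal(gtStatus(comps[[id]][[L]]), "OK")
      expect_equal(gtAlleles(comps[[id]][[L]]),
                   sort(truth$genotypes[[L]][owner, ]))
    }
  }
  cl <- suppressWarnings(clusterIndividuals(gt))
  detected <- length(unique(sim$truth_map$owner))
  expect_length(clusters(cl), detected)
})

test_that("species-positive scats are always carnivore-positive (nested target)", {
  p <- SimParams(n_individuals = 6L, n_scats = 80L, seed = 9L)
  sim <- simulateScats(simulatePopulation(p), p)
  calls <- t(vapply(sim$samples, function(s)
    c(sp = callAssay(s@assays$species)$call,
      ca = callAssay(s@assays$carnivore)$call), character(2)))
  sp_pos <- calls[, "sp"] == "POSITIVE"
  expect_true(any(sp_pos))
  expect_true(all(calls[sp_pos, "ca"] == "POSITIVE"))
})

test_that("the off-target fraction sets the expected species-positive yield", {
  # composition matched to a 71-scat survey with 27% target scats
  p <- SimParams(n_scats = 71L, offtarget_fraction = 0.73,
                 failure_rate = 0, seed = 1L)
  n_pos <- vapply(1:20, function(r) {
    pr <- p; pr@seed <- 1000L + r
    sim <- simulateScats(simulatePopulation(pr), pr)
    sum(vapply(sim$samples, function(s)
      callAssay(s@assays$species)$call == "POSITIVE", logical(1)))
  }, numeric(1))
  mu <- 71 * 0.27
  se <- sqrt(71 * 0.27 * 0.73 / 20)
  expect_lt(abs(mean(n_pos) - mu), 3 * se)
})

test_that("dropout depresses raw single-replicate heterozygosity", {
  p <- SimParams(n_individuals = 20L, n_scats = 120L, offtarget_fraction = 0,
                 dropout_rate = 0.3, failure_rate = 0,
                 false_allele_rate = 0, seed = 21L)
  truth <- simulatePopulation(p)
  sim <- simulateScats(truth, p)
  owner_of <- stats::setNames(match(sim$truth_map$owner,
                                    truth$individuals$id),
                              sim$truth_map$sample_id)
  n_het_obs <- 0L; n_obs <- 0L
  for (id in names(sim$samples)) {
    s <- sim$samples[[id]]
    for (L in truth$loci) {
      pair <- truth$genotypes[[L]][owner_of[[id]], ]
      if (pair[1] == pair[2]) next
      for (o in s@genotypes[[L]]) {
        if (!length(o)) next
        n_obs <- n_obs + 1L
        if (length(o) == 2L) n_het_obs <- n_het_obs + 1L
      }
    }
  }
  # among non-failed replicates of true heterozygotes, both alleles survive
  # with probability (1-d)^2 / (1-d^2) = (1-d)/(1+d)
  d <- 0.3
  p_het <- (1 - d) / (1 + d)
  se <- sqrt(p_het * (1 - p_het) / n_obs)
  expect_lt(abs(n_het_obs / n_obs - p_het), 3 * se)
  expect_lt(n_het_obs / n_obs, 1)   # systematic deficit
})

test_that("realized genotype frequencies converge to the drawn frequencies", {
  dev_at <- function(n) {
    p <- SimParams(n_individuals = n, n_loci = 1L, alleles_per_locus = 6L,
                   seed = 13L)
    truth <- simulatePopulation(p)
    realized <- table(factor(truth$genotypes$L01,
                             levels = names(truth$freqs$L01))) / (2 * n)
    max(abs(as.numeric(realized) - truth$freqs$L01))
  }
  expect_lt(dev_at(5000L), dev_at(50L))
})

test_that("simulated surveys round-trip through the CSV formats", {
  p <- SimParams(n_individuals = 5L, n_scats = 15L, seed = 55L)
  truth <- simulatePopulation(p)
  sim <- simulateScats(truth, p)
  dir <- withr::local_tempdir()
  paths <- writeSurveyCSV(sim, dir)
  expect_true(all(file.exists(paths)))
  samples <- readSampleSheet(paths[["sample_sheet"]])
  expect_length(samples, length(sim$samples))
  reps <- readGenotypeReplicates(paths[["genotype_replicates"]])
  samples <- attachGenotypeReplicates(samples, reps)
  for (id in names(reps)) {
    got <- consensusSample(samples[[id]], truth$loci)$genotypes
    want <- consensusSample(sim$samples[[id]], truth$loci)$genotypes
    for (L in truth$loci) {
      expect_equal(gtStatus(got[[L]]), gtStatus(want[[L]]))
      expect_equal(gtAlleles(got[[L]]), gtAlleles(want[[L]]))
    }
  }
})

test_that("recovery experiment reports coherent per-run scores", {
  p <- SimParams(n_individuals = 6L, n_scats = 20L, offtarget_fraction = 0,
                 dropout_rate = 0, failure_rate = 0, false_allele_rate = 0,
                 seed = 100L)
  rec <- recoveryExperiment(p, n_runs = 5L)
  expect_equal(nrow(rec$runs), 5L)
  expect_true(all(rec$runs$recovered >= 0))
  expect_equal(rec$summary$exact_fraction,
               mean(rec$runs$recovered == rec$runs$detected))
  # heavy amplification failure loses loci to MISSING; the resulting
  # unresolved splits are withheld, so the count can only shrink
  ph <- SimParams(n_individuals = 6L, n_scats = 20L, offtarget_fraction = 0,
                  dropout_rate = 0, failure_rate = 0.6,
                  false_allele_rate = 0, seed = 200L)
  rech <- recoveryExperiment(ph, n_runs = 20L)
  expect_lte(rech$summary$mean_recovered, rech$summary$mean_detected)
})
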
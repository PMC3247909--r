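test_that("the match predicate compares only co-typed unambiguous loci", {
  gt <- survey_gt()
  comps <- composites(gt)
  expect_equal(genotypesMatch(comps$SL54, comps$SL55), "MATCH")
  expect_equal(genotypesMatch(comps$SL49, comps$SL57), "MISMATCH")
  # the sample missing/ambiguous at three loci shares too few with anyone
  # it does not contradict
  mk <- function(pairs) setNames(lapply(names(pairs), function(L)
    if (is.null(pairs[[L]])) LocusGenotype(L, status = "MISSING")
    else LocusGenotype(L, as.integer(pairs[[L]]))), names(pairs))
  a <- mk(list(L1 = c(1, 2), L2 = c(3, 4), L3 = c(5, 6), L4 = NULL,
               L5 = NULL, L6 = NULL))
  b <- mk(list(L1 = c(1, 2), L2 = c(3, 4), L3 = c(5, 6), L4 = c(7, 8),
               L5 = c(9, 10), L6 = c(11, 12)))
  expect_equal(genotypesMatch(a, b), "UNRESOLVED")
  expect_equal(genotypesMatch(a, b, min_shared = 3L), "MATCH")
  # allele pairs compare unordered
  a2 <- mk(list(L1 = c(2, 1), L2 = c(4, 3), L3 = c(6, 5), L4 = c(8, 7),
                L5 = c(10, 9), L6 = c(12, 11)))
  expect_equal(genotypesMatch(a2, b), "MATCH")
  expect_error(genotypesMatch(setNames(a, paste0("X", 1:6)), b), "disjoint")
})

test_that("clustering the packaged table recovers the survey's individuals", {
  gt <- survey_gt()
  cl <- clusterIndividuals(gt)
  expect_length(clusters(cl), 9L)
  sizes <- vapply(clusters(cl), function(c1) length(c1$members), integer(1))
  expect_equal(sum(sizes == 2L), 1L)
  two <- clusters(cl)[[which(sizes == 2L)]]
  expect_setequal(two$members, c("SL54", "SL55"))
  site_of <- vapply(clusters(cl), function(c1) c1$sites$site[1L],
                    character(1))
  expect_equal(sum(site_of == "SPNP"), 4L)
  expect_equal(sum(site_of == "KCA"), 5L)
  expect_equal(nrow(cl@conflicts), 0L)
})

test_that("identical composites collapse to one cluster; clustering is idempotent", {
  gt <- survey_gt()
  comps <- composites(gt)
  same <- setNames(rep(comps["SL49"], 10), paste0("s", 1:10))
  expect_length(clusters(clusterIndividuals(same)), 1L)
  # re-clustering the cluster consensus composites yields the same partition
  cl <- clusterIndividuals(gt)
  cl2 <- clusterIndividuals(composites(cl))
  expect_length(clusters(cl2), length(clusters(cl)))
  expect_equal(vapply(clusters(cl2), function(c1) length(c1$members),
                      integer(1)), rep(1L, 9L))
})

test_that("cluster count is invariant to input order when matches are transitive", {
  gt <- survey_gt()
  comps <- composites(gt)
  set.seed(5)
  for (i in 1:10) {
    per <- comps[sample(length(comps))]
    cl <- clusterIndividuals(per)
    expect_length(clusters(cl), 9L)
    expect_equal(nrow(cl@conflicts), 0L)
  }
})

test_that("non-transitive matches are clustered by first link and reported", {
  mk6 <- function(...) {
    pairs <- list(...)
    setNames(lapply(seq_along(pairs), function(i)
      if (is.null(pairs[[i]]))
        LocusGenotype(paste0("L", i), status = "MISSING")
      else LocusGenotype(paste0("L", i), as.integer(pairs[[i]]))),
      paste0("L", seq_along(pairs)))
  }
  # A matches B (loci 1-4), B matches C (loci 1-3 and 6), but A and C
  # conflict at locus 5 where B is untyped: an intransitive triple
  A <- mk6(c(1, 1), c(2, 2), c(3, 3), c(4, 4), c(5, 5), NULL)
  B <- mk6(c(1, 1), c(2, 2), c(3, 3), c(4, 4), NULL, c(7, 7))
  C <- mk6(c(1, 1), c(2, 2), c(3, 3), NULL, c(9, 9), c(7, 7))
  expect_equal(genotypesMatch(A, B), "MATCH")
  expect_equal(genotypesMatch(B, C), "MATCH")
  expect_equal(genotypesMatch(A, C), "MISMATCH")
  expect_warning(cl <- clusterIndividuals(list(a = A, b = B, c = C)),
                 "non-transitive")
  expect_length(clusters(cl), 2L)   # first-link rule: {a,b}, {c}
  expect_equal(nrow(cl@conflicts), 1L)
})

test_that("sex attribution is unanimous per cluster, with conflicts flagged", {
  gt <- survey_gt()
  cl <- attachSex(clusterIndividuals(gt), survey_sex_calls_map())
  tly <- sexTally(cl)
  expect_equal(unname(tly["MALE"]), 3L)
  expect_equal(unname(tly["FEMALE"]), 6L)
  by_site <- sexTally(cl, by_site = TRUE)
  expect_equal(unname(by_site["SPNP", "MALE"]), 1L)
  expect_equal(unname(by_site["KCA", "MALE"]), 2L)
  # conflicting members force UNKNOWN with a warning
  bad <- survey_sex_calls_map()
  bad["SL55"] <- "MALE"
  expect_warning(clb <- attachSex(clusterIndividuals(gt), bad),
                 "conflicting")
  expect_equal(unname(sexTally(clb)["UNKNOWN"]), 1L)
})

test_that("match support is the product of sibling PID over compared loci", {
  gt <- survey_gt()
  cl <- clusterIndividuals(gt)
  st <- locusStatsTable(alleleFrequencies(cl))
  pid_map <- setNames(st$pid_sib, st$locus)
  ms <- matchSupport(cl, pid_map)
  expect_equal(nrow(ms), 1L)
  expect_equal(ms$n_loci_compared, 6L)
  # independent hand multiplication of the six per-locus values
  expect_equal(ms$p_chance_identity, prod(pid_map), tolerance = 1e-12)
  expect_equal(ms$p_chance_identity, 0.01791216, tolerance = 1e-6)
  # halving one per-locus PID halves the product
  half <- pid_map; half["PUN124"] <- half["PUN124"] / 2
  expect_equal(matchSupport(cl, half)$p_chance_identity,
               ms$p_chance_identity / 2)
  expect_error(matchSupport(cl, pid_map[-1]), "absent")
  # empty product convention: a cluster compared at no loci has support 1
  blank <- setNames(lapply(names(pid_map), function(L)
    LocusGenotype(L, status = "MISSING")), names(pid_map))
  fake <- new("IndividualClusters", clusters = list(list(
    individual_id = 1L, members = c("x", "y"),
    composite = blank, member_composites = list(blank, blank),
    sex = NA_character_,
    sites = data.frame(site = "X", region = "Y", year = 2008L),
    unresolved = TRUE)), min_shared = 4L,
    conflicts = data.frame())
  expect_equal(matchSupport(fake, pid_map)$p_chance_identity, 1)
})
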
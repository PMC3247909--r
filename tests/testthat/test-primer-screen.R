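test_that("an alignment with no divergence yields no diagnostic sites", {
  aln <- c(target = strrep("ACGT", 15), off = strrep("ACGT", 15))
  expect_equal(nrow(scanDiagnosticSites(aln, "target", k = 20)), 0L)
})

test_that("target-unique bases at the 3' end produce a forward site", {
  base <- strrep("A", 30)
  tgt <- base
  substr(tgt, 19, 20) <- "GG"   # two unique bases at columns 19-20
  aln <- c(target = tgt, off1 = base, off2 = base)
  hits <- scanDiagnosticSites(aln, "target", k = 20, window3 = 5, min3 = 2,
                              strand = "forward")
  expect_true(0 %in% hits$start)
  h0 <- hits[hits$start == 0, ]
  expect_equal(h0$min_3prime_mismatches, 2)
  expect_equal(h0$min_total_mismatches, 2)
})

test_that("scan agrees with the brute-force re-scorer on random alignments", {
  set.seed(42)
  for (rep in 1:5) {
    aln <- random_alignment(3, 200, divergence = 0.12)
    for (sdir in c("forward", "reverse")) {
      got <- scanDiagnosticSites(aln, "target", k = 20, window3 = 5,
                                 min3 = 2, min_total = 5, strand = sdir)
      want <- brute_scan(aln, "target", 20, 5, 2, 5, sdir)
      expect_equal(got$start, want$start)
      expect_equal(got$min_3prime_mismatches, want$min_3prime_mismatches)
      expect_equal(got$min_total_mismatches, want$min_total_mismatches)
    }
  }
})

test_that("stricter mismatch thresholds never add sites", {
  set.seed(11)
  aln <- random_alignment(4, 300, divergence = 0.15)
  n_fwd <- vapply(1:4, function(m)
    nrow(scanDiagnosticSites(aln, "target", min3 = m, strand = "forward")),
    integer(1))
  n_rev <- vapply(3:8, function(m)
    nrow(scanDiagnosticSites(aln, "target", min_total = m,
                             strand = "reverse")), integer(1))
  expect_true(all(diff(n_fwd) <= 0))
  expect_true(all(diff(n_rev) <= 0))
})

test_that("reverse-complementing the alignment mirrors site coordinates", {
  set.seed(3)
  aln <- random_alignment(3, 150, divergence = 0.12)
  rc <- vapply(aln, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  k <- 20L; L <- 150L
  # with thresholds at zero every window is reported, so the per-window
  # mismatch statistics themselves must mirror
  fwd <- scanDiagnosticSites(aln, "target", k = k, min3 = 0, min_total = 0,
                             strand = "forward")
  rev_on_rc <- scanDiagnosticSites(rc, "target", k = k, min3 = 0,
                                   min_total = 0, strand = "reverse")
  m <- match(L - k - fwd$start, rev_on_rc$start)
  expect_false(anyNA(m))
  expect_equal(rev_on_rc$min_3prime_mismatches[m], fwd$min_3prime_mismatches)
  expect_equal(rev_on_rc$min_total_mismatches[m], fwd$min_total_mismatches)
})

test_that("gaps and Ns in the target window disqualify the site", {
  tgt <- paste0(strrep("A", 10), "-", strrep("A", 19))
  off <- strrep("C", 30)
  hits <- scanDiagnosticSites(c(target = tgt, off = off), "target", k = 20,
                              strand = "forward")
  # every 20-mer window overlaps the gap at column 11 except none (length 30)
  expect_equal(nrow(hits), 0L)
})

test_that("amplicon lengths count ungapped target bases between primer ends", {
  aln <- c(t = strrep("ACGT", 40), o = strrep("TGCA", 40))
  # 20-mer, 110-base spacer, 20-mer: 150 bp amplicon
  expect_equal(ampliconForPair(aln, "t", list(start = 0, k = 20),
                               list(start = 130, k = 20)), 150L)
  # gaps in the spacer are excluded from the length
  gapped <- paste0(strrep("A", 60), strrep("-", 10), strrep("A", 100))
  aln2 <- c(t = gapped, o = strrep("C", 170))
  expect_equal(ampliconForPair(aln2, "t", list(start = 0, k = 20),
                               list(start = 140, k = 20)), 150L)
  expect_error(ampliconForPair(aln, "t", list(start = 100, k = 20),
                               list(start = 50, k = 20)), "inverted")
  expect_error(ampliconForPair(aln, "t", list(start = 0, k = 20),
                               list(start = 10, k = 20)), "overlap")
})

test_that("the packaged synthetic alignment contains the engineered assay design", {
  aln <- readAlignmentFasta(scatidExample("synthetic_cytb_alignment.fasta"))
  fwd <- scanDiagnosticSites(aln, "snow_leopard_synthetic",
                             strand = "forward")
  rev <- scanDiagnosticSites(aln, "snow_leopard_synthetic",
                             strand = "reverse")
  expect_true(40 %in% fwd$start)
  expect_true(190 %in% rev$start)
  expect_equal(ampliconForPair(aln, "snow_leopard_synthetic",
                               list(start = 40, k = 20),
                               list(start = 190, k = 20)), 170L)
})
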
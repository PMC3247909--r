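# shared fixtures and independent oracles

survey_gt <- function()
  readGenotypeTable(scatidExample("survey_genotypes.csv"))

survey_sex_calls_map <- function() {
  sx <- utils::read.csv(scatidExample("survey_sex_calls.csv"),
                        stringsAsFactors = FALSE)
  stats::setNames(toupper(sx$sex), sx$sample_id)
}

survey_sheet <- function()
  readSampleSheet(scatidExample("survey_sample_sheet.csv"))

assay_reps <- function(bands, pos = TRUE, neg = TRUE) {
  n <- length(bands)
  data.frame(band = bands, pos_ctrl_ok = rep(pos, length.out = n),
             neg_ctrl_ok = rep(neg, length.out = n))
}

# triplicate observations whose 2-of-3 consensus reproduces a given call
reps_for_call <- function(g) {
  switch(gtStatus(g),
    OK = {
      a <- gtAlleles(g)
      if (a[1] == a[2]) list(a[1], a[1], a[1])
      else list(a, a, a)
    },
    AMBIGUOUS = {
      cand <- gtCandidates(g)
      confirmed <- cand[length(cand)]
      list(confirmed, confirmed, cand[-length(cand)])
    },
    MISSING = list(integer(), integer(), integer()))
}

# brute-force re-scorer for the diagnostic-site scan: plain loops, no
# rolling sums, shared with nothing in the implementation
brute_scan <- function(aln, target, k, window3, min3, min_total, strand) {
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  tgt <- m[target, ]; off <- m[setdiff(rownames(m), target), , drop = FALSE]
  hits <- NULL
  for (s in 1:(ncol(m) - k + 1)) {
    win <- s:(s + k - 1)
    if (any(tgt[win] %in% c("-", "N"))) next
    w3 <- if (strand == "forward") win[(k - window3 + 1):k]
          else win[1:window3]
    mins3 <- Inf; mint <- Inf
    for (o in rownames(off)) {
      mm <- function(cols) sum(tgt[cols] != off[o, cols] &
                                 off[o, cols] != "N")
      mins3 <- min(mins3, mm(w3)); mint <- min(mint, mm(win))
    }
    keep <- if (strand == "forward") mins3 >= min3 else mint >= min_total
    if (keep)
      hits <- rbind(hits, data.frame(start = s - 1, strand = strand, k = k,
                                     min_3prime_mismatches = mins3,
                                     min_total_mismatches = mint))
  }
  if (is.null(hits))
    hits <- data.frame(start = integer(), strand = character(),
                       k = integer(), min_3prime_mismatches = numeric(),
                       min_total_mismatches = numeric())
  hits
}

random_alignment <- function(n_species, len, divergence = 0.1) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, len, replace = TRUE)
  stats::setNames(vapply(seq_len(n_species), function(i) {
    x <- anc
    idx <- which(stats::runif(len) < divergence)
    x[idx] <- vapply(x[idx], function(b)
      sample(setdiff(bases, b), 1), character(1))
    paste(x, collapse = "")
  }, character(1)), c("target", paste0("off", seq_len(n_species - 1))))
}

# exhaustive genotype-enumeration oracle for PID-unrelated
pid_u_enum <- function(p) {
  k <- length(p); tot <- 0
  for (i in 1:k) for (j in i:k) {
    pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    tot <- tot + pg^2
  }
  tot
}

# Monte-Carlo sibling-pair oracle: Mendelian sampling from random HWE parents
pid_sib_mc <- function(p, n = 200000L) {
  k <- length(p); al <- seq_len(k)
  mom <- matrix(sample(al, 2L * n, TRUE, p), ncol = 2)
  dad <- matrix(sample(al, 2L * n, TRUE, p), ncol = 2)
  pick <- function(m) m[cbind(seq_len(n), sample(1:2, n, TRUE))]
  s1 <- cbind(pick(mom), pick(dad)); s2 <- cbind(pick(mom), pick(dad))
  g1 <- paste(pmin(s1[, 1], s1[, 2]), pmax(s1[, 1], s1[, 2]))
  g2 <- paste(pmin(s2[, 1], s2[, 2]), pmax(s2[, 1], s2[, 2]))
  mean(g1 == g2)
}

random_freqs <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}
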
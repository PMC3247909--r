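#' @include AllClasses.R
NULL

#' Compare two composite genotypes
#'
#' Pairwise match predicate for individual identification. Only loci where
#' both composites carry a confirmed (OK) call are compared; AMBIGUOUS and
#' MISSING loci never are. Allele pairs are compared unordered. Any
#' difference at a compared locus is a MISMATCH; identity at
#' \code{min_shared} or more compared loci is a MATCH; fewer comparable loci
#' than \code{min_shared}, with no difference, is UNRESOLVED (not enough
#' information to unite the samples).
#'
#' @param a,b composite genotypes: named lists locus -> [LocusGenotype-class]
#'   over the same panel.
#' @param min_shared minimum co-typed loci for a MATCH (default 4 of a
#'   6-locus panel).
#' @return "MATCH", "MISMATCH" or "UNRESOLVED".
#' @export
genotypesMatch <- function(a, b, min_shared = 4L) {
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stop("composites have disjoint locus panels")
  n_cmp <- 0L
  for (L in shared) {
    ga <- a[[L]]; gb <- b[[L]]
    if (gtStatus(ga) != "OK" || gtStatus(gb) != "OK") next
    n_cmp <- n_cmp + 1L
    if (!identical(sort(gtAlleles(ga)), sort(gtAlleles(gb))))
      return("MISMATCH")
  }
  if (n_cmp >= min_shared) "MATCH" else "UNRESOLVED"
}

# compact key matrix for fast pairwise comparison: one row per composite,
# one column per locus, "a1/a2" for OK calls and NA otherwise
.key_matrix <- function(comps, loci) {
  t(vapply(comps, function(cl) vapply(loci, function(L) {
    g <- cl[[L]]
    if (!is.null(g) && gtStatus(g) == "OK")
      paste(sort(gtAlleles(g)), collapse = "/")
    else NA_character_
  }, character(1)), character(length(loci))))
}

.match_keys <- function(ka, kb, min_shared) {
  both <- !is.na(ka) & !is.na(kb)
  if (any(ka[both] != kb[both])) "MISMATCH"
  else if (sum(both) >= min_shared) "MATCH" else "UNRESOLVED"
}

.merge_composite <- function(comps, loci) {
  stats::setNames(lapply(loci, function(L) {
    gs <- lapply(comps, `[[`, L)
    st <- vapply(gs, gtStatus, character(1))
    if (any(st == "OK")) {
      # within a MATCH cluster all OK calls at a locus agree
      gs[[which(st == "OK")[1L]]]
    } else if (any(st == "AMBIGUOUS")) {
      LocusGenotype(L, status = "AMBIGUOUS",
                    candidates = unlist(lapply(gs[st == "AMBIGUOUS"],
                                               gtCandidates)))
    } else LocusGenotype(L, status = "MISSING")
  }), loci)
}

#' Cluster scat samples into individuals by genotype identity
#'
#' Greedy agglomeration in input order: each sample joins the first existing
#' cluster whose every member it MATCHes (see [genotypesMatch()]); otherwise
#' it founds a new cluster. UNRESOLVED pairs (too few comparable loci) are
#' kept separate, erring toward splitting; a singleton cluster that at
#' least one other sample could not be distinguished from is flagged
#' \code{unresolved}, so conservative counts can withhold it and report a
#' minimum number of individuals present. After clustering, a
#' transitivity audit recomputes all cross-cluster pairs; any MATCH between
#' members of different clusters (a non-transitive triple) is reported in
#' the \code{conflicts} slot. Deterministic given input order.
#'
#' @param x a [GenotypeTable-class], or a named list of composite genotypes.
#' @param min_shared minimum co-typed loci for a MATCH.
#' @return An [IndividualClusters-class]; individuals are numbered in order
#'   of first appearance.
#' @examples
#' gt <- readGenotypeTable(scatidExample("survey_genotypes.csv"))
#' cl <- clusterIndividuals(gt)
#' cl
#' @export
clusterIndividuals <- function(x, min_shared = 4L) {
  if (is(x, "GenotypeTable")) {
    comps <- composites(x)
    meta <- x@samples
    lc <- x@loci
  } else {
    comps <- x
    stopifnot(!is.null(names(comps)))
    meta <- data.frame(sample_id = names(comps), site = NA_character_,
                       region = NA_character_, year = NA_integer_,
                       stringsAsFactors = FALSE)
    lc <- names(comps[[1L]])
  }
  keys <- .key_matrix(comps, lc)
  n <- length(comps)
  assign <- integer(n)
  cluster_members <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (ci in seq_along(cluster_members)) {
      res <- vapply(cluster_members[[ci]], function(j)
        .match_keys(keys[i, ], keys[j, ], min_shared), character(1))
      if (any(res == "MISMATCH")) next
      if (all(res == "MATCH")) {
        cluster_members[[ci]] <- c(cluster_members[[ci]], i)
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cluster_members[[length(cluster_members) + 1L]] <- i
      assign[i] <- length(cluster_members)
    }
  }
  # full pairwise recount: transitivity audit + unresolved-pair flags
  conflicts <- data.frame(sample_a = character(), sample_b = character(),
                          stringsAsFactors = FALSE)
  ever_unresolved <- logical(n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    res <- .match_keys(keys[i, ], keys[j, ], min_shared)
    if (res == "UNRESOLVED") ever_unresolved[c(i, j)] <- TRUE
    if (res == "MATCH" && assign[i] != assign[j])
      conflicts <- rbind(conflicts, data.frame(
        sample_a = meta$sample_id[i], sample_b = meta$sample_id[j],
        stringsAsFactors = FALSE))
  }
  if (nrow(conflicts))
    warning("non-transitive MATCH relation: ", nrow(conflicts),
            " cross-cluster matching pair(s); see conflicts slot")
  cl_list <- lapply(seq_along(cluster_members), function(ci) {
    idx <- cluster_members[[ci]]
    # a singleton is "unresolved" when some other sample could not be
    # distinguished from it (too few comparable loci): it may not be a
    # distinct individual, so conservative counts withhold it
    unresolved <- length(idx) == 1L && ever_unresolved[idx]
    list(individual_id = ci,
         members = meta$sample_id[idx],
         composite = .merge_composite(comps[idx], lc),
         member_composites = comps[idx],
         sex = NA_character_,
         sites = meta[idx, c("site", "region", "year"), drop = FALSE],
         unresolved = unresolved)
  })
  new("IndividualClusters", clusters = cl_list,
      min_shared = as.integer(min_shared), conflicts = conflicts)
}

#' Attach sex calls to individual clusters
#'
#' Cluster sex is the unanimous sex of its members (UNKNOWN members are
#' uninformative); members conflicting MALE vs FEMALE set the cluster to
#' UNKNOWN with a warning.
#'
#' @param cl an [IndividualClusters-class].
#' @param sample_sex named character vector sample_id -> "MALE" / "FEMALE" /
#'   "UNKNOWN".
#' @return The clusters with \code{sex} filled in.
#' @export
attachSex <- function(cl, sample_sex) {
  stopifnot(is(cl, "IndividualClusters"))
  cl@clusters <- lapply(cl@clusters, function(c1) {
    sx <- unique(sample_sex[c1$members])
    sx <- sx[!is.na(sx) & sx != "UNKNOWN"]
    if (length(sx) == 1L) c1$sex <- sx
    else if (length(sx) > 1L) {
      warning("conflicting sex calls in cluster ", c1$individual_id,
              " (", paste(c1$members, collapse = ","), "): set to UNKNOWN")
      c1$sex <- "UNKNOWN"
    } else c1$sex <- "UNKNOWN"
    c1
  })
  cl
}

#' Sex tally of recovered individuals
#'
#' @param cl an [IndividualClusters-class] after [attachSex()].
#' @param by_site also break the tally down by collection site.
#' @return Named integer vector over MALE/FEMALE/UNKNOWN, or a site x sex
#'   table when \code{by_site}.
#' @export
sexTally <- function(cl, by_site = FALSE) {
  sexes <- vapply(cl@clusters, function(c1)
    if (is.na(c1$sex)) "UNKNOWN" else c1$sex, character(1))
  if (!by_site)
    return(table(factor(sexes, levels = c("MALE", "FEMALE", "UNKNOWN"))))
  sites <- vapply(cl@clusters, function(c1) c1$sites$site[1L], character(1))
  table(sites, factor(sexes, levels = c("MALE", "FEMALE", "UNKNOWN")))
}

#' Chance-identity support for multi-member clusters
#'
#' For each cluster with more than one member, the probability that a full
#' sibling of one member would share the observed composite by chance: the
#' product of per-locus sibling probability-of-identity over the loci
#' actually compared within the cluster (loci OK in all members). The empty
#' product (no compared loci) is 1, i.e. no support.
#'
#' @param cl an [IndividualClusters-class].
#' @param pid_sib_per_locus named numeric: locus -> sibling PID (see
#'   [pidLocus()]).
#' @return data.frame with columns individual_id, n_members, n_loci_compared,
#'   p_chance_identity; one row per multi-member cluster.
#' @export
matchSupport <- function(cl, pid_sib_per_locus) {
  stopifnot(is(cl, "IndividualClusters"))
  multi <- Filter(function(c1) length(c1$members) > 1L, cl@clusters)
  out <- lapply(multi, function(c1) {
    lc <- names(c1$composite)
    # loci actually compared: OK in every member of the cluster
    cmp <- lc[vapply(lc, function(L)
      all(vapply(c1$member_composites, function(mc)
        gtStatus(mc[[L]]) == "OK", logical(1))), logical(1))]
    if (length(setdiff(cmp, names(pid_sib_per_locus))))
      stop("compared locus absent from PID map: ",
           paste(setdiff(cmp, names(pid_sib_per_locus)), collapse = ","))
    data.frame(individual_id = c1$individual_id,
               n_members = length(c1$members),
               n_loci_compared = length(cmp),
               p_chance_identity = prod(pid_sib_per_locus[cmp]))
  })
  if (!length(out))
    return(data.frame(individual_id = integer(), n_members = integer(),
                      n_loci_compared = integer(),
                      p_chance_identity = numeric()))
  do.call(rbind, out)
}
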
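#' @include AllClasses.R
NULL

#' Accessors for pipeline containers
#'
#' Small accessor family used instead of direct slot access: \code{loci()}
#' returns the locus panel; \code{sampleIDs()} the sample identifiers;
#' \code{composites()} the per-sample composite genotypes (named lists of
#' [LocusGenotype-class]); \code{clusters()} the individual clusters;
#' \code{alleleFreqs()} per-locus allele frequency vectors; \code{gtStatus()},
#' \code{gtAlleles()} and \code{gtCandidates()} the fields of a single call.
#'
#' @param x a pipeline object.
#' @param locus locus name (for \code{alleleFreqs}); all loci when missing.
#' @return See each method.
#' @name accessors
#' @examples
#' gt <- readGenotypeTable(scatidExample("survey_genotypes.csv"))
#' loci(gt)
#' sampleIDs(gt)
#' gtStatus(composites(gt)[[1]][["PUN124"]])
NULL

#' @rdname accessors
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setGeneric("composites", function(x) standardGeneric("composites"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("alleleFreqs", function(x, locus) standardGeneric("alleleFreqs"))

#' @rdname accessors
#' @export
setMethod("loci", "GenotypeTable", function(x) x@loci)

#' @rdname accessors
#' @export
setMethod("loci", "AlleleFreqTable", function(x) x@loci)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "GenotypeTable", function(x) x@samples$sample_id)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "IndividualClusters", function(x)
  unlist(lapply(x@clusters, `[[`, "members"), use.names = FALSE))

#' @rdname accessors
#' @export
setMethod("composites", "GenotypeTable", function(x)
  stats::setNames(x@calls, x@samples$sample_id))

#' @rdname accessors
#' @export
setMethod("composites", "IndividualClusters", function(x)
  stats::setNames(lapply(x@clusters, `[[`, "composite"),
                  vapply(x@clusters, function(cl)
                    as.character(cl$individual_id), character(1))))

#' @rdname accessors
#' @export
setMethod("clusters", "IndividualClusters", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("alleleFreqs", "AlleleFreqTable", function(x, locus) {
  if (missing(locus)) return(x@freqs)
  if (!locus %in% x@loci) stop("unknown locus: ", locus)
  x@freqs[[locus]]
})

#' @rdname accessors
#' @export
gtStatus <- function(x) x@status

#' @rdname accessors
#' @export
gtAlleles <- function(x) x@alleles

#' @rdname accessors
#' @export
gtCandidates <- function(x) x@candidates

#' Sample metadata of a genotype table
#'
#' @param x a [GenotypeTable-class].
#' @return data.frame with columns sample_id, site, region, year.
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "GenotypeTable"))
  x@samples
}
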
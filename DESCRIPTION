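Package: scatID
Title: Noninvasive Scat-DNA Surveys: Species Assays, Consensus Microsatellite
    Genotyping, Individual Identification and Diversity Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for noninvasive genetic surveys of elusive
    carnivores from field-collected scats. Implements replicate-level
    presence/absence PCR call logic for carnivore-, species- and
    sex-identification assays with control validation; consensus
    microsatellite genotyping from triplicate PCRs under an explicit error
    model (amplification failure, allelic dropout, false alleles);
    individual identification by composite-genotype matching with
    probability-of-identity support; per-locus and cumulative genetic
    diversity statistics (Na, Ne, Ho, He, unbiased He, PID-unrelated,
    PID-sibling); a 3'-mismatch screen for species-diagnostic primer sites
    in multi-species alignments; and a forward simulator of scat surveys
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Genetics, SNP, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'assay-calls.R'
    'cli.R'
    'consensus.R'
    'matching.R'
    'popgen.R'
    'primer-screen.R'
    'simulate.R'
    'survey-io.R'
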
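---
title: "Noninvasive scat surveys: from replicate PCRs to individuals and diversity"
author: "scatID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive scat surveys: from replicate PCRs to individuals and diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatID)
```

## The problem

Noninvasive genetic surveys identify individual animals from DNA left in
the environment, most often scats. For a low-density, elusive carnivore
this is frequently the only practical census method, but fecal DNA is
degraded and dilute, so every inference has to survive an explicit error
model:

* **off-target scats** — a large fraction of field-identified scats belong
  to sympatric species;
* **amplification failure** — a PCR replicate yields nothing;
* **allelic dropout** — one allele of a heterozygote fails to amplify,
  mimicking a homozygote;
* **false alleles** — amplification artifacts scored as extra alleles.

`scatID` models the complete chain: replicated presence/absence assays with
controls, consensus microsatellite genotyping, individual identification by
composite-genotype matching, and the population-genetic summaries used to
decide whether matching is statistically defensible. A forward simulator
with known ground truth validates every stage.

## Assay calling

Each presence/absence assay (carnivore-generic, species-diagnostic, and the
Y-chromosome sex test) is run in triplicate with a positive and a
no-template negative control per replicate. `callAssay()` discards any
replicate with a failed control and then applies a symmetric 2-of-3 rule:

* POSITIVE — at least `min_positive = 2` valid banded replicates;
* NEGATIVE — at least `min_valid = 2` valid replicates, fewer than 2 banded;
* INVALID — fewer than 2 interpretable replicates.

Requiring two banded replicates guards against single-replicate
contamination; requiring two valid replicates before declaring absence
guards against dropout. The source protocols state the triplicate design
but not the decision threshold, so the rule is this package's choice and
both thresholds are exposed as parameters; a sample with a single band of
three is deliberately uninterpretable (UNKNOWN for sex, and never promoted
to a positive).

Sex is only read from samples whose species assay is POSITIVE: absence of
the Y amplicon is evidence of a female only when the template demonstrably
amplifies, so `callSex()` refuses to interpret the assay otherwise.

`congruenceTable()` cross-tabulates the species and carnivore calls. Since
the species target is nested within carnivores, every species-positive
sample should verify as carnivore; departures flag assay or template
problems. INVALID calls are tallied separately, never forced into the 2×2.

## Consensus genotyping

Microsatellite genotyping follows the multiple-tubes principle
(`consensusLocus()`): an allele is *confirmed* when observed in at least
`min_support = 2` of the replicates. The outcome vocabulary is explicit:

* two confirmed alleles → OK heterozygote;
* one confirmed allele and nothing else ever seen → OK homozygote;
* one confirmed allele plus unconfirmed observations (possible dropout of
  the partner) → AMBIGUOUS, with the full candidate set retained;
* observations but nothing confirmed → AMBIGUOUS;
* all replicates failed → MISSING.

Ambiguity is preserved into output tables in slash notation (`101/103`)
rather than forced to a call, because downstream statistics treat these
loci differently from confirmed ones (below). A replicate showing more than
two alleles signals a scoring fault or mixed sample and is an error, not a
call.

A sample counts as "successfully genotyped" (`genotypingSuccessRate()`)
when scored — OK or AMBIGUOUS — at no fewer than `min_scored` loci,
defaulting to one fewer than the panel size. The near-complete default
reflects practice: a sample unscored at a single locus but informative at
the rest still enters individual identification; the threshold is a
parameter for stricter definitions.

## Individual matching

`genotypesMatch()` compares two composites only at loci where both carry
confirmed calls; allele pairs compare unordered and must be exactly equal
(alleles are integer fragment sizes; no binning tolerance). Any difference
is a MISMATCH; identity at `min_shared = 4` or more co-typed loci of the
6-locus panel is a MATCH; fewer comparable loci is UNRESOLVED.

The default of 4 is a deliberate compromise. Full 6-locus identity is the
cleanest evidence, but real surveys contain informative samples typed at
4–5 loci; requiring 6 would discard them, while accepting matches at very
few loci invites chance identity (the sibling PID at 4 typical loci here is
on the order of 0.05–0.1). The threshold errs toward splitting, consistent
with reporting a *minimum* number of individuals present, and is logged in
output.

`clusterIndividuals()` agglomerates greedily in input order (a sample joins
the first cluster it matches against every member of), then audits all
pairs: cross-cluster MATCHes (non-transitive triples) are warned about and
reported in the `conflicts` slot. Singleton clusters that at least one
other sample could not be distinguished from are flagged `unresolved`;
conservative counts (the simulator's recovery experiment) withhold them.

`matchSupport()` quantifies each multi-sample cluster: the product of
per-locus sibling PID over the loci actually compared is the probability
that even a full sibling would share the observed composite by chance.

## Diversity and probability of identity

When no independent population sample exists, allele frequencies must come
from the unique genotypes observed: `alleleFrequencies()` collapses
duplicate scats first (each individual contributes exactly two allele
copies per locus) and excludes AMBIGUOUS and MISSING calls entirely, so the
per-locus sample size N varies across the panel. This exclusion rule is
what makes reported per-locus N, Na and Ho reproducible from published
genotype tables that print slash cells.

Per locus, with allele frequencies $p_i$ and $s_k = \sum_i p_i^k$:

$$N_e = 1/s_2, \quad H_e = 1 - s_2, \quad uH_e = \tfrac{2N}{2N-1} H_e,
\quad H_o = \text{het count}/N$$

$$PID_{unrel} = 2 s_2^2 - s_4, \qquad
PID_{sib} = 0.25 + 0.5\,s_2 + 0.5\,s_2^2 - 0.25\,s_4$$

Cumulative PIDs are products across loci (independence assumed). All
arithmetic runs at full floating precision; `formatSummaryTable()` applies
the conventional presentation rounding (Ne to 1 decimal, heterozygosities
to 3) only at report time. Overall He and Ho are unweighted across-locus
means. Loci with N = 0 report NA statistics, never zeros.

The tests verify $H_e = 1 - 1/N_e$ to 1e-12, the unrelated PID against
exhaustive genotype enumeration ($\sum_g P(g)^2$) on a thousand random
frequency vectors, and the sibling PID against a Monte-Carlo Mendelian
sibling-pair simulator (200,000 pairs per vector, 3-SE criterion).

On the packaged survey the cumulative PIDs computed under these documented
rules are ≈ 1.05 × 10⁻⁴ (unrelated) and ≈ 0.0179 (sibling). Published
summaries of this survey print 0.00014 and 0.0182; those values are not
exactly recoverable under any rule documented here (the originating
program's exact input — duplicate handling, slash-cell resolution — is
unknown), so the package reports its own values and treats the comparison
as an order-of-magnitude check rather than tuning to match.

## Primer screening

`scanDiagnosticSites()` implements the allele-specific-PCR design logic for
species-diagnostic primers on a multi-species alignment: a forward site
needs at least 2 mismatches versus *every* off-target species within the
3′-terminal window of the primer (3′ mismatches are what block extension),
and a reverse site needs more than 4 mismatches anywhere in the primer.
Choices the underlying protocol leaves open, fixed here and exposed as
parameters: the 3′ window is the terminal 5 bases (standard ASP practice);
the reverse criterion counts over the whole primer; a gap or N in the
target window disqualifies the site (un-synthesizable); an N in an
off-target is treated as compatible (not counted as a mismatch), the
conservative direction for claiming specificity. Coordinates are 0-based
half-open alignment columns; `ampliconForPair()` reports ungapped target
lengths. The packaged alignment is synthetic (built to exercise the scan);
the scan itself is verified against a brute-force per-window re-scorer.

## The simulator

`SimParams()` defaults describe the survey regime this pipeline targets: a
small population (9 individuals) genotyped at 6 loci with observed allele
counts (6, 4, 4, 3, 4, 2), symmetric-Dirichlet allele frequencies
(concentration 1), roughly 2 scats deposited per individual, an off-target
scat fraction of 0.73 (with ~58% of off-targets from other carnivores),
triplicate PCR, and error rates typical of aged fecal DNA: wholesale
replicate failure 0.3 (about the fraction of samples too degraded to
analyze in such surveys), per-allele dropout 0.2, false alleles at 0.05 per
replicate drawn within ±2 bp of real alleles to stress exact-match
clustering realistically.

The model is deliberately minimal: Hardy–Weinberg equilibrium, independent
loci, no null alleles, no stutter, no spatial structure, no
individual-level DNA-quality heterogeneity. Template amplifiability is
drawn once per scat × replicate and shared by the assays, which makes the
species assay's positives a strict subset of the carnivore assay's — the
nested-target property real surveys exhibit. Consequences for
interpretation: passing recovery tests demonstrate the pipeline's logic is
correct *under its own assumptions*; they do not certify performance on
populations with related individuals (PID-sibling is the guard), null
alleles, or locus-dependent degradation.

`recoveryExperiment()` runs the full pipeline over many simulated surveys.
Two behaviors worth knowing:

* With all error rates at zero, the recovered count equals the number of
  individuals that actually deposited a species-positive scat, except for
  rare chance-identity merges bounded by the panel's cumulative PID.
* Under heavy *failure* the count can only shrink (lost loci produce
  UNRESOLVED singletons that are withheld). Under heavy *dropout* the
  direction is not guaranteed: one allele of a heterozygote can drop in
  every replicate (probability $d^{n_\text{rep}}$ per allele), producing a
  *confirmed* false homozygote that positively mismatches its true
  siblings — an overcount exact-match clustering cannot detect. This is the
  quantitative argument for replication and for mismatch-tolerant matching
  when dropout is severe.

## Numerical and degenerate-input choices

* Allele identity is exact integer equality on fragment size.
* Frequencies must sum to 1 within 1e-9 on entry to PID functions; the
  validity check on frequency tables uses 1e-12.
* An AMBIGUOUS call with a single candidate is legal (one unconfirmed
  observation); candidate sets are sorted, deduplicated integers.
* Empty surveys give all-zero congruence tables with NA congruence; the
  empty PID product is 1; N = 0 loci report NA statistics.
* The simulator is byte-deterministic under its seed; per-run seeds in the
  recovery experiment are small offsets of the base seed.

## Validation scale

The packaged checks run the 10-sample survey end to end (well under a
second), 1,000 error-free recovery surveys at 10 individuals / 30 scats,
1,000 fuzzed frequency vectors against the enumeration oracle, and 20
vectors × 200,000 Monte-Carlo sibling pairs — sizes chosen so the whole
suite completes in a few minutes while leaving the stochastic criteria
3-standard-error headroom.

## Limitations

* Matching is exact; no mismatch-tolerant or likelihood-based matching
  (e.g. dropout-aware pairwise scores), so severe dropout splits rather
  than merges.
* No capture–recapture abundance estimation: the output is a minimum count.
* No HWE tests, F-statistics or relatedness inference; frequencies from a
  handful of individuals are estimates of convenience, not population
  parameters.
* The primer screen scores annealing mismatches only — no melting
  temperature, secondary structure or primer-dimer modeling.
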
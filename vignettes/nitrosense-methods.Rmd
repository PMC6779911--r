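---
title: "Methods: nitrate-sensitive gene discovery and compartmentalized nitrogen flux"
author: "nitrosense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nitrate-sensitive gene discovery and compartmentalized nitrogen flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nitrosense` re-implements, as a tested pipeline, a multi-omics analysis of
short-term nitrogen-source shifts in the marine diatom *Phaeodactylum
tricornutum*: which genes respond specifically to nitrate (rather than to
nitrogen availability in general), how the proteome tracks those
transcript responses, whether a candidate binding-site motif is enriched
in the promoters of the most nitrate-sensitive genes, and how assimilated
nitrogen is shuttled between chloroplast and mitochondria under nitrate
versus urea growth. Every stage can be exercised on synthetic data with
planted ground truth, which is how the package tests and the acceptance
script evaluate it.

# The experimental design being emulated

Cultures growing on ammonium are starved of nitrogen for two hours,
spiked briefly with nitrate, and then split into four treatments (no
nitrogen, ammonium, nitrite, nitrate) sampled at 15 min, 45 min and 18 h,
in two biological replicates. That yields 15 conditions per replicate:
three pretreatment samples (`preNH4`, `preN0`, `preNO3`) and 12
treatment-by-time conditions. External nitrogen is exhausted by 18 h, so
the 18 h samples and the no-nitrogen arm count as N-unavailable; the
nitrate-spiked pretreatment counts as a nitrate-exposed, N-available
sample.

# Expression coding and response types

Counts are normalized as RPKM (`1e9 * c / (L * N)`). Differential
expression against the ammonium pretreatment control uses a two-sided
conditional negative-binomial exact test on library-size-adjusted counts:
group totals are modeled as negative binomial with a supplied dispersion,
and conditional on the combined total the p-value sums the probability of
every split at most as likely as the observed one. As the dispersion
approaches zero this reduces to the conditional binomial (Poisson) exact
test, which the tests verify by enumeration. Dispersion is estimated by a
count-weighted method-of-moments across replicate groups with optional
shrinkage of per-gene moment estimates toward the common value; the
tagwise empirical-Bayes machinery of dedicated DE packages is deliberately
not reproduced, and an import path for an externally computed DE table is
provided instead (`readDETable()`). Library-size normalization is
total-count scaling; trimmed-mean normalization is out of scope.

Per gene, the 12 comparisons are coded +1 (BH FDR < 0.05 and positive
log2 fold change), -1 (significant, negative) or 0, giving a vector over
a 3^12 = 531,441-pattern space. Patterns are clustered with average
linkage (UPGMA) on one-minus-Pearson distance and the dendrogram is cut
into `k = 201` response types (RTs), a deliberately arbitrary, configurable
granularity. Three numerical conventions matter:

* Pearson correlation is undefined for zero-variance patterns (the
  never-significant all-zero code). Identical constant patterns are at
  distance 0 and a constant pattern is at distance 1 from anything else,
  which groups never-DE genes without asserting similarity to responders.
* Identical patterns are deduplicated before clustering and re-attached
  with multiplicity weights (`hclust(..., members=)`); this is exactly
  equivalent to clustering the expanded matrix (verified in the tests)
  and keeps the distance matrix at the size of the distinct-pattern set.
* When `k` exceeds the number of distinct patterns, each distinct pattern
  becomes its own RT; RT ids are assigned by first-member order so the
  numbering is input-order canonical.

An RT is flagged nitrate-specific when its mean standardized profile over
the early nitrate conditions (NO3 at 15 and 45 min) exceeds the
corresponding ammonium, nitrite and no-N means by more than a margin
(default 0: any excess). The margin rule is a documented convention; the
underlying study states the concept but not a formula.

# The three-dimensional nitrate-specificity metric

Candidates are genes with mean RPKM > 5 across conditions and
`RPKM(preNO3) > RPKM(preN0)` (strict). On replicate-averaged
`log2(RPKM + 1)` the three contrasts are: ammonium repression at 15 min
relative to the nitrate pretreatment; nitrate induction at 15 min versus
ammonium at 15 min; and nitrate induction at 15 min versus nitrite at
15 min. The subtraction scale is configurable (`log2p1`, `raw`,
`standardized_rpkm`); log scale is the default because raw-RPKM
subtraction is dominated by high expressors. Each contrast is z-scored
over candidates (the tested population; z-scoring over all genes is the
other defensible reading and is not used). A gene passes a dimension when
its z-value strictly exceeds the type-7 empirical 85th percentile; NS
genes pass all three, and HNS genes are NS genes that also belong to a
nitrate-flagged RT. The intersection is what gives the call its
precision: percentile gating alone admits roughly `0.15^3` of candidates
under independence, and RT membership removes gate-passers whose coded
pattern is not nitrate-shaped.

# Proteome rollup, clustering and enrichment

Log2 peptide abundances are rolled up to proteins by reference scaling:
the reference peptide is the one observed in the most channels (ties by
higher mean abundance), other peptides are shifted by the median
difference to the reference over shared channels (a peptide sharing no
channel is dropped with a warning), and the protein profile is the
channel-wise median of shifted peptides. Peptides mapping to several
proteins roll up into flagged protein-group rows, excluded from
enrichment by default. Possible outlier-peptide rejection in the original
rollup tool is not described in its text and is not implemented.
Channel medians are then centered (central-tendency normalization,
idempotent), and profiles are standardized first within treatment blocks
and then across the concatenated vector; zero-variance rows become zeros
and singleton blocks are centered only and flagged.

Proteins are clustered with seeded K-means into `k = 100` proteome
clusters (PCs). On row-standardized profiles the Euclidean metric is a
monotone transform of correlation distance, so this matches
correlation-based K-means; missing values are mean-imputed (zero) for
clustering only, and empty clusters are repaired by splitting the largest.
RT-by-PC association uses the upper-tail hypergeometric test over genes
carrying both assignments, BH-adjusted across all pairs; the original
description says only that clusters were "surveyed", so the test choice
is the package's own, and it is validated against closed-form tails.

# Promoter motif scanning

Promoters are the 500 bp upstream of the start codon (0-based half-open
arithmetic; truncated and flagged at contig edges; deliberately not
truncated against upstream neighbours). Motifs arrive in MEME minimal
text format. Scanning scores every window on both strands with the
log2-odds matrix (background-weighted pseudocount 0.1) and computes exact
p-values by dynamic programming over the per-position score distribution
discretized at 1e-3 bits; tests verify the DP tail against exhaustive
4^w enumeration for widths up to 6 (within 1e-6). Windows containing
ambiguous bases are skipped; opposite-strand overlaps both count, and
same-strand duplicates count once per start. The background model is
0-order, estimated from the scanned set by default. Motif density is
operationalized per promoter (fixed length makes per-kb a constant
multiple), and comparisons against larger gene sets use seeded random
subsamples of the focal set's size, mirroring how a small focal set is
compared against large background classes.

# Flux balance analysis on the toy nitrogen network

The published genome-scale model is not bundled; a hand-built, ~60
reaction compartmentalized toy network
(`inst/extdata/ptoy_nitrogen.json`) encodes the pathways of interest with
carbon and nitrogen atom annotations: chloroplast nitrate assimilation
(NR in the cytosol, NiR, GSII/GOGAT in the plastid), mitochondrial urea
assimilation (urease, GSIII/GOGAT), paired aspartate and alanine
transaminase shuttles, plastid and mitochondrial pyruvate carboxylases
with TCA-segment reactions (akg to oaa oxidation, malic-enzyme
decarboxylation) so the mitochondrion has anaplerosis and carbon exits,
and the split-organelle arginine route (plastid ornithine synthesis,
mitochondrial carbamoyl-phosphate/citrulline, cytosolic
argininosuccinate). Validity checks enforce exact C and N balance of
every internal reaction; exchange reactions are exempt by definition.
Energy and redox are not modeled. Two engineered capacities make the
qualitative shuttle behavior identifiable: direct glutamate/glutamine
transport is restricted (|v| <= 0.005) and the transaminases are
irreversible in their physiological directions (plastid AST writes amino
nitrogen onto oxaloacetate, mitochondrial ALT onto pyruvate). These are
documented in the fixture file itself.

Constraints follow the study's settings: O2 evolution capped at 10
mmol/gDW/h (`EX_o2_e` upper bound), maintenance as a 0.33 lower bound on
the mitochondrial alternative oxidase, ammonium transport between
organelles and cytosol capped at 0.1 (the source prints no time unit;
read as mmol/gDW/h for dimensional consistency), and one nitrogen
exchange open per scenario. Measured metabolite concentration changes
(nmol per mg protein over the first hour) convert to mmol/gDW/h through
the 70% biomass protein fraction (factor 7e-4) and enter as sink
reactions with both bounds fixed at the rate. Infeasible sink sets are
relaxed by bisection-scaling the largest-magnitude sink first, with every
alteration reported; in the default urea scenario the synthetic proline
accumulation rate of 6.6 exceeds the mitochondrial proline-synthesis
capacity bound of 1 and relaxes to ~1, intentionally reproducing the
documented adjustment in the source study.

The LP is solved by a dense two-phase primal simplex with variable
bounds and Bland's rule, written in the package because no
linear-programming library is otherwise available to it; it is checked in
the tests against an independent interior-point implementation. Solver
feasibility tolerance is 1e-9 and solutions are reported at 1e-6
(`|S v|` and atom balance). The loopless step fixes exchanges and the
objective at their solved values and minimizes the internal L1 norm via
flux splitting, which cannot change the objective and never increases
internal flux; alternate optima are possible in the raw LP, so the
shuttle report is computed on the loopless solution only and all shuttle
assertions use dominance thresholds rather than exact fluxes. Net
carrier transfer between chloroplast and mitochondrion is the
direction-consistent common flow of the two cytosolic legs
(organelle-to-cytosol and cytosol-to-organelle), so a carrier feeding
cytosolic biomass does not count as inter-organelle transfer.

# The synthetic-data generator

The generator (`simulateNitrogenExperiment()`) draws every pipeline input
from one seed:

* **Counts.** Negative binomial around archetype mean profiles on the
  log2 RPKM scale, with gene dispersions log-normal around 0.1 (sdlog
  0.3) and library sizes log-normal around 5e6. Five archetypes:
  `n_replete` (up where nitrogen is available), `n_deplete` (the
  complement), `nitrate_specific` (up on `preNO3` and early NO3, down on
  early NH4/NO2), `ammonium_specific` (the ammonium mirror), and `flat`.
  Default proportions 0.30 / 0.30 / 0.005 / 0.005 / 0.39 put over half
  the genome in the broad availability classes and plant 60
  nitrate-specific genes at the default 12,000-gene scale. Effect sizes
  vary around 4 log2 units, truncated one unit either side, so every
  planted responder is at least 3 log2 units. Archetype counts follow the
  configured proportions exactly (largest-remainder apportionment, then
  a seeded shuffle), which makes recovery denominators deterministic.
  Baseline log2 RPKM is N(3, 1.5) for the bulk transcriptome; the two
  source-specific archetypes draw from N(4.5, 1), the clearly expressed
  stratum, because the real genes they emulate (nitrate transporters,
  NR, NiR) are well expressed and a recovery benchmark should plant its
  positives above the detection filter it feeds (mean RPKM > 5) —
  otherwise recall measures filter attrition instead of method behavior.
* **Proteome.** A seeded random subset of genes (default 52%, the
  detected fraction scale of the study) gets a protein profile equal to
  its standardized transcript profile plus Gaussian noise, observed
  through 1-6 peptides with peptide offsets and 15% missing-at-random
  channels (at least one observed channel kept per peptide) — enough
  structure to exercise the rollup and the RT-by-PC enrichment.
* **Promoters.** I.i.d. background sequence (A/T 0.3, C/G 0.2) with
  exact consensus instances of the supplied motif planted at
  non-overlapping positions and random strands, with counts
  Poisson(base + slope * specificity); placement is by rejection
  sampling so realized counts keep the Poisson law. The packaged motif
  is a synthetic 9 bp ETS-like matrix (core CCGGAAG) and is labeled
  synthetic; it is constructed, not discovered.
* **Labeling and metabolites.** Exponential labeled fractions
  `1 - exp(-kt)` at 0/1/3/8 h over a small amino acid panel with fast
  (glutamine) to slow (proline) rate constants, and scenario-specific
  metabolite concentration tables for the flux constraints.

What the generator does not emulate: read-level artifacts (GC and
length biases beyond the RPKM length term, mapping ambiguity),
overdispersion heterogeneity beyond log-normal gene dispersions,
correlated genes within archetypes (genes are conditionally independent
given the archetype), peptide-level interference or isotope impurity, and
promoter sequence composition beyond 0-order background. Passing the
recovery tests therefore shows the pipeline recovers planted structure
under its own statistical assumptions, not that it is robust to every
artifact of real data.

# Problem sizes and determinism

The test suite and acceptance script run the full design at 12,000 genes
and 2 replicates (the study's scale), with smaller gene counts (400-6,000)
for focused properties; recovery is averaged over ten seeds. All
randomness flows through explicit seeds: equal seeds give byte-identical
datasets and identical HNS calls, which the tests assert. K-means uses
five seeded restarts; the simplex and every closed-form stage are
deterministic.

# Known limitations

* The DE stage is a deliberate simplification of the original tool chain
  (common rather than tagwise dispersion, total-count rather than TMM
  normalization); headline gene counts from the deposited data are not
  reproducible at this scale and are not targets.
* The toy flux network reproduces qualitative shuttle behavior, not the
  published model's flux values; absolute growth rates on the fixture
  are arbitrary in scale.
* Percentile gating with strict inequality can retain one gene fewer
  than the nominal fraction under ties.
* The promoter scanner computes exact p-values per window but no
  genome-wide q-values (out of scope).
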
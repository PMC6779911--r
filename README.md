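# nitrosense

Multi-omics analysis of short-term nitrogen-source shifts in the model
diatom *Phaeodactylum tricornutum*, for researchers studying how
phytoplankton sense and assimilate nitrate. Diatoms outcompete other
phytoplankton for episodic nitrate pulses, and the package implements a
pipeline that asks, on time-course data spanning four nitrogen treatments
(no N, ammonium, nitrite, nitrate at 15 min / 45 min / 18 h after a
starve-and-spike pretreatment):

1. **Which genes respond specifically to nitrate?** Per-comparison
   negative-binomial exact tests against the ammonium control are coded
   into three-state patterns (+1 / 0 / −1 over 12 comparisons, a
   3^12 = 531,441-pattern space), clustered by UPGMA on one-minus-Pearson
   distance into 201 response types (RTs). In parallel, a
   three-dimensional nitrate-specificity metric is computed on
   log2(RPKM+1): ammonium repression relative to the nitrate
   pretreatment, nitrate-vs-ammonium induction at 15 min, and
   nitrate-vs-nitrite induction at 15 min, each standardized over
   candidate genes (mean RPKM > 5, nitrate-pretreatment responsive).
   Genes above the 85th percentile in all three dimensions are
   nitrate-specific (NS); NS genes inside nitrate-flagged RTs are
   **highly nitrate-sensitive (HNS)**.
2. **Does the proteome track the transcript response?** Peptides roll up
   to proteins by reference-scaled medians, are median-centered and
   standardized in two stages, clustered by seeded K-means into 100
   proteome clusters, and tested for RT enrichment with hypergeometric
   tails.
3. **Is a binding-site motif concentrated in HNS promoters?** 500 bp
   promoters are scanned with a PWM using exact dynamic-programming
   p-values (FIMO-style), and motif density is related to the
   specificity metric.
4. **How does nitrogen move between organelles?** Flux balance analysis
   on a compartmentalized toy model of diatom nitrogen assimilation with
   metabolite-accumulation constraints (S·v = dx/dt via fixed-rate
   sinks), solved looplessly; the report quantifies how much amino
   nitrogen travels chloroplast↔mitochondria on aspartate, alanine,
   glutamate and glutamine carriers, plus urea-cycle arginine synthesis
   and ¹⁵N labeling-rate summaries (100 · f(3 h)/3 percent per hour).

A seeded synthetic-data generator produces every input with planted
truth (response archetypes, motif placements, labeling curves), so the
whole pipeline is testable end to end with measurable precision/recall.

## Worked example

```r
library(nitrosense)

cfg <- simulationConfig(n_genes = 2000, seed = 1)
res <- runPipeline(cfg, k_rt = 201, stages = c("expression", "flux"))
rec <- recoveryReport(res)

length(res$expression$hns$candidates)  # 954 candidate genes
length(res$expression$hns$ns)          # 26 NS genes
length(res$expression$hns$hns)         # 10 HNS genes
rec$hns_precision                      # 1
rec$hns_recall                         # 1

res$flux$nitrate$shuttle$routes
#>       route n_flux dominance
#> 1 aspartate 0.3616         1
#> 2   alanine 0.0000         0
#> 3 glutamate 0.0000         0
#> 4 glutamine 0.0000         0
res$flux$urea$shuttle$routes
#>       route n_flux dominance
#> 1 aspartate  0.000         0
#> 2   alanine -1.185         1
res$flux$urea$relaxation
#>       sink original   relaxed
#> 1 SK_pro_c  6.60002 0.9998321
```

Reading the output: of 2000 simulated genes (10 planted nitrate-specific
at ≥ 3 log2 effect), 954 pass the expression/pretreatment candidate
filter, 26 clear the 85th-percentile gate in all three specificity
dimensions, and intersecting with nitrate-flagged response types leaves
10 HNS genes — exactly the planted set (precision and recall 1). On the
flux side, nitrogen assimilated in the chloroplast (nitrate growth)
reaches the mitochondria on an aspartate/oxaloacetate carrier, while
nitrogen assimilated in the mitochondria (urea growth) returns on an
alanine/pyruvate carrier (negative sign = mitochondrion→chloroplast),
and the infeasible synthetic proline accumulation rate (6.6
mmol gDW⁻¹ h⁻¹) is relaxed to the model's proline-synthesis capacity
(~1), mirroring the adjustment documented for the original study.

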
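# qtlMeta

Meta-analysis of quantitative trait loci (QTLs) on consensus genetic maps.

Individual QTL mapping studies for a complex trait — the motivating case is
maize plant height (PH) and ear height (EH) — disagree on where a locus
sits: populations differ in design, size and marker coverage, so each study
reports a peak with a wide confidence interval (CI) on its own linkage map.
`qtlMeta` is for geneticists who have curated such a multi-study QTL
compendium and want the consensus loci ("meta-QTLs", MQTLs): regions
supported by several independent studies, with a CI narrow enough to mine
for candidate genes.

The package implements the full pipeline:

1. **Compendium QC and CI imputation.** Records with PVE < 1% or
   LOD < 1.5 are removed. A missing 95% CI is imputed from the
   Darvasi–Soller expected interval width,

   CI = 530 / (N · R²) for F2-like designs (F2, BC, F2:3, F3, F4),
   CI = 163 / (N · R²) for homozygous immortal designs (RIL, DH),

   with N the population size and R² the proportion of phenotypic variance
   explained (PVE%/100), centered on the peak and floored at 0 cM.
2. **Homothetic projection.** Each QTL's peak and CI bounds are carried
   from the study map onto a reference map through the tightest pair of
   flanking markers shared by both maps (affine rescaling per anchor
   interval; no extrapolation beyond the shared-marker span).
3. **Gaussian meta-analysis.** Per chromosome, each projected QTL
   contributes a position x\_i with σ\_i = CI width / 3.92. The
   position-sorted QTLs are partitioned into k contiguous clusters by an
   exact dynamic program maximising Σ log φ(x\_i; μ, σ\_i²); k is chosen by
   majority vote of five information criteria (AIC, AICc, AIC3, BIC, AWE).
   Each winning cluster becomes an MQTL at the inverse-variance consensus
   position μ = Σ(x\_i/σ\_i²)/Σ(1/σ\_i²) with 95% CI μ ± 1.96·se,
   se = (Σ σ\_i⁻²)^(−1/2) — always at least as narrow as the narrowest
   member CI.
4. **Physical anchoring.** MQTL genetic CIs are converted to bp through
   piecewise-linear interpolation across marker anchors; overlapping genes
   are pulled from a GFF3 annotation and tallied into functional
   categories (hormone, cell wall, sugar, photosynthesis, cytoskeleton)
   by keyword matching.
5. **Synthetic scenarios.** A fully seeded generator produces multi-study
   compendia, distorted per-study maps, anchors and toy annotations with
   known ground truth, for calibration and parameter-recovery studies.

## Worked example

```r
library(qtlMeta)

sc <- simulateScenario(scenarioConfig(seed = 42))
sc$compendium
#> QTLCompendium: 72 QTL record(s)
#>   traits: EH=35, PH=37; chromosomes: 1,2,3
#>   studies: 13; records lacking a CI: 14

res <- runMetaPipeline(sc$compendium, sc$sourceMaps, sc$reference,
                       anchors = sc$anchors, genes = sc$genes)
res$projection$rate
#> [1] 0.9861111
res$mqtls
#> MQTLSet: 10 MQTL(s) on 3 chromosome(s)
#>   CI width (cM): min 1.72, mean 3.15, max 5.01; member QTLs: 71

recoveryMetrics(res$mqtls, sc$truth)[c("k_error", "position_rmse",
                                       "ci_coverage")]
#> $k_error
#> 1 2 3
#> 0 0 1
#> $position_rmse
#> [1] 0.8012738
#> $ci_coverage
#> [1] 0.7777778
```

The three simulated chromosomes each carry three true loci at 50/150/250
cM. The pipeline projects 71 of 72 literature-style QTLs onto the
reference map and places consensus positions within ~0.8 cM of truth. On
this seed, chromosomes 1 and 2 recover exactly three MQTLs each while
chromosome 3 oversplits one locus into two adjacent MQTLs (`k_error` 1) —
the characteristic failure mode of information-criterion voting over an
exhaustively optimized segmentation, discussed in the vignette; position
accuracy is unaffected. Two true loci fall just outside their MQTL's
narrow CI (chromosome 1's locus at 50 cM misses the 47.33–49.91 interval
by ~0.1 cM; chromosome 3's split locus at 250 cM similarly), giving 7/9
coverage on this single seed — across 100 seeds coverage averages ~0.95
(see `scripts/acceptance.R`).

The packaged transcription of a published 29-MQTL maize PH/EH summary is
available for benchmarking the summary statistics:

```r
tab <- loadPublishedMQTLSummary()
mqtlSummary(data.frame(chromosome = tab$chromosome, ci_lo = tab$ci_lo_cM,
                       ci_hi = tab$ci_hi_cM, n_qtls = tab$n_qtls,
                       trait_class = tab$trait_class))$ci_width
#>   min  mean   max
#>  0.80 26.27 75.20
```

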
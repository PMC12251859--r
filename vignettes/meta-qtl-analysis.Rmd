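---
title: "Meta-QTL analysis on consensus genetic maps with qtlMeta"
author: "qtlMeta authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-QTL analysis on consensus genetic maps with qtlMeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlMeta)
```

## The problem

A QTL mapping study reports, for each detected locus, a peak position and a
confidence interval (CI) on the study's own linkage map, together with the
LOD score and the phenotypic variance explained (PVE). Across studies of
the same trait — here the motivating system is maize plant height (PH) and
ear height (EH) — these reports are only loosely comparable: populations
differ in design (F2, F2:3, F3, F4, RIL, DH), size, and marker coverage,
and each map has its own scale. Meta-QTL analysis integrates such a
compendium into consensus loci (MQTLs) with narrowed CIs, which can then
be anchored on the physical genome and mined for candidate genes.

`qtlMeta` implements the four analysis stages and a synthetic-data
generator. This vignette describes the model behind each stage, the
parameters that matter, the numerical choices, and what the simulation
harness does and does not demonstrate.

## Stage 1: compendium QC and CI imputation

Records are removed when PVE < 1% or LOD < 1.5, with strict inequalities;
a record missing both values survives (the condition cannot be evaluated)
and is flagged in the returned run log. `qualityFilter()` always
partitions its input: kept plus removed equal the input in its original
order.

A missing 95% CI is imputed from the Darvasi–Soller expected interval
width,

$$\mathrm{CI} = \frac{530}{N R^2} \quad\text{(F2-like)},\qquad
  \mathrm{CI} = \frac{163}{N R^2} \quad\text{(RIL/DH)},$$

where $N$ is the mapping-population size and $R^2$ the *proportion* of
variance explained. Published compendia usually quote PVE in percent, and
the formulas are meaningless on that scale (an $N=200$, 10%-PVE QTL would
get a 0.265 cM interval instead of the plausible 26.5 cM), so
`imputeCIWidth()` divides `pve_percent` by 100. Design-to-equation
assignment follows standard practice for the designs the two equations do
not name explicitly: selfed F2-derived families (F2:3, F3, F4) behave like
F2 and use the 530 numerator; doubled haploids are homozygous immortal
lines like RILs and use 163.

The imputed interval is centered on the peak — the expected interval is
symmetric and nothing in the record justifies asymmetry — and the lower
bound is floored at 0 cM without shifting the upper bound, so the peak
always stays inside its CI and `completeCIs()` is idempotent.

## Stage 2: projection onto the reference map

QTLs are carried onto a single dense reference scaffold (for maize, an
IBM2-2008-Neighbors-like map) by homothetic (affine) rescaling between
flanking markers shared by the source and reference maps:

$$x' = r_L + (x - s_L)\,\frac{r_R - r_L}{s_R - s_L}.$$

Three choices matter:

* **Per-point anchoring.** The peak and the two CI bounds are each
  bracketed independently by the tightest shared-marker pair around *that
  point*. A long CI therefore crosses several anchor intervals instead of
  being stretched through one global pair, which keeps local map
  distortions local.
* **No extrapolation.** A point outside the span of shared markers fails
  (`no_common_flank`) rather than being extrapolated. This mirrors how
  real compendia lose QTLs — wide intervals and sparse shared markers —
  and the failure reasons are reported per QTL.
* **Reversed local order.** If a shared-marker pair is inverted on the
  reference map the affine map simply reverses orientation; projected CI
  bounds are re-sorted, and in the rare case where per-point anchor pairs
  disagree enough that the projected peak escapes the re-sorted CI, the
  peak is clamped into it.

Shared markers are exact fixed points of the projection to machine
precision, and within one anchor interval the map is strictly monotone —
both properties are asserted by the test suite on jittered maps.

`mapSummary()` reports map totals; the mean inter-marker interval divides
the summed length by (markers − chromosomes), the number of actual
intervals. Published map summaries do not always follow a consistent
convention here, so small discrepancies with printed averages are
expected.

## Stage 3: Gaussian meta-analysis

Each projected QTL enters as a Gaussian position observation: mean $x_i$
(projected peak) and standard deviation $\sigma_i$ = projected CI width /
3.92, the 95%-interval to SD conversion. Per chromosome, the
position-sorted QTLs are partitioned into $k$ contiguous clusters; a
cluster's fit is the maximum-likelihood common position

$$\hat\mu = \frac{\sum x_i/\sigma_i^2}{\sum 1/\sigma_i^2},\qquad
  \mathrm{se}(\hat\mu) = \Big(\sum \sigma_i^{-2}\Big)^{-1/2},$$

with log-likelihood $\sum_i \log\varphi(x_i;\hat\mu,\sigma_i^2)$. The
best partition for each $k$ is found *exactly* by dynamic programming over
the sorted order — equivalent to enumerating all $\binom{n-1}{k-1}$
contiguous partitions, which the tests verify — so results are
deterministic and independent of input order. A soft-assignment EM
mixture is deliberately out of scope: hard contiguous assignment is
exactly optimizable and testable against brute force.

### Model-order selection

Five criteria are computed for each candidate $k$: AIC, AICc, AIC3, BIC
and the approximate weight of evidence AWE $= -2L + 2p(3/2 + \ln n)$.
Each criterion votes for its minimizing $k$ (ties toward the smaller
$k$); the chosen model is the $k$ with at least three of five votes,
falling back to plurality (ties again toward parsimony) when no majority
exists.

The free-parameter count is the one genuinely open design choice. The
package uses $p = 2k - 1$: the $k$ cluster means plus the $k-1$ segment
boundaries (equivalently, mixing proportions — the count used by the
classical mixture formulation of QTL meta-analysis). The alternative
$p = k$, counting only the means, is available by passing `p` to
`informationCriteria()`, but it is statistically indefensible here:
because the DP maximises the likelihood over every boundary placement,
the deviance gained by adding a cluster behaves like the maximum of
roughly $n$ dependent $\chi^2_1$ variables (about 6–8 for $n \approx 24$)
rather than a single $\chi^2_1$. With $p=k$, every criterion except AWE
then overselects almost always; counting the boundaries restores penalties
of the right order. Even so, model-order selection by fixed-dimension
criteria over an exhaustively optimized segmentation remains slightly
liberal — on the package's default recovery scenario the voted $k$ equals
the true number of loci in roughly 55–60% of chromosome runs, with
essentially all misses being a one-cluster overshoot that splits one true
locus in two. Position estimates and coverage are much more robust than
the order itself (see below), which is the practically relevant part:
oversplitting costs a duplicated locus report, not a misplaced one.

Each winning cluster becomes an MQTL: position $\hat\mu$, 95% CI
$\hat\mu \pm 1.96\,\mathrm{se}$, members, and a trait class that is the
union of member traits (`"PH"`, `"EH"` or `"PH, EH"`). Because
$\mathrm{se} \le \min_i \sigma_i$, an MQTL CI is never wider than its
narrowest member CI — asserted on every meta-analysis run in the tests.
MQTLs are indexed left to right as `MQTL{chr}-{i}`. The default pooled
mode clusters both traits together, reflecting summary tables in the
field where most MQTLs carry both PH and EH members; `mode = "per-trait"`
analyses traits separately and re-indexes the merged result, for workflows
that meta-analyse each trait on its own. `kmax` defaults to
`min(n, 10)` candidate orders per chromosome. Reported cM summaries use
2-decimal half-up rounding, the convention of published MQTL tables.

## Stage 4: physical anchoring and candidate genes

Genetic CI bounds are converted to bp by piecewise-linear interpolation
across *all* marker anchors of the chromosome, not just the two CI
flanking markers: interpolation degrades gracefully when a flanking
marker lacks a physical position, matching the usual
"next nearest marker" fallback of manual anchoring. Endpoints outside the
anchored span are clamped to the terminal anchors (no extrapolation);
consecutive anchors sharing a cM position fall back to the first anchor's
physical position. Where genetic and physical order conflict the anchors
are flagged with a warning but used as given.

Gene extraction uses closed-interval, any-overlap semantics on 1-based
GFF3 coordinates (a gene abutting the interval edge is included), via
GenomicRanges. Functional classification is a case-insensitive keyword
tally against a packaged dictionary covering the categories commonly
reported in plant-architecture candidate-gene work (hormone, cell wall,
sugar, photosynthesis, cytoskeleton); a gene may carry several tags, so
category percentages may sum past 100, and unmatched genes fall into
`other`. Statistical GO enrichment against a live ontology is explicitly
out of scope — percentages here are descriptive tallies.

## The synthetic-data generator

`simulateScenario()` emulates the statistical structure of a
literature-curated compendium with known truth. The defaults are the
package's reference conditions, chosen once to mirror a realistic
13-study maize compendium:

| parameter | default | rationale |
|---|---|---|
| chromosomes × length | 3 × 300 cM | enough independent replicates per run at realistic chromosome scale |
| true loci | 50/150/250 cM | well-separated (100 cM) consensus targets |
| studies | 13 (4 F2, 4 F2:3, 1 F3, 1 F4, 2 RIL, 1 DH; N = 120–271) | the design/size mix of published PH/EH compendia |
| QTLs per locus | 8 | typical support per consensus locus |
| PVE | U(3.23, 31.93)% | the single-QTL PVE range reported for PH/EH |
| CI omitted | 25% of records | exercises the imputation path |
| map derivation | keep 60% of markers, log-normal interval jitter (sd 0.1) | per-study maps are sparser and length-distorted |
| LOD | 2.5 + 0.45·PVE + N(0, 0.5), floored at 1.6 | reproduces reported LOD ranges qualitatively; LOD–PVE coupling is invented and config-exposed |

The one structural commitment is *calibration*: the reported peak is the
true position plus Gaussian noise with sd = Darvasi–Soller width / 3.92,
so simulated CIs are correct 95% intervals — exactly the self-consistency
the meta-analysis model assumes. `noiseScale` scales this sd (0 gives
the noiseless limit, where the whole pipeline must return the true locus
count and positions to numerical precision — a test the suite runs).
Everything is a pure function of the config, whose seed is mandatory.

What the generator does *not* emulate: correlated detection across
studies, asymmetric or misreported CIs, reference-map marker-order
errors, linked loci closer than the CI scale, and selective reporting.
Passing the recovery tests therefore shows the estimator is correct under
its own assumptions, not that real compendia satisfy them.

On this default scenario (100 seeds × 3 chromosomes), the pipeline
projects ~98% of QTLs, places consensus positions with mean absolute
error well under 1 cM, and covers ~95% of true loci with an MQTL CI;
the voted cluster count matches the truth in roughly 55–60% of
chromosome runs, with the overshoot behavior discussed above. These
problem sizes (72-record compendia, 180-marker reference maps, 100
replicates) are the package's reference settings for its own validation
runs and keep a full recovery study under two minutes on one core.

## Known limitations

* Model-order voting is liberal (see Stage 3); users who need a
  conservative locus count can inspect the per-chromosome criteria table
  (`criteriaTables()`) and follow AWE alone.
* The reference map is taken as the consensus scaffold; de novo
  marker-order consensus across conflicting maps is not implemented.
* Projection requires shared marker *names*; no fuzzy marker matching is
  attempted.
* Physical anchoring assumes anchors from the same assembly as the gene
  annotation; the package cannot detect assembly-version mismatches.
* QTLs reported twice across publications are not deduplicated.
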
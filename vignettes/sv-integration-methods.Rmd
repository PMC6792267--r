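---
title: "Breakpoint-proximity integration of structural variants with expression and methylation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint-proximity integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A somatic structural variant (SSV) joins two genomic coordinates at a
breakpoint junction. Even when neither coordinate falls inside a gene, the
rearrangement can alter nearby gene regulation: promoters lose or gain
enhancer contacts when topologically associated domains (TADs) are
disrupted, distal enhancers can be translocated next to genes that
normally lack one, and DNA from genomic regions of very different baseline
methylation is stitched next to a CpG island (CGI). `svcis` implements a
cohort-scale scan for such effects: for every gene (expression) and every
CGI probe (methylation), it asks whether samples whose breakpoints lie
near the gene systematically deviate in the measured value, above and
beyond what cancer type and copy-number alteration (CNA) explain.

# The association model

## Predictors

Two encodings of "a breakpoint near gene *g* in sample *s*" are provided.

* **Window indicator.** `window_matrix()` marks presence/absence of at
  least one breakpoint in a fixed region. The canonical regions are
  0–20, 20–50 and 50–100 kb on each side plus the gene body. Windows are
  half-open in distance space (`near <= d < far`), so the three flank
  windows partition each flank; the gene body (both boundaries inclusive)
  owns its breakpoints exclusively — a body breakpoint is never also a
  flank hit. Upstream windows are anchored at the strand-aware gene start
  and downstream windows at the strand-aware gene end. Anchoring
  downstream windows at the start instead would leave them entirely inside
  the body for genes longer than the window, and the body/flank
  disjointness rule would empty them; end-anchoring keeps each region
  meaningful for genes of any length. An `stranded = FALSE` switch gives
  plain left/right windows.
* **Distance metric.** `distance_matrix()` records the distance from the
  closest same-chromosome breakpoint to the gene start, capped at 1 Mb;
  samples with no breakpoint within 1 Mb are imputed at the cap. The
  engine models `log2 d`; a breakpoint exactly at the gene start is stored
  as 1 bp so the log is defined. The single per-gene test over the ±1 Mb
  region avoids multiple testing across adjacent windows and lets sparse
  per-cancer-type cohorts be scanned.

## Response transforms and fit

Expression is modelled as `log2(x + 1)` (the pseudocount makes zero counts
finite and is configurable); methylation beta values are clamped into
`[1e-3, 1 - 1e-3]` and logit-transformed — both standard variance-
stabilising choices for linear modelling of these data types. Each feature
is fit by ordinary least squares against the predictor plus covariates,
with a two-sided *t* test on the predictor coefficient. Covariates:
cancer type or project (dummy-coded; within a single cancer type the
cancer-type covariate collapses to the project, which still captures
processing differences between cohorts that share a tissue), gene-level
CNA (the feature's own log2 tumor/normal ratio), WGS coverage class
(low-pass sequencing detects fewer SSVs), purity, ploidy, age, total
breakpoint count, overall methylation, and the feature's own breakpoint
distance (for burden scans). Missing numeric covariates are mean-imputed
within the scan and flagged on the result object.

Conventions and edge cases:

* **min-3 carriers.** A feature is tested only when at least three samples
  carry a breakpoint in the scanned region (window mode: 1-entries;
  distance mode: entries below the cap). Features below 80% non-missing
  response values are skipped.
* **Direction.** A breakpoint-associated *increase* is reported as `+`:
  for the distance predictor, where proximity means a *smaller* value, the
  coefficient sign is negated.
* **Degeneracy.** Constant predictors and predictors lying in the span of
  the covariates are reported `skipped_degenerate` (the coefficient would
  not identify a breakpoint effect). Collinear covariate columns are
  dropped by QR pivoting, as `lm()` does.

## FDR and the permutation null

`storey_qvalues()` estimates the null proportion pi0 on the lambda grid
0, 0.05, …, 0.90 with a cubic smoothing spline evaluated at the largest
lambda (clamped into (0, 1]) and computes step-up q-values; at `pi0 = 1`
they coincide exactly with Benjamini–Hochberg. `permutation_null()`
re-runs a scan with the predictor's sample labels permuted as whole
columns — each patient's entire breakpoint profile moves together, so the
genome-wide breakpoint co-occurrence structure is preserved while the
link to the molecular profiles is broken — and compares the observed
nominally-significant count to the permutation distribution.

# Rearrangement context

An SSV is **TAD-disrupting** when its two breakpoints do not fall inside
the same TAD interval; inter-chromosomal SSVs always disrupt, and a
breakpoint in an inter-TAD gap counts as disrupting by default (a flag
reports gaps as a third category instead). Enrichment of disruption in a
subset of SSVs (e.g. those whose nearby gene is a scan hit and whose
carrier deviates by more than 0.4 SD from the feature median) is a 2×2
chi-squared test without continuity correction.

**Enhancer hijacking** is screened over associations between a gene and
the closest breakpoint 0–500 kb upstream whose retained flank faces away
from the gene (`-` orientation for `+`-strand genes, `+` for `-`-strand
genes), so that mate-side sequence is fused toward the promoter. An
association is flagged when (a) the gene has no applicable enhancer
(ubiquitous, or tissue tags mapped to the sample's cancer type) within
1 Mb of its start, and (b) an applicable enhancer sits on the mate's
retained flank with fused distance `|tss − breakpoint| + |mate − enhancer|`
at most 500 kb. The additive fused distance treats the junction as a
simple splice of the two retained flanks and ignores any further
rearrangement of the derivative chromosome; it is an approximation chosen
for transparency, and shrinking the budget can only remove flags.

**Rearranged-region methylation.** For each SSV–CGI association (one
closest breakpoint per probe and sample within 1 Mb), the mean
normal-tissue beta over a 50 kb window anchored at the mate breakpoint and
extending into its retained flank is compared with the normal beta of the
CGI probe itself, using a per-cancer-type normal-tissue surrogate panel;
`delta = region − CGI`. Because CGIs are normally unmethylated and the
bulk genome is methylated, `delta` is positive on average; the subsets of
associations whose probe is a scan hit with carrier deviation beyond
±0.4 SD are compared against all associations by both a Spearman rank
correlation of subset membership with delta and a Welch two-sample test —
the two statistics are labelled separately in the output because they
answer slightly different questions (monotone association versus mean
difference).

**Alteration calls.** "Altered in the carrier" means the carrier sample's
transformed value deviates more than 0.4 SD from the feature's
cross-sample median (the SD is the ordinary standard deviation about the
mean, with median centering, implemented literally); amplification and
deletion are |log2 tumor/normal| > 1.

# Burden analysis

Near-duplicate calls (both breakpoint ends strictly less than 10 bp
apart, same chromosome pair) are single-linkage collapsed to one
representative — the lowest-coordinate member — before counting; merges
across SV classes are allowed by default since duplicated calls from
different callers often disagree on class. The per-sample burden is
`log2(count + 1)`, standardised to SD-from-median units within each WGS
coverage stratum separately (low-pass sequencing systematically detects
fewer events, so a common scale would conflate coverage with biology).
Burden scans delegate to the same OLS engine with the log count as
predictor and mandatory WGS-class and project covariates; the overall
methylation of a sample (median beta over all probes) and the feature's
own breakpoint distance are available as additional covariates. Signature
scores average per-gene SD-from-median normalised log expression over a
gene set, normalised within cancer types for immune signatures (where
infiltration contrasts are within-tissue) and across samples otherwise.

# The synthetic cohort generator

`simulate_cohort()` produces the full input bundle (BEDPE, TSV matrices,
BED annotation, sample table, normal-tissue panel) plus a ground-truth
ledger. It emulates, at desk scale, the statistical structure the scans
assume:

* **Scale.** 300 samples, three cancer types, 2,000 genes with three CGI
  probes each (promoter ~0.1 baseline beta, gene body ~0.5, flanking
  ~0.8 — the genome outside CGIs is methylated), four 250 Mb chromosomes.
  The 1 Gb genome was sized so that ~60 SSVs per high-pass sample gives a
  breakpoint density of ~0.12 per Mb per sample, matching the order of
  magnitude of real pan-cancer WGS call sets (~10^5 SSVs over ~2,000
  cases on a 3 Gb genome); density, not count, is what the distance
  predictor sees.
* **SSVs.** Class mix over deletions/duplications/inversions/
  translocations, sizes log-uniform 1 kb–10 Mb, orientations consistent
  with class geometry. Per-sample counts are Poisson with log-normally
  varying rates (SD 0.5 on the log scale): real tumors differ in burden
  by orders of magnitude, and a fixed rate would make the global SSV
  index nearly degenerate within coverage strata. Low-pass samples
  detect half the events.
* **Planted effects.** 15 expression-up, 5 expression-down genes
  (±1.0 log2 in 10% of samples, breakpoints placed 1–18 kb upstream),
  10 methylation-up (promoter probe) and 10 methylation-down (gene-body
  probe) at ±1.0 logit, 20 burden-linked genes (+0.5 log2 per SD of log
  burden), two per-type "joint" genes per cancer type (type-restricted
  expression effect plus a type-wide methylation elevation), and 4 hijack
  genes among the expression-up set. Planted SSV mates span TADs with
  probability 0.9; hijack SSVs always take a distal mate (a short-range
  rearrangement cannot satisfy the no-native-enhancer-within-1-Mb
  condition) with a ubiquitous enhancer planted 50–200 kb onto the
  retained flank, and the hijack genes' 1 Mb neighbourhoods are kept
  clear of other applicable enhancers. Methylation-down mates land in
  designated 100 kb low-methylation segments of the normal panel.
* **Couplings.** Genes with a breakpoint within 100 kb gain copy
  (+1.2 log2) with probability 0.3, and expression follows CNA with a
  0.9 log2-per-unit dosage effect — so CNA is a genuine confounder that
  the scans must remove. All probes share a per-sample methylation shift
  of −0.2 logit per SD of log burden, reproducing burden-coupled global
  hypomethylation.

## What passing tests do and do not show

The generator's noise is Gaussian on the modelling scale, effects are
homogeneous across carriers, and the burden–methylation coupling is a
single shared factor. Real data violate all three (heavy-tailed
expression, heterogeneous effect sizes, multiple global methylation
programs such as CIMP and leucocyte infiltration), and real breakpoint
calls carry false positives and coverage-dependent false negatives beyond
the simple detection multiplier used here. Recovery and calibration
results on the synthetic cohorts therefore demonstrate correctness of the
machinery and its behaviour at the modelled operating point, not expected
power on any particular real cohort. One faithful nuisance is retained
deliberately: because high-burden samples have breakpoints near every
gene, the distance predictor is correlated with burden, and the
methylation scan inherits a mild excess of burden-driven negative
associations — the same confounding the covariate analyses are designed
to expose (burden-driven hits disappear when total breakpoint count or
overall methylation enters the model). Empirical-FDR accounting treats a
feature planted with any effect type as a true signal; the calibration
target is the expression scan with cancer-type and CNA covariates, whose
nulls are exactly modelled.

# Numerical and design choices

* OLS is solved by QR with pivoting; rank-deficient covariate blocks are
  dropped, and a predictor inside the covariate span (residual sum of
  squares below 1e-10 of its norm) is reported degenerate rather than
  silently refit.
* The q-value step-up is arranged so that `pi0 = 1` reproduces
  `p.adjust(p, "BH")` bit-for-bit.
* Window/distance matrices are computed by sorted-position binary search
  (`findInterval`) per sample and chromosome; interval containment for
  TADs, enhancers and panel probes uses GenomicRanges. The half-open
  window boundary semantics are pinned by exhaustive brute-force oracle
  tests.
* The vectorised rearranged-region mean (per-chromosome cumulative sums)
  is tested to agree with the scalar GenomicRanges primitive to 1e-12.
* Chi-squared overlap tests use no continuity correction, matching the
  large-count setting; when any expected cell is below 5 the test falls
  back to a one-sided Fisher test (which is also the mode used for
  gene-set enrichment). The overlap universe is the intersection of
  features tested in both analyses, and is configurable.
* Collapsing tolerance is a strict `< 10` bases on both ends; collapsing
  is idempotent by construction (single-linkage components).
* Pipeline stages fan the one config seed out per stage, so adding a
  stage does not shift another stage's random stream; re-running with the
  same config and inputs reproduces identical manifests.
* Default thresholds: FDR 5% pan-cancer, 10% per-type, 0.1% for
  type-differential methylation, ±0.4 SD alteration deviation, ±1 log2
  amplification/deletion, 1 Mb distance cap, 500 kb hijack budget, 1 Mb
  native-enhancer radius, 50 kb methylome window, 10 bp collapse.

## Problem sizes used in the test suite

Unit tests run on 60–150-sample, 150-gene cohorts; power-dependent
properties (joint-gene recovery, burden-module recovery) use 200–300
samples, and the calibration and recovery checks run the default
300 × 2,000 configuration, with the empirical-FDR check averaging 20
seeded replicates. These sizes were chosen so each property is tested at
the scale where its expected behaviour holds with comfortable margin.

# Known limitations

* BEDPE is the only SSV input dialect; no VCF SV parsing, no liftover.
* The hijack flag evaluates a single junction; chains of rearrangements
  (chromothripsis-like derivatives) are out of scope.
* Per-type scans with very small types are underpowered by design; the
  min-carrier rule, not the engine, is the binding constraint there.
* Mixed models, robust regression and moderated variance estimators are
  deliberately absent: the per-feature OLS with explicit covariates is
  the model this framework defines.
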
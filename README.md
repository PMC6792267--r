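# svcis

Integration of somatic structural variant (SSV) breakpoints with gene
expression and CpG-island (CGI) DNA methylation across cancer cohorts.

Whole-genome sequencing of tumors yields catalogs of SSVs — rearrangements
joining two genomic coordinates at a breakpoint junction. Breakpoints
landing near a gene can deregulate it without altering its coding sequence:
by removing or repositioning *cis*-regulatory elements, disrupting the
topologically associated domain (TAD) that confines its enhancer contacts,
hijacking a distal enhancer onto the derivative chromosome, or rearranging
DNA from a region whose normal methylation level differs sharply from the
gene's own CGI. `svcis` is for computational cancer-genomics groups who
have per-sample breakpoint calls (BEDPE), expression and 450K-style
methylation matrices, gene-level copy-number (CNA) ratios and sample
metadata, and want to scan every gene and CGI probe for recurrent
breakpoint-proximity associations while controlling for cancer type, copy
number and technical covariates.

## The model

Two gene-by-sample breakpoint predictors are built from the calls:

* **Genomic region windows** — for a window *w* relative to the gene
  (0–20, 20–50, 50–100 kb upstream or downstream, or the gene body),
  `x_gs = 1` if sample *s* has at least one breakpoint in *w* of gene *g*.
* **Distance metric** — `d_gs = min_b |pos_b − tss_g|`, the distance from
  the closest same-chromosome breakpoint to the gene start, capped and
  imputed at 1 Mb; the predictor is `log2 d_gs`.

For each feature the engine fits ordinary least squares

```
y_gs = β0 + β1 x_gs (or log2 d_gs) + γ' c_s + ε
```

with `y` log2(expression + 1) or logit(beta) and covariates `c` drawn from
cancer type/project, gene-level CNA, WGS coverage class, purity, ploidy,
age, total breakpoint count and overall methylation. A two-sided *t* test
on `β1` gives per-feature p-values; false-discovery rates are
Storey–Tibshirani q-values, and a patient-shuffling permutation null
(breakpoint profiles permuted as whole columns) checks the FDR estimates.
Features are tested only with ≥ 3 breakpoint carriers. Downstream layers
classify SSVs as TAD-disrupting (breakpoints not sharing a TAD), flag
orientation-consistent enhancer hijacks (no native enhancer within 1 Mb,
fused gene-to-enhancer distance ≤ 500 kb through the junction), compare
normal-tissue methylation of the rearranged region (50 kb at the mate
breakpoint) with the CGI near the gene, and correlate every feature with
the per-sample structural-variation burden (log2 SSV count standardized
within WGS coverage strata).

A first-class synthetic-cohort generator (`simulate_cohort()`) emulates
these data — planted cis effects, CNA–breakpoint coupling, TAD-spanning
rearrangements, hijack geometry, burden-coupled hypomethylation — with a
ground-truth ledger for recovery benchmarking.

## Worked example

```r
library(svcis)

co <- simulate_cohort(sim_config(seed = 1))   # 300 samples, 2000 genes
D  <- distance_matrix(co$bps, co$genes, samples = co$sample_info$sample_id)
sc <- sv_scan(co$expr, D, co$sample_info,
              config = scan_config(covariates = c("cancer_type", "cna")),
              cna = co$cna)
sc
#> sv_scan [log2_distance predictor] over 300 samples
#>   features: 2000 tested, 0 skipped (min carriers), 0 skipped (degenerate)
#>   significant at FDR < 5%: 21 (+15 / -6); pi0 = 0.927
evaluate_recovery(co$truth, sc, 0.05, c("expr_up", "expr_down"))[c("recall", "sign_accuracy")]
#> $recall
#> [1] 0.75
#> $sign_accuracy
#> [1] 1
```

The scan recovers 15 of the 20 planted expression effects (15 up-, 5
down-regulated, 1.0 log2 units in 10% of samples) at FDR < 5% for this
seed (the recall averaged over 20 replicates is 0.82), with the direction
of every discovery matching the planted sign; the handful of additional
hits are breakpoint-coupled burden genes. `run_pipeline(co)`
executes the full stage graph (features → scans → overlap → TAD/enhancer
context → methylome shift → burden) and `write_report()` prints the
direction counts, hijack percentages and beta-shift summaries.

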
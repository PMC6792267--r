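# Association engine: OLS fits, q-values, scans, permutation null.

test_that("single-feature fit matches the normal-equations oracle", {
  # the worked 4-point example: slope is exactly 1
  fit <- fit_feature_association(c(1, 2, 2, 3), c(0, 1, 1, 2))
  expect_equal(fit$coefficient, 1.0)
  expect_equal(fit$status, "tested")

  set.seed(1)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    p <- sample(0:4, 1)
    x <- rnorm(n)
    C <- if (p > 0) matrix(rnorm(n * p), n) else NULL
    y <- rnorm(n)
    fit <- fit_feature_association(y, x, C)
    orc <- oracle_ols(y, x, C)
    expect_equal(fit$coefficient, unname(orc$coef), tolerance = 1e-10)
    expect_equal(fit$se, unname(orc$se), tolerance = 1e-10)
    expect_equal(fit$p, unname(orc$p), tolerance = 1e-10)
  }
})

test_that("degenerate predictors and aliased designs are skipped", {
  y <- rnorm(20)
  expect_equal(fit_feature_association(y, rep(0, 20))$status,
               "skipped_degenerate")
  # predictor identical to a covariate column: aliased
  x <- rnorm(20)
  fit <- fit_feature_association(y, x, cbind(x))
  expect_equal(fit$status, "skipped_degenerate")
  # collinear covariates are dropped but the fit proceeds
  C <- cbind(a = rnorm(20))
  fit2 <- fit_feature_association(y, x, cbind(C, b = 2 * C[, 1]))
  expect_equal(fit2$status, "tested")
  expect_equal(fit2$coefficient,
               fit_feature_association(y, x, C)$coefficient)
})

test_that("a confounder-driven response shows no predictor effect", {
  # y depends only on covariate c; x is independent of y given c
  hits <- vapply(1:100, function(seed) {
    set.seed(seed)
    c_ <- rnorm(200)
    y <- 2 * c_ + rnorm(200)
    x <- 0.5 * c_ + rnorm(200)
    fit <- fit_feature_association(y, x, cbind(c_))
    abs(fit$coefficient) < 3 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("direction convention: closer breakpoint raising response is '+'", {
  set.seed(2)
  d <- runif(100, 10, 20)        # log2 distance
  y <- -0.5 * d + rnorm(100, 0, 0.1)  # closer (small d) => larger y
  fit <- fit_feature_association(y, d, predictor = "log2_distance")
  expect_lt(fit$coefficient, 0)
  expect_equal(fit$direction, "+")
  fitb <- fit_feature_association(y, d, predictor = "binary")
  expect_equal(fitb$direction, "-")
})

test_that("Storey q-values reduce to BH at pi0 = 1 and estimate pi0 sanely", {
  expect_error(storey_qvalues(numeric(0)), "empty")
  expect_error(storey_qvalues(c(0.5, 1.2)), "0, 1")

  all_one <- storey_qvalues(rep(1, 50))
  expect_true(all(all_one$q == 1))
  expect_equal(all_one$pi0, 1)

  set.seed(5)
  p <- runif(500)^1.5  # enriched near 0
  expect_equal(storey_qvalues(p, pi0 = 1)$q, p.adjust(p, "BH"))

  set.seed(9)
  u <- runif(1000)
  qv <- storey_qvalues(u)
  expect_gte(qv$pi0, 0.85)
  expect_lte(qv$pi0, 1)
  # q monotone non-decreasing in p
  o <- order(u)
  expect_true(all(diff(qv$q[o]) >= -1e-12))
  # never below the pi0-scaled BH baseline
  expect_true(all(qv$q >= qv$pi0 * p.adjust(u, "BH") - 1e-12))
})

test_that("scan applies carrier rules, transforms, and is order-invariant", {
  co <- simulate_cohort(small_cfg(seed = 3))
  D <- distance_matrix(co$bps, co$genes, samples = co$sample_info$sample_id)
  cfg <- scan_config(covariates = c("cancer_type", "cna"))
  sc <- sv_scan(co$expr, D, co$sample_info, config = cfg, cna = co$cna)
  r <- sc$results
  expect_equal(nrow(r), nrow(co$expr))
  # min-carriers rule: tested features have >= 3 entries below the cap
  expect_true(all(r$n_carriers[r$status == "tested"] >= 3))
  expect_true(all(r$status[r$n_carriers < 3] == "skipped_min_carriers"))
  # q only on tested features
  expect_true(all(is.na(r$q_value[r$status != "tested"])))

  # permuting feature and sample order leaves results unchanged
  perm_f <- sample(rownames(co$expr))
  perm_s <- sample(colnames(co$expr))
  sc2 <- sv_scan(co$expr[perm_f, perm_s], D, co$sample_info,
                 config = cfg, cna = co$cna)
  r2 <- sc2$results[match(r$feature_id, sc2$results$feature_id), ]
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-12)
  expect_equal(r2$coefficient, r$coefficient, tolerance = 1e-12)
})

test_that("a two-carrier feature is skipped under the min-3 rule", {
  genes <- toy_genes()
  bps <- toy_bps(c("s1", "s2"), "chr1", rep(genes$tss[1] - 5000, 2),
                 pos2 = c(5e6, 6e6))
  D <- distance_matrix(bps, genes, samples = paste0("s", 1:10))
  si <- data.frame(sample_id = paste0("s", 1:10), project = "p",
                   cancer_type = rep(c("a", "b"), 5), wgs_pass = "high")
  expr <- omics_matrix(matrix(2^rnorm(30, 6), 3, 10,
                              dimnames = list(genes$gene_id, si$sample_id)),
                       "expression")
  sc <- sv_scan(expr, D, si, config = scan_config())
  expect_equal(sc$results$status[sc$results$feature_id == "gA"],
               "skipped_min_carriers")
  expect_error(sv_scan(expr, D, si, samples = "none_such"), "empty sample")
})

test_that("permutation null is deterministic and matches the observed null", {
  co <- simulate_cohort(null_sim_config(n_samples = 60, n_genes = 1000,
                                        ssv_rate = 25, n_chrom = 2,
                                        chrom_length = 1.2e8,
                                        n_enhancers = 50, n_low_regions = 5,
                                        seed = 8))
  D <- distance_matrix(co$bps, co$genes, samples = co$sample_info$sample_id)
  cfg <- scan_config(covariates = c("cancer_type", "cna"))
  pn <- permutation_null(co$expr, D, co$sample_info, n_perm = 50, seed = 4,
                         config = cfg, cna = co$cna)
  pn2 <- permutation_null(co$expr, D, co$sample_info, n_perm = 5, seed = 4,
                          config = cfg, cna = co$cna)
  expect_identical(pn$perm_counts[1:5], pn2$perm_counts)
  expect_error(permutation_null(co$expr, D, co$sample_info, n_perm = 0),
               "n_perm")
  # on a null cohort the observed significant fraction matches the
  # permutation distribution
  expect_gt(pn$observed / mean(pn$perm_counts), 0.8)
  expect_lt(pn$observed / mean(pn$perm_counts), 1.25)
})

test_that("planted effects push the observed count past every permutation", {
  co <- simulate_cohort(small_cfg(seed = 12, effect_expr = 2))
  keep <- unique(c(co$truth$features$gene_id[
    co$truth$features$effect_type %in% c("expr_up", "expr_down")],
    rownames(co$expr)[1:40]))
  expr_sub <- co$expr[intersect(rownames(co$expr), keep), ]
  expr_sub <- omics_matrix(expr_sub, "expression")
  D <- distance_matrix(co$bps, co$genes, samples = co$sample_info$sample_id)
  pn <- permutation_null(expr_sub, D, co$sample_info, n_perm = 30, seed = 2,
                         config = scan_config(covariates = c("cancer_type", "cna")),
                         cna = co$cna)
  expect_gt(pn$observed, max(pn$perm_counts))
})
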
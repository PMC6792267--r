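# Rearranged-region methylation versus the nearby CGI.

toy_panel <- function() {
  probes <- data.frame(
    probe_id = c(paste0("w", 1:6), "cgi1", "far1"),
    chrom = "chr1",
    pos = c(seq(955000, 996000, length.out = 6), 2000300, 5e6),
    stringsAsFactors = FALSE)
  beta <- cbind(breast_normal = c(rep(0.8, 6), 0.1, 0.5),
                lung_normal = c(rep(0.6, 6), 0.2, 0.5))
  normal_panel(probes, beta)
}

test_that("rearranged-region mean follows orientation and the enumeration oracle", {
  panel <- toy_panel()
  # '+' orientation keeps the lower flank: [950000, 1000000] holds w1..w6
  expect_equal(rearranged_region_beta("chr1", 1000000, "+", panel,
                                      "breast_normal"), 0.8)
  # '-' keeps the upper flank: no probes there
  expect_true(is.na(rearranged_region_beta("chr1", 1000000, "-", panel,
                                           "breast_normal")))
  # partial window: only the probes actually inside count
  got <- rearranged_region_beta("chr1", 980000, "+", panel, "lung_normal")
  inside <- panel$probes$pos >= 930000 & panel$probes$pos <= 980000
  expect_equal(got, mean(panel$beta[inside, "lung_normal"]))
  expect_error(rearranged_region_beta("chr1", 1e6, "+", panel, "nope"),
               "unknown tissue")
})

test_that("beta shift records and subset means match a hand enumeration", {
  panel <- toy_panel()
  si <- data.frame(sample_id = c("sA", "sB"), project = "p",
                   cancer_type = c("breast", "lung"), wgs_pass = "high")
  tissue_map <- data.frame(cancer_type = c("breast", "lung"),
                           tissue = c("breast_normal", "lung_normal"))
  assoc <- data.frame(
    probe_id = "cgi1", gene_id = "g1", sample_id = c("sA", "sB"),
    ssv_id = c("v1", "v2"), bp_chrom = "chr1", bp_pos = 2.1e6,
    mate_chrom = "chr1", mate_pos = 1000000, mate_orient = "+",
    dist = 1e5, stringsAsFactors = FALSE)
  sh <- ssv_cgi_beta_shift(assoc, panel, tissue_map, si)
  # breast: region 0.8 vs CGI 0.1 -> +0.7 ; lung: 0.6 vs 0.2 -> +0.4
  expect_equal(sh$records$delta, c(0.7, 0.4))
  expect_equal(sh$summary$mean_delta[sh$summary$subset == "all"], 0.55)
  expect_equal(sh$summary$se_delta[sh$summary$subset == "all"],
               sd(c(0.7, 0.4)) / sqrt(2))
  expect_error(ssv_cgi_beta_shift(assoc[0, ], panel, tissue_map, si), "empty")
  # unmapped cancer type is dropped with a warning
  si2 <- si
  si2$cancer_type[2] <- "mystery"
  expect_warning(sh2 <- ssv_cgi_beta_shift(assoc, panel, tissue_map, si2),
                 "surrogate")
  expect_equal(nrow(sh2$records), 1)
})

test_that("a flat normal methylome gives zero deltas everywhere", {
  probes <- data.frame(probe_id = paste0("p", 1:50), chrom = "chr1",
                       pos = seq(1e5, 5e6, length.out = 50))
  panel <- normal_panel(probes, cbind(t_normal = rep(0.42, 50)))
  si <- data.frame(sample_id = "s1", project = "p", cancer_type = "t",
                   wgs_pass = "high")
  tm <- data.frame(cancer_type = "t", tissue = "t_normal")
  assoc <- data.frame(probe_id = paste0("p", c(5, 20, 40)), gene_id = "g",
                      sample_id = "s1", ssv_id = paste0("v", 1:3),
                      bp_chrom = "chr1", bp_pos = 1e6, mate_chrom = "chr1",
                      mate_pos = c(1e6, 2e6, 4e6), mate_orient = "+",
                      dist = 1e4, stringsAsFactors = FALSE)
  sh <- ssv_cgi_beta_shift(assoc, panel, tm, si)
  expect_true(all(abs(sh$records$delta) < 1e-12))
})

test_that("records are invariant to association input order", {
  co <- simulate_cohort(small_cfg(seed = 5))
  assoc <- build_cgi_associations(co$bps, co$genes, co$probes,
                                  co$sample_info$sample_id)
  assoc_shuffled <- assoc[sample(nrow(assoc)), ]
  sh1 <- ssv_cgi_beta_shift(assoc, co$panel, co$tissue_map, co$sample_info)
  sh2 <- ssv_cgi_beta_shift(assoc_shuffled, co$panel, co$tissue_map,
                            co$sample_info)
  key <- function(x) x[order(x$probe_id, x$sample_id, x$ssv_id), "delta"]
  expect_equal(key(sh1$records), key(sh2$records))
  expect_equal(sh1$summary$mean_delta, sh2$summary$mean_delta)
})

test_that("closest-breakpoint association keeps one breakpoint per probe and sample", {
  genes <- toy_genes()
  probes <- probe_table(data.frame(
    probe_id = "pr1", chrom = "chr1", pos = 999700, cgi_id = "c1",
    gene_id = "gA", region_class = "promoter"))
  bps <- toy_bps(rep("s1", 2), "chr1", c(1e6 - 4e4, 1e6 - 2e4),
                 pos2 = c(5e6, 7e6))
  assoc <- build_cgi_associations(bps, genes, probes)
  expect_equal(nrow(assoc), 1)
  expect_equal(assoc$dist, 2e4)
  expect_equal(assoc$mate_pos, 7e6)
})

test_that("rearrangements planted into low-methylation segments have low deltas", {
  co <- simulate_cohort(small_cfg(seed = 23, n_samples = 150))
  assoc <- build_cgi_associations(co$bps, co$genes, co$probes,
                                  co$sample_info$sample_id)
  sh <- ssv_cgi_beta_shift(assoc, co$panel, co$tissue_map, co$sample_info)
  rec <- sh$records
  md_probes <- co$truth$features$feature_id[
    co$truth$features$effect_type == "meth_down"]
  planted <- rec$probe_id %in% md_probes &
    grepl("p_meth_down", rec$ssv_id)
  expect_gt(sum(planted), 10)
  expect_lt(mean(rec$delta[planted], na.rm = TRUE),
            mean(rec$delta, na.rm = TRUE) - 0.1)
})

test_that("the hypo-altered subset shows a depressed beta shift at cohort scale", {
  co <- simulate_cohort(sim_config(seed = 7))
  D <- distance_matrix(co$bps, co$genes, samples = co$sample_info$sample_id)
  fmap <- setNames(co$probes$gene_id, co$probes$probe_id)
  scm <- sv_scan(co$meth, D, co$sample_info,
                 config = scan_config(covariates = c("cancer_type", "cna")),
                 cna = co$cna, feature_map = fmap)
  alt <- alteration_calls(co$meth, co$sample_info$sample_id)
  assoc <- build_cgi_associations(co$bps, co$genes, co$probes,
                                  co$sample_info$sample_id)
  sh <- ssv_cgi_beta_shift(assoc, co$panel, co$tissue_map, co$sample_info,
                           scan = scm, alterations = alt)
  s <- sh$summary
  expect_lt(s$mean_delta[s$subset == "cancer_hypo"],
            s$mean_delta[s$subset == "all"])
  expect_lt(s$two_sample_p[s$subset == "cancer_hypo"], 0.01)
  expect_gt(s$mean_delta[s$subset == "cancer_hyper"],
            s$mean_delta[s$subset == "all"])
})
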
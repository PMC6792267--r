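# TAD disruption, alteration calls, enhancer hijacking.

toy_tads <- function() {
  data.frame(chrom = c("chr1", "chr1", "chr2"),
             start = c(0, 200000, 0), end = c(100000, 300000, 150000))
}

test_that("TAD classification follows the rule table over all placements", {
  tads <- toy_tads()
  place <- function(p1, p2, c1 = "chr1", c2 = "chr1") {
    classify_tad_disruption(toy_bps("s1", c1, p1, c2, p2), tads)
  }
  expect_equal(place(10, 90000), "non_disrupting")       # same TAD
  expect_equal(place(10, 250000), "disrupting")          # two TADs
  expect_equal(place(150000, 50000), "disrupting")       # one end in a gap
  expect_equal(place(10, 50000, c2 = "chr2"), "disrupting")  # inter-chromosomal
  expect_equal(place(150000, 160000), "disrupting")      # both in gap
  gp <- classify_tad_disruption(toy_bps("s1", "chr1", 150000, "chr1", 160000),
                                tads, gap_category = TRUE)
  expect_equal(gp, "gap")
  # symmetric in the two breakpoints (normalisation swaps ends)
  expect_equal(place(250000, 10), place(10, 250000))
  expect_error(classify_tad_disruption(
    toy_bps("s1", "chr1", 10, "chr1", 20),
    data.frame(chrom = "chr1", start = c(0, 50000), end = c(100000, 150000))),
    "overlap")
})

test_that("TAD enrichment matches the hand 2x2 chi-squared", {
  disruption <- rep(c("disrupting", "non_disrupting"), c(80, 60))
  subset <- c(rep(TRUE, 30), rep(FALSE, 50), rep(TRUE, 10), rep(FALSE, 50))
  te <- tad_enrichment_test(disruption, subset)
  tab <- matrix(c(30, 10, 50, 50), 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(te$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-10)
  expect_equal(te$frac_subset, 0.75)
  # equal fractions: statistic ~ 0
  te0 <- tad_enrichment_test(rep(c("disrupting", "non_disrupting"), 50),
                             rep(c(TRUE, FALSE), each = 50))
  expect_lt(te0$statistic, 1e-10)
  expect_error(tad_enrichment_test(disruption, rep(FALSE, 140)), "empty")
})

test_that("alteration calls threshold deviations off the feature median", {
  vals <- matrix(2^c(5, 6, 7, 8, 20) - 1, 1, 5,
                 dimnames = list("g1", paste0("s", 1:5)))
  ac <- alteration_calls(omics_matrix(vals, "expression"), threshold_sd = 0.4)
  v <- log2(vals + 1)
  dev <- (v - median(v)) / sd(v)
  expect_equal(unname(ac$deviation[1, ]), unname(dev[1, ]))
  expect_equal(unname(ac$altered[1, ]), unname(ifelse(dev > 0.4, 1L,
                                                      ifelse(dev < -0.4, -1L, 0L))[1, ]))
  cna <- matrix(c(-1.5, 0, 0.5, 1.2, 2), 1, 5,
                dimnames = list("g1", paste0("s", 1:5)))
  ac2 <- alteration_calls(omics_matrix(vals, "expression"),
                          cna = omics_matrix(cna, "cna_log2"))
  expect_equal(unname(ac2$amp_del[1, ]), c(-1L, 0L, 0L, 1L, 1L))
})

test_that("enhancer hijack flags follow the orientation truth table exactly", {
  # one gene per strand, enhancers placed on controlled flanks of the mate
  genes <- gene_table(data.frame(
    gene_id = c("gp", "gm"), chrom = "chr1",
    start = c(2e6, 5e6), end = c(2.05e6, 5.05e6), strand = c("+", "-")))
  si <- data.frame(sample_id = "s1", project = "p", cancer_type = "breast",
                   wgs_pass = "high")
  # mate on chr2 at 10 Mb; enhancers on either side of it, plus one far
  # native enhancer near gp (800 kb) used in one scenario
  grid <- expand.grid(gene = c("gp", "gm"), bp_orient = c("+", "-"),
                      mate_orient = c("+", "-"), enh_side = c("below", "above"),
                      native = c(FALSE, TRUE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid$gene[i]
    gi <- genes[genes$gene_id == g, ]
    d1 <- 1e5
    bp_pos <- gi$tss + if (g == "gp") -d1 else d1
    bps <- toy_bps("s1", "chr1", bp_pos, "chr2", 1e7,
                   orient1 = grid$bp_orient[i], orient2 = grid$mate_orient[i])
    enh <- data.frame(chrom = "chr2",
                      start = if (grid$enh_side[i] == "below") 1e7 - 2e5 else 1e7 + 2e5,
                      end = NA, specificity = "ubiquitous")
    enh$end <- enh$start + 1000
    if (grid$native[i]) {
      enh <- rbind(enh, data.frame(chrom = "chr1", start = gi$tss + 8e5,
                                   end = gi$tss + 8e5 + 1000,
                                   specificity = "ubiquitous"))
    }
    assoc <- upstream_bp_associations(bps, genes)
    hj <- enhancer_hijack_scan(assoc, genes, enh, si)
    # truth table, derived independently: the association exists only when
    # the breakpoint's retained flank faces away from the gene ('-' for '+'
    # genes, '+' for '-' genes); the hijack additionally needs the enhancer
    # on the mate's retained flank ('+' keeps below, '-' keeps above),
    # fused distance 100 kb + ~200 kb <= 500 kb, and no native enhancer.
    assoc_expected <- grid$bp_orient[i] == (if (g == "gp") "-" else "+")
    hijack_expected <- assoc_expected && !grid$native[i] &&
      ((grid$mate_orient[i] == "+") == (grid$enh_side[i] == "below"))
    expect_equal(nrow(hj) == 1 && any(hj$gene_id == g), assoc_expected,
                 info = paste(unlist(grid[i, ]), collapse = "/"))
    expect_equal(any(hj$hijack), hijack_expected,
                 info = paste(unlist(grid[i, ]), collapse = "/"))
    if (hijack_expected) {
      d2 <- if (grid$enh_side[i] == "below") 2e5 - 500 else 2e5 + 500
      expect_equal(hj$fused_dist, d1 + d2)
    }
  }
})

test_that("native enhancers within 1 Mb veto the hijack; tighter budgets are monotone", {
  genes <- gene_table(data.frame(gene_id = "gp", chrom = "chr1",
                                 start = 2e6, end = 2.05e6, strand = "+"))
  si <- data.frame(sample_id = "s1", project = "p", cancer_type = "breast",
                   wgs_pass = "high")
  bps <- toy_bps("s1", "chr1", 2e6 - 1e5, "chr2", 1e7,
                 orient1 = "-", orient2 = "+")
  assoc <- upstream_bp_associations(bps, genes)
  enh_near <- data.frame(chrom = c("chr2", "chr1"),
                         start = c(1e7 - 2e5, 2e6 + 8e5),
                         end = c(1e7 - 2e5 + 1000, 2e6 + 8e5 + 1000),
                         specificity = "ubiquitous")
  hj <- enhancer_hijack_scan(assoc, genes, enh_near, si)
  expect_true(hj$native_enh)
  expect_false(hj$hijack)
  # remove the native enhancer: hijack at 500 kb budget but not at 200 kb
  hj2 <- enhancer_hijack_scan(assoc, genes, enh_near[1, ], si)
  expect_true(hj2$hijack)
  hj3 <- enhancer_hijack_scan(assoc, genes, enh_near[1, ], si,
                              fusion_budget = 2e5)
  expect_false(hj3$hijack)
})

test_that("tissue-specific enhancers apply only to matching cancer types", {
  genes <- gene_table(data.frame(gene_id = "gp", chrom = "chr1",
                                 start = 2e6, end = 2.05e6, strand = "+"))
  si <- data.frame(sample_id = c("s1", "s2"), project = "p",
                   cancer_type = c("breast", "lung"), wgs_pass = "high")
  type_map <- data.frame(cancer_type = "breast", tag = "mammary")
  bps <- toy_bps(c("s1", "s2"), "chr1", rep(2e6 - 1e5, 2), "chr2", rep(1e7, 2),
                 orient1 = "-", orient2 = "+")
  enh <- data.frame(chrom = "chr2", start = 1e7 - 2e5, end = 1e7 - 2e5 + 1000,
                    specificity = "mammary")
  hj <- enhancer_hijack_scan(upstream_bp_associations(bps, genes),
                             genes, enh, si, type_map)
  expect_equal(hj$hijack[hj$sample_id == "s1"], TRUE)
  expect_equal(hj$hijack[hj$sample_id == "s2"], FALSE)
})

test_that("hijack percentages are subset-invariant under random labels", {
  set.seed(41)
  n <- 5000
  genes_ids <- sprintf("g%03d", 1:200)
  hijacks <- data.frame(gene_id = sample(genes_ids, n, TRUE),
                        sample_id = sample(sprintf("s%03d", 1:100), n, TRUE),
                        hijack = runif(n) < 0.08, stringsAsFactors = FALSE)
  # random alteration labels via a minimal alteration_calls-shaped object
  alt <- structure(list(
    altered = matrix(sample(c(-1L, 0L, 1L), 200 * 100, TRUE),
                     200, 100, dimnames = list(genes_ids, sprintf("s%03d", 1:100))),
    threshold_sd = 0.4), class = "alteration_calls")
  scan <- structure(list(results = data.frame(
    feature_id = genes_ids, status = "tested",
    q_value = runif(200, 0, 0.04), stringsAsFactors = FALSE)),
    class = "sv_scan")
  hs <- hijack_summary(hijacks, scan, alt)
  overall <- hs$pct_hijack[hs$subset == "all"]
  expect_lt(abs(hs$pct_hijack[hs$subset == "up"] - overall), 2)
  expect_lt(abs(hs$pct_hijack[hs$subset == "down"] - overall), 2)
})
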
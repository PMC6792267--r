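# SSV collapsing, burden profiles, signature scores, burden scans.

test_that("collapsing merges duplicates under the strict <10 bp rule", {
  mk <- function(p1a, p2a, p1b, p2b) {
    breakpoint_set(data.frame(
      sample_id = "s1", chrom1 = "chr1", pos1 = c(p1a, p1b), orient1 = "+",
      chrom2 = "chr1", pos2 = c(p2a, p2b), orient2 = "-"))
  }
  expect_equal(nrow(collapse_ssvs(mk(100, 5000, 100, 5000))), 1)
  expect_equal(nrow(collapse_ssvs(mk(100, 5000, 109, 5009))), 1)  # 9 bp apart
  expect_equal(nrow(collapse_ssvs(mk(100, 5000, 110, 5010))), 2)  # 10 bp: kept
  expect_equal(nrow(collapse_ssvs(mk(100, 5000, 105, 5020))), 2)  # one end far
  # representative is the lowest-coordinate member
  expect_equal(collapse_ssvs(mk(109, 5009, 100, 5000))$pos1, 100)
  expect_error(collapse_ssvs(mk(1, 2, 3, 4), tol = -1), "non-negative")
})

test_that("collapsing matches a brute-force single-linkage oracle and is idempotent", {
  set.seed(13)
  base_p1 <- sample(1e6, 30)
  jitter <- function(p, k) p + sample(-12:12, k, replace = TRUE)
  n_dup <- sample(1:3, 30, replace = TRUE)
  df <- data.frame(
    sample_id = rep("s1", sum(n_dup)),
    chrom1 = "chr1", pos1 = jitter(rep(base_p1, n_dup), sum(n_dup)),
    orient1 = "+", chrom2 = "chr1",
    pos2 = jitter(rep(base_p1 + 5e4, n_dup), sum(n_dup)), orient2 = "-",
    stringsAsFactors = FALSE)
  bps <- breakpoint_set(df)
  col <- collapse_ssvs(bps)
  # oracle: BFS over the strict-<10 adjacency graph
  n <- nrow(bps)
  adj <- outer(bps$pos1, bps$pos1, function(a, b) abs(a - b) < 10) &
    outer(bps$pos2, bps$pos2, function(a, b) abs(a - b) < 10)
  comp <- rep(NA_integer_, n)
  k <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- k
      frontier <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0),
                          which(!is.na(comp)))
    }
  }
  expect_equal(nrow(col), k)
  # representatives are exactly the per-component minima
  reps <- vapply(seq_len(k), function(cc) {
    idx <- which(comp == cc)
    idx[order(bps$pos1[idx], bps$pos2[idx])][1]
  }, integer(1))
  expect_setequal(col$pos1, bps$pos1[reps])
  # idempotence
  expect_equal(nrow(collapse_ssvs(col)), nrow(col))
})

test_that("burden profile standardises within WGS strata", {
  si <- data.frame(sample_id = paste0("s", 1:7), project = "p",
                   cancer_type = "t",
                   wgs_pass = c(rep("low", 4), rep("high", 3)))
  counts <- c(4, 9, 19, 39, 80, 80, 80)
  rows <- do.call(rbind, lapply(seq_along(counts), function(i) {
    data.frame(sample_id = si$sample_id[i], chrom1 = "chr1",
               pos1 = seq_len(counts[i]) * 1000, orient1 = "+",
               chrom2 = "chr1", pos2 = seq_len(counts[i]) * 1000 + 5e4,
               orient2 = "-")
  }))
  expect_warning(bp <- burden_profile(breakpoint_set(rows), si),
                 "zero-variance")
  expect_equal(bp$total_ssv, counts)
  x <- log2(counts[1:4] + 1)
  expect_equal(bp$global_ssv_index[1:4], (x - median(x)) / sd(x))
  expect_equal(bp$global_ssv_index[5:7], rep(0, 3))  # degenerate stratum
  expect_equal(median(bp$global_ssv_index[1:4]), 0)
})

test_that("overall methylation and CNA indices are the median and SD", {
  si <- data.frame(sample_id = "s1", project = "p", cancer_type = "t",
                   wgs_pass = "low")
  bps <- toy_bps("s1", "chr1", 1e5)
  meth <- omics_matrix(matrix(c(0.1, 0.5, 0.9), 3, 1,
                              dimnames = list(paste0("p", 1:3), "s1")),
                       "methylation_beta")
  cna <- omics_matrix(matrix(c(-1, 0, 1, 2), 4, 1,
                             dimnames = list(paste0("g", 1:4), "s1")),
                      "cna_log2")
  bp <- suppressWarnings(burden_profile(bps, si, meth = meth, cna = cna))
  expect_equal(bp$overall_methylation, 0.5)
  expect_equal(bp$overall_cna, sd(c(-1, 0, 1, 2)))
})

test_that("signature scores equal means of normalised member values", {
  set.seed(19)
  expr <- omics_matrix(
    matrix(2^rnorm(200, 6) - 1, 10, 20,
           dimnames = list(paste0("g", 1:10), paste0("s", 1:20))),
    "expression")
  si <- data.frame(sample_id = paste0("s", 1:20), project = "p",
                   cancer_type = rep(c("a", "b"), 10), wgs_pass = "high")
  # enumeration oracle over an explicit normalisation
  v <- log2(expr[paste0("g", 1:4), ] + 1)
  z <- t(apply(v, 1, function(r) (r - median(r)) / sd(r)))
  sc <- signature_score(expr, paste0("g", 1:4), set_name = "sig4")
  expect_equal(unname(sc$score), unname(colMeans(z)))
  # singleton score equals the gene's own normalised value
  r7 <- log2(expr["g7", ] + 1)
  s1 <- signature_score(expr, "g7")
  expect_equal(unname(s1$score), unname((r7 - median(r7)) / sd(r7)))
  # set score is the mean of singleton scores
  singles <- sapply(paste0("g", 1:4), function(g) signature_score(expr, g)$score)
  expect_equal(unname(sc$score), unname(rowMeans(singles)))
  # within-type normalisation uses per-type medians
  sw <- signature_score(expr, "g7", si, normalization = "within_cancer_type")
  ra <- log2(expr["g7", si$cancer_type == "a"] + 1)
  expect_equal(unname(sw$score[sw$sample_id == "s1"]),
               unname(((ra - median(ra)) / sd(ra))["s1"]))
  expect_error(signature_score(expr, c("nope1", "nope2")), "no gene")
})

test_that("burden scan uses the log count predictor with mandatory covariates", {
  co <- simulate_cohort(small_cfg(seed = 29, n_samples = 200))
  collapsed <- collapse_ssvs(co$bps)
  bp <- burden_profile(collapsed, co$sample_info, meth = co$meth)
  sc <- burden_scan(co$expr, bp, co$sample_info)
  expect_true(all(c("wgs_pass", "project") %in% sc$config$covariates))
  expect_equal(sc$predictor_type, "burden")
  # burden-linked genes rank high
  bl <- co$truth$features$feature_id[
    co$truth$features$effect_type == "burden_linked"]
  r <- sc$results
  hits <- r$feature_id[r$status == "tested" & !is.na(r$q_value) & r$q_value < 0.05]
  expect_gte(mean(bl %in% hits), 0.8)
  # constant burden: every feature degenerate
  bp0 <- bp
  bp0$total_ssv <- 50L
  sc0 <- burden_scan(co$expr, bp0, co$sample_info)
  expect_true(all(sc0$results$status == "skipped_degenerate"))
})
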
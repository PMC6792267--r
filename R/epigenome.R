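# Cancer-type differential methylation, hit-set overlap tests, and
# residualised expression-methylation correlation.

#' Differential CGI methylation of one cancer type versus the rest
#'
#' Welch two-sample t test per probe on logit-transformed (clamped) beta
#' values, one cancer type against all other scanned samples; "high in
#' type" corresponds to a positive t statistic. Probes with fewer than two
#' usable values in either group are skipped (NA statistics).
#'
#' @param meth a `methylation_beta` [omics_matrix()].
#' @param sample_info sample metadata table.
#' @param type the cancer type defining group 1.
#' @param samples optional sample subset.
#' @param clamp_eps beta clamp width before the logit.
#' @return data frame with per-probe `t`, `p`, `q` (Storey q-values over
#'   the tested probes) and group sizes; attribute `pi0`.
#' @export
differential_methylation_by_type <- function(meth, sample_info, type,
                                             samples = NULL, clamp_eps = 1e-3) {
  common <- intersect(colnames(meth), sample_info$sample_id)
  if (!is.null(samples)) common <- intersect(common, samples)
  grp <- sample_info$cancer_type[match(common, sample_info$sample_id)] == type
  if (sum(grp) < 2 || sum(!grp) < 2) {
    stop("need at least two samples in the type and in the rest")
  }
  v <- logit_clamped(meth[, common, drop = FALSE], clamp_eps)
  res <- row_welch_t(v[, grp, drop = FALSE], v[, !grp, drop = FALSE])
  tested <- !is.na(res$p)
  q <- rep(NA_real_, length(res$p))
  pi0 <- NA_real_
  if (any(tested)) {
    qv <- storey_qvalues(res$p[tested])
    q[tested] <- qv$q
    pi0 <- qv$pi0
  }
  out <- data.frame(probe_id = rownames(meth), t = res$t, p = res$p, q = q,
                    n_type = res$n1, n_rest = res$n2,
                    stringsAsFactors = FALSE)
  attr(out, "pi0") <- pi0
  out
}

# Row-wise Welch (unequal-variance) t test; returns t, p, df and the
# per-row usable group sizes. Rows with <2 usable values in a group, or
# zero pooled variance, get NA.
row_welch_t <- function(a, b) {
  n1 <- rowSums(!is.na(a))
  n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE)
  m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- rowSums((a - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((b - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  ok <- n1 >= 2 & n2 >= 2 & se2 > 0
  t <- ifelse(ok, (m1 - m2) / sqrt(se2), NA_real_)
  df <- ifelse(ok, se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), NA_real_)
  p <- ifelse(ok, 2 * pt(-abs(t), df), NA_real_)
  # identical degenerate groups: a zero difference carries no evidence
  zero_se <- n1 >= 2 & n2 >= 2 & se2 == 0
  t[zero_se] <- 0
  p[zero_se] <- 1
  list(t = t, p = p, df = df, n1 = n1, n2 = n2)
}

#' Differential methylation for every cancer type
#'
#' @inheritParams differential_methylation_by_type
#' @param types cancer types to test (default: all with >= `min_n` samples).
#' @param min_n minimum samples per type.
#' @return named list of per-type data frames.
#' @export
differential_methylation_all_types <- function(meth, sample_info, types = NULL,
                                               samples = NULL, min_n = 10,
                                               clamp_eps = 1e-3) {
  common <- intersect(colnames(meth), sample_info$sample_id)
  if (!is.null(samples)) common <- intersect(common, samples)
  tab <- table(sample_info$cancer_type[match(common, sample_info$sample_id)])
  if (is.null(types)) types <- names(tab)[tab >= min_n]
  setNames(lapply(types, function(ty) {
    differential_methylation_by_type(meth, sample_info, ty, common, clamp_eps)
  }), types)
}

#' Overlap test between two feature sets within a universe
#'
#' Tests whether two feature sets overlap more than expected under
#' independence (`expected = |A| * |B| / |U|`). The default is a
#' chi-squared test on the 2x2 membership table (without continuity
#' correction, falling back to a one-sided Fisher test when any expected
#' cell is below 5); `mode = "fisher"` forces the one-sided Fisher test,
#' as used for gene-set enrichment.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all eligible features.
#' @param mode `"chi2"` or `"fisher"`.
#' @return an `overlap_test` list with counts, `expected_overlap`,
#'   `statistic`, `p_value` and `test_used`.
#' @export
set_overlap_test <- function(setA, setB, universe, mode = c("chi2", "fisher")) {
  mode <- match.arg(mode)
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  setA <- unique(intersect(setA, universe))
  setB <- unique(intersect(setB, universe))
  nU <- length(universe)
  nA <- length(setA)
  nB <- length(setB)
  nAB <- length(intersect(setA, setB))
  expected <- nA * nB / nU
  tab <- matrix(c(nAB, nA - nAB, nB - nAB, nU - nA - nB + nAB), 2, 2)
  exp_cells <- outer(rowSums(tab), colSums(tab)) / nU
  use_fisher <- mode == "fisher" || any(exp_cells < 5)
  if (use_fisher) {
    ft <- fisher.test(tab, alternative = "greater")
    stat <- unname(ft$estimate)
    p <- ft$p.value
    test_used <- "fisher_one_sided"
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic)
    p <- ct$p.value
    test_used <- "chi2"
  }
  structure(list(n_universe = nU, n_setA = nA, n_setB = nB, n_overlap = nAB,
                 expected_overlap = expected, statistic = stat,
                 p_value = p, test_used = test_used),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap: %d of A=%d x B=%d in universe %d (expected %.1f)\n",
              x$n_overlap, x$n_setA, x$n_setB, x$n_universe, x$expected_overlap))
  cat(sprintf("  %s: statistic = %.3g, p = %.3g\n",
              x$test_used, x$statistic, x$p_value))
  invisible(x)
}

#' Gene-set enrichment by one-sided Fisher test
#'
#' Flat gene-set enrichment of a hit list against GMT gene sets.
#'
#' @param hits character vector of significant genes.
#' @param gene_sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe all tested genes.
#' @return data frame with per-set counts, odds ratio, p and BH-free
#'   Storey q-values.
#' @export
gene_set_enrichment <- function(hits, gene_sets, universe) {
  rows <- lapply(names(gene_sets), function(nm) {
    ot <- set_overlap_test(hits, gene_sets[[nm]], universe, mode = "fisher")
    data.frame(set_name = nm, n_set = ot$n_setB, n_hits = ot$n_setA,
               n_overlap = ot$n_overlap, expected = ot$expected_overlap,
               p = ot$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- storey_qvalues(out$p, pi0 = 1)$q
  out[order(out$p), ]
}

#' Read gene sets from a GMT file
#' @param path GMT path (set name, description, then member genes per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[[`, character(1), 1))
}

#' Residualised Pearson correlation of two feature vectors
#'
#' Both vectors are residualised on the covariate matrix (OLS) and the
#' Pearson correlation of the residuals is tested with the t transform,
#' with degrees of freedom reduced by the covariate rank.
#'
#' @param y1,y2 numeric vectors (already transformed).
#' @param covariates numeric covariate matrix or NULL.
#' @return list with `r`, `t`, `df`, `p`, `n`; all NA when fewer than 4
#'   complete observations remain.
#' @export
residual_correlation <- function(y1, y2, covariates = NULL) {
  keep <- !(is.na(y1) | is.na(y2))
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  y1 <- y1[keep]
  y2 <- y2[keep]
  n <- length(y1)
  if (n < 4) return(list(r = NA_real_, t = NA_real_, df = NA_real_,
                         p = NA_real_, n = n))
  rank_c <- 0L
  if (!is.null(covariates)) {
    X <- cbind(1, covariates[keep, , drop = FALSE])
    qr_x <- qr(X)
    rank_c <- qr_x$rank - 1L
    y1 <- qr.resid(qr_x, y1)
    y2 <- qr.resid(qr_x, y2)
  }
  r <- cor(y1, y2)
  df <- n - 2 - rank_c
  if (df < 1 || is.na(r) || abs(r) >= 1) {
    t <- if (!is.na(r) && abs(r) >= 1) Inf * sign(r) else NA_real_
    p <- if (!is.na(r) && abs(r) >= 1) 0 else NA_real_
    return(list(r = r, t = t, df = df, p = p, n = n))
  }
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, t = t, df = df, p = 2 * pt(-abs(t), df), n = n)
}

#' Residualised correlation scan over feature pairs
#'
#' Applies [residual_correlation()] to each (expression gene, methylation
#' probe) pair after the kind-appropriate transforms, with Storey q-values
#' over tested pairs. Used to find genes whose expression and CGI
#' methylation are inversely correlated across samples.
#'
#' @param expr expression [omics_matrix()].
#' @param meth methylation [omics_matrix()].
#' @param pairs data frame with columns `gene_id`, `probe_id`.
#' @param sample_info sample metadata table.
#' @param covariates covariate names as in [scan_config()] (sample-level
#'   covariates only; `cna` is supported via the `cna` argument).
#' @param cna optional CNA matrix for the `cna` covariate.
#' @param clamp_eps beta clamp width.
#' @return data frame of per-pair `r`, `p`, `q`.
#' @export
residual_correlation_scan <- function(expr, meth, pairs, sample_info,
                                      covariates = "cancer_type", cna = NULL,
                                      clamp_eps = 1e-3) {
  common <- Reduce(intersect, list(colnames(expr), colnames(meth),
                                   sample_info$sample_id))
  if (!length(common)) stop("empty sample intersection")
  C0 <- build_covariate_design(setdiff(covariates, "cna"), sample_info, common)
  out <- pairs
  out$r <- out$p <- NA_real_
  out$n <- NA_integer_
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene_id[i]
    pr <- pairs$probe_id[i]
    if (!(g %in% rownames(expr)) || !(pr %in% rownames(meth))) next
    y1 <- log2(expr[g, common] + 1)
    y2 <- logit_clamped(meth[pr, common], clamp_eps)
    Cf <- C0
    if ("cna" %in% covariates && !is.null(cna) && g %in% rownames(cna)) {
      cv <- as.numeric(cna[g, common])
      cv[is.na(cv)] <- mean(cv, na.rm = TRUE)
      Cf <- cbind(Cf, cna = cv)
    }
    rc <- residual_correlation(y1, y2, Cf)
    out$r[i] <- rc$r
    out$p[i] <- rc$p
    out$n[i] <- rc$n
  }
  out$q <- NA_real_
  tested <- !is.na(out$p)
  if (any(tested)) out$q[tested] <- storey_qvalues(out$p[tested])$q
  out
}
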
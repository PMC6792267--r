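# Covariate-adjusted per-feature linear association engine.
#
# For each feature the transformed omics value is regressed on a breakpoint
# predictor (binary window indicator, log2 closest-breakpoint distance, or
# log2 total SSV count) plus covariates, with a two-sided t test on the
# predictor coefficient, Storey-Tibshirani q-values over the tested
# features, and a patient-shuffling permutation null.

#' Scan configuration
#'
#' Collects the tunable parameters of an association scan. `min_carriers`
#' implements the rule that a feature is only tested when at least three
#' samples carry a breakpoint in the scanned region (1-entries in window
#' mode; entries below the distance cap in distance mode).
#'
#' @param covariates character vector drawn from `cancer_type`, `project`,
#'   `cna`, `purity`, `ploidy`, `age`, `wgs_pass`, `total_bp_count`,
#'   `overall_methylation`, `proximal_bp`.
#' @param min_carriers minimum carrier count for a feature to be tested.
#' @param clamp_eps beta clamp width before the logit.
#' @param min_nonmissing minimum fraction of non-missing response values,
#'   over the scanned samples, for a feature to be tested.
#' @return a `scan_config` list.
#' @export
scan_config <- function(covariates = "cancer_type", min_carriers = 3,
                        clamp_eps = 1e-3, min_nonmissing = 0.8) {
  if (min_carriers < 2) stop("min_carriers must be >= 2")
  structure(list(covariates = covariates, min_carriers = min_carriers,
                 clamp_eps = clamp_eps, min_nonmissing = min_nonmissing),
            class = "scan_config")
}

#' Single-feature covariate-adjusted linear association
#'
#' Ordinary least squares fit of `y ~ x + covariates` with a two-sided t
#' test on the `x` coefficient. Rank-deficient designs are handled by
#' dropping aliased covariate columns (QR pivoting, as `lm` does); if the
#' predictor itself is constant or aliased the feature is reported as
#' degenerate. The reported direction follows the convention that a
#' breakpoint-associated *increase* in the response is `+`: for the
#' log2-distance predictor (where a closer breakpoint means a smaller
#' predictor value) the direction is the negated coefficient sign.
#'
#' @param y numeric response vector (already transformed).
#' @param x numeric predictor vector.
#' @param covariates numeric matrix of covariates (may be NULL).
#' @param predictor one of `"binary"`, `"log2_distance"`, `"burden"`;
#'   controls the sign convention only.
#' @return list with `coefficient`, `se`, `t`, `p`, `df`, `n`, `direction`,
#'   `status` (`tested` or `skipped_degenerate`) and `note`.
#' @export
fit_feature_association <- function(y, x, covariates = NULL,
                                    predictor = c("binary", "log2_distance", "burden")) {
  predictor <- match.arg(predictor)
  skip <- function(note) list(coefficient = NA_real_, se = NA_real_,
                              t = NA_real_, p = NA_real_, df = NA_integer_,
                              n = length(y), direction = NA_character_,
                              status = "skipped_degenerate", note = note)
  keep <- !(is.na(y) | is.na(x))
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  y <- y[keep]
  x <- x[keep]
  C <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
  n <- length(y)
  if (n < 4) return(skip("too few usable samples"))
  if (var(x) == 0) return(skip("constant predictor"))
  if (!is.null(C)) {
    # predictor lying in the span of the covariates is not identifiable
    rx <- qr.resid(qr(cbind(1, C)), x)
    if (sum(rx^2) < 1e-10 * sum(x^2)) {
      return(skip("predictor aliased with covariates"))
    }
  }
  X <- cbind(`(Intercept)` = 1, x = x, C)
  qr_x <- qr(X)
  r <- qr_x$rank
  pivot <- qr_x$pivot[seq_len(r)]
  if (!(2L %in% pivot)) return(skip("predictor aliased with covariates"))
  df <- n - r
  if (df < 1) return(skip("no residual degrees of freedom"))
  beta <- qr.coef(qr_x, y)
  res <- qr.resid(qr_x, y)
  sigma2 <- sum(res^2) / df
  R <- qr.R(qr_x)[seq_len(r), seq_len(r), drop = FALSE]
  xtx_inv <- chol2inv(R)
  pos <- match(2L, pivot)
  se <- sqrt(sigma2 * xtx_inv[pos, pos])
  coef_x <- beta["x"]
  tval <- if (se > 0) coef_x / se else NA_real_
  pval <- if (is.na(tval)) NA_real_ else 2 * pt(-abs(tval), df)
  sgn <- sign(coef_x)
  if (predictor == "log2_distance") sgn <- -sgn
  list(coefficient = unname(coef_x), se = unname(se), t = unname(tval),
       p = unname(pval), df = df, n = n,
       direction = if (is.na(sgn) || sgn == 0) NA_character_ else if (sgn > 0) "+" else "-",
       status = "tested", note = NA_character_)
}

# Assemble the sample-level covariate design for a scan; per-feature
# covariates (cna, proximal_bp) are appended inside the feature loop.
build_covariate_design <- function(covariates, sample_info, samples,
                                   extra = list()) {
  if (!length(covariates)) return(NULL)
  si <- sample_info[match(samples, sample_info$sample_id), , drop = FALSE]
  cols <- list()
  imputed <- character()
  for (cv in setdiff(covariates, c("cna", "proximal_bp"))) {
    v <- switch(cv,
      cancer_type = , project = , wgs_pass = {
        f <- factor(si[[cv]])
        if (nlevels(f) < 2) NULL else {
          mm <- model.matrix(~f)[, -1, drop = FALSE]
          colnames(mm) <- paste0(cv, levels(f)[-1])
          mm
        }
      },
      purity = , ploidy = , age = {
        num <- as.numeric(si[[cv]])
        if (anyNA(num)) {
          imputed <- c(imputed, cv)
          num[is.na(num)] <- mean(num, na.rm = TRUE)
        }
        matrix(num, ncol = 1, dimnames = list(NULL, cv))
      },
      total_bp_count = , overall_methylation = {
        v <- extra[[cv]]
        if (is.null(v)) stop("covariate '", cv, "' requested but not supplied")
        matrix(as.numeric(v[samples]), ncol = 1, dimnames = list(NULL, cv))
      },
      stop("unknown covariate: ", cv)
    )
    if (!is.null(v)) cols[[cv]] <- v
  }
  out <- if (length(cols)) do.call(cbind, cols) else NULL
  if (!is.null(out)) attr(out, "imputed") <- imputed
  out
}

#' Covariate-adjusted association scan over an omics matrix
#'
#' The central fitting function. Each feature of `response` is regressed
#' (after its declared transform) on the breakpoint predictor with the
#' requested covariates; q-values are computed over tested features only.
#' Methylation probes are joined to the gene-level predictor through
#' `feature_map`.
#'
#' @param response an [omics_matrix()] (features x samples).
#' @param predictor a `bp_feature_matrix` from [window_matrix()] or
#'   [distance_matrix()], or a named per-sample numeric vector (burden
#'   predictor, used as log2(count + 1)).
#' @param sample_info sample metadata table (see [read_sample_table()]).
#' @param config a [scan_config()].
#' @param cna optional `cna_log2` [omics_matrix()]; required when `cna` is
#'   among the covariates (matched to features via `feature_map`/rownames).
#' @param feature_map named character vector mapping response feature ids
#'   to gene ids of the predictor/CNA rows; NULL for direct rowname match.
#' @param samples optional explicit sample subset; default is the
#'   intersection of response, predictor and metadata samples.
#' @param extra_covariates named list of per-sample numeric vectors for the
#'   `total_bp_count` and `overall_methylation` covariates.
#' @param proximal_bp optional distance `bp_feature_matrix` supplying the
#'   per-feature `proximal_bp` covariate (its own log2 distance row).
#' @return an object of class `sv_scan`; see [print.sv_scan()].
#' @export
sv_scan <- function(response, predictor, sample_info,
                    config = scan_config(), cna = NULL, feature_map = NULL,
                    samples = NULL, extra_covariates = list(),
                    proximal_bp = NULL) {
  stopifnot(inherits(config, "scan_config"))
  pred_is_matrix <- is.matrix(predictor)
  pred_type <- if (!pred_is_matrix) "burden"
    else if (attr(predictor, "mode") == "window") "window_binary"
    else "log2_distance"
  pred_samples <- if (pred_is_matrix) colnames(predictor) else names(predictor)
  common <- Reduce(intersect, list(colnames(response), pred_samples,
                                   sample_info$sample_id))
  if (!is.null(samples)) common <- intersect(common, samples)
  if ("cna" %in% config$covariates) {
    if (is.null(cna)) stop("cna covariate requested but no CNA matrix supplied")
    common <- intersect(common, colnames(cna))
  }
  if (!length(common)) stop("empty sample intersection between inputs")
  dropped <- length(union(colnames(response), pred_samples)) - length(common)
  if (dropped > 0) svcis_log("scan over %d samples (%d dropped in join)",
                             length(common), dropped)
  transform <- attr(response, "transform") %||% "identity"
  feats <- rownames(response)
  map <- if (is.null(feature_map)) setNames(feats, feats) else feature_map[feats]
  if (pred_is_matrix) {
    has_pred <- !is.na(map) & map %in% rownames(predictor)
    if (!all(has_pred)) {
      svcis_log("%d features without a predictor row dropped", sum(!has_pred))
      feats <- feats[has_pred]
      map <- map[has_pred]
    }
  }
  C0 <- build_covariate_design(config$covariates, sample_info, common,
                               extra_covariates)
  dmax <- if (pred_is_matrix && pred_type == "log2_distance") attr(predictor, "dmax") else NA
  if (!pred_is_matrix) {
    xb <- log2(as.numeric(predictor[common]) + 1)
  }
  res_list <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[i]
    y_raw <- response[f, common]
    y <- transform_values(y_raw, transform, config$clamp_eps)
    if (pred_is_matrix) {
      xr <- predictor[map[[i]], common]
      x <- if (pred_type == "log2_distance") log2(pmax(xr, 1)) else xr
    } else {
      xr <- x <- xb
    }
    usable <- !is.na(y) & !is.na(x)
    if (mean(!is.na(y)) < config$min_nonmissing) {
      res_list[[i]] <- list(status = "skipped_degenerate",
                            note = "below min_nonmissing",
                            n = sum(usable), carriers = NA_integer_)
      next
    }
    carriers <- switch(pred_type,
      window_binary = sum(xr[usable] == 1),
      log2_distance = sum(xr[usable] < dmax),
      burden = sum(usable))
    if (pred_type != "burden" && carriers < config$min_carriers) {
      res_list[[i]] <- list(status = "skipped_min_carriers", note = NA_character_,
                            n = sum(usable), carriers = carriers)
      next
    }
    Cf <- C0
    if ("cna" %in% config$covariates) {
      g <- map[[i]]
      cna_row <- if (g %in% rownames(cna)) as.numeric(cna[g, common]) else NA_real_
      if (all(is.na(cna_row))) {
        res_list[[i]] <- list(status = "skipped_degenerate",
                              note = "no CNA values for feature",
                              n = sum(usable), carriers = carriers)
        next
      }
      cna_row[is.na(cna_row)] <- mean(cna_row, na.rm = TRUE)
      Cf <- cbind(Cf, cna = cna_row)
    }
    if ("proximal_bp" %in% config$covariates) {
      if (is.null(proximal_bp)) stop("proximal_bp covariate requested but no distance matrix supplied")
      g <- map[[i]]
      if (g %in% rownames(proximal_bp)) {
        Cf <- cbind(Cf, proximal_bp = log2(pmax(proximal_bp[g, common], 1)))
      }
    }
    fit <- fit_feature_association(
      y, x, Cf,
      predictor = switch(pred_type, window_binary = "binary",
                         log2_distance = "log2_distance", burden = "burden"))
    fit$carriers <- if (pred_type == "burden") sum(usable) else carriers
    res_list[[i]] <- fit
  }
  results <- data.frame(
    feature_id = feats,
    n_samples = vapply(res_list, function(r) as.integer(r$n), integer(1)),
    n_carriers = vapply(res_list, function(r) as.integer(r$carriers %||% NA_integer_), integer(1)),
    coefficient = vapply(res_list, function(r) r$coefficient %||% NA_real_, numeric(1)),
    se = vapply(res_list, function(r) r$se %||% NA_real_, numeric(1)),
    t_stat = vapply(res_list, function(r) r$t %||% NA_real_, numeric(1)),
    p_value = vapply(res_list, function(r) r$p %||% NA_real_, numeric(1)),
    direction = vapply(res_list, function(r) r$direction %||% NA_character_, character(1)),
    status = vapply(res_list, function(r) r$status, character(1)),
    stringsAsFactors = FALSE
  )
  tested <- results$status == "tested" & !is.na(results$p_value)
  results$q_value <- NA_real_
  pi0 <- NA_real_
  if (any(tested)) {
    qv <- storey_qvalues(results$p_value[tested])
    results$q_value[tested] <- qv$q
    pi0 <- qv$pi0
  }
  structure(list(results = results, pi0 = pi0, samples = common,
                 predictor_type = pred_type, config = config,
                 imputed_covariates = attr(C0, "imputed"),
                 call = sys.call()),
            class = "sv_scan")
}

#' @describeIn sv_scan number of tested / significant features by direction.
#' @param x,object an `sv_scan` object.
#' @param fdr q-value cutoff used by the print/summary methods.
#' @param ... unused.
#' @export
print.sv_scan <- function(x, fdr = 0.05, ...) {
  r <- x$results
  tested <- r$status == "tested"
  sig <- tested & !is.na(r$q_value) & r$q_value < fdr
  cat(sprintf("sv_scan [%s predictor] over %d samples\n",
              x$predictor_type, length(x$samples)))
  cat(sprintf("  features: %d tested, %d skipped (min carriers), %d skipped (degenerate)\n",
              sum(tested), sum(r$status == "skipped_min_carriers"),
              sum(r$status == "skipped_degenerate")))
  cat(sprintf("  significant at FDR < %g%%: %d (+%d / -%d); pi0 = %.3f\n",
              100 * fdr, sum(sig), sum(sig & r$direction == "+"),
              sum(sig & r$direction == "-"), x$pi0))
  invisible(x)
}

#' @describeIn sv_scan summary with the top-ranked features.
#' @method summary sv_scan
#' @export
summary.sv_scan <- function(object, fdr = 0.05, ...) {
  r <- object$results
  tested <- r[r$status == "tested", ]
  tested <- tested[order(tested$p_value), ]
  out <- list(scan = object, fdr = fdr,
              n_significant = sum(tested$q_value < fdr, na.rm = TRUE),
              top = head(tested, 10))
  class(out) <- "summary.sv_scan"
  out
}

#' @export
print.summary.sv_scan <- function(x, ...) {
  print(x$scan, fdr = x$fdr)
  cat("\nTop features:\n")
  print(x$top[, c("feature_id", "n_carriers", "coefficient", "t_stat",
                  "p_value", "q_value", "direction")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @describeIn sv_scan named vector of predictor coefficients (tested features).
#' @method coef sv_scan
#' @export
coef.sv_scan <- function(object, ...) {
  r <- object$results
  tested <- r$status == "tested"
  setNames(r$coefficient[tested], r$feature_id[tested])
}

#' @describeIn sv_scan volcano-style plot of oriented effect vs -log10 p.
#' @param y unused.
#' @method plot sv_scan
#' @export
plot.sv_scan <- function(x, y, fdr = 0.05, ...) {
  r <- x$results[x$results$status == "tested", ]
  eff <- r$coefficient * ifelse(x$predictor_type == "log2_distance", -1, 1)
  sig <- !is.na(r$q_value) & r$q_value < fdr
  plot(eff, -log10(r$p_value),
       col = ifelse(sig, ifelse(eff > 0, "firebrick", "navy"), "grey60"),
       pch = 16, cex = 0.5,
       xlab = "breakpoint-associated effect (oriented)",
       ylab = expression(-log[10] ~ p), ...)
  abline(h = -log10(0.05), lty = 3)
  invisible(x)
}

#' Storey-Tibshirani q-values
#'
#' Estimates the proportion of true nulls pi0 on the lambda grid
#' 0, 0.05, ..., 0.90 with a cubic smoothing spline evaluated at the
#' largest lambda (clamped into (0, 1]), then computes q-values as the
#' pi0-scaled step-up minima. With `pi0 = 1` the q-values reduce exactly
#' to Benjamini-Hochberg adjusted p-values.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param pi0 optionally force the null proportion (e.g. 1 for plain BH).
#' @param lambda grid for pi0 estimation.
#' @return list with `q` (same order as `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, pi0 = NULL, lambda = seq(0, 0.90, by = 0.05)) {
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- if (m < 2 || length(unique(pi0_l)) == 1) {
      pi0_l[length(pi0_l)]
    } else {
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      predict(fit, x = max(lambda))$y
    }
    pi0 <- min(pi0, 1)
    pi0 <- max(pi0, 1e-8)
  }
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(pi0 * (m / (m:1)) * p[o]))
  list(q = q, pi0 = pi0)
}

#' Permutation null by shuffling patient identities
#'
#' Re-runs the scan with the predictor's sample labels permuted as a unit
#' (each sample's whole breakpoint profile moves together while covariates
#' stay with the samples of the response), and compares the observed count
#' of nominally significant features to the permutation distribution.
#'
#' @inheritParams sv_scan
#' @param n_perm number of permutations (default 100).
#' @param alpha nominal p-value cutoff for the significant-feature counts.
#' @param seed RNG seed for the permutation sequence.
#' @param ... passed to [sv_scan()].
#' @return an `sv_permutation` list: observed count, per-permutation
#'   counts, and the exceedance p-value `(1 + #{perm >= obs}) / (1 + n)`.
#' @export
permutation_null <- function(response, predictor, sample_info,
                             n_perm = 100, alpha = 0.05, seed = 1, ...) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- sv_scan(response, predictor, sample_info, ...)
  count_sig <- function(sc) {
    r <- sc$results
    sum(r$status == "tested" & !is.na(r$p_value) & r$p_value < alpha)
  }
  observed <- count_sig(obs)
  n_tested <- sum(obs$results$status == "tested")
  pred_is_matrix <- is.matrix(predictor)
  ids <- if (pred_is_matrix) colnames(predictor) else names(predictor)
  set.seed(seed)
  perm_counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample(ids)
    pp <- predictor
    if (pred_is_matrix) colnames(pp) <- perm else names(pp) <- perm
    perm_counts[b] <- count_sig(sv_scan(response, pp, sample_info, ...))
  }
  structure(list(observed = observed, n_tested = n_tested,
                 perm_counts = perm_counts, alpha = alpha,
                 p_exceed = (1 + sum(perm_counts >= observed)) / (1 + n_perm)),
            class = "sv_permutation")
}

#' @export
print.sv_permutation <- function(x, ...) {
  cat(sprintf("permutation null: observed %d/%d features with p < %g\n",
              x$observed, x$n_tested, x$alpha))
  cat(sprintf("  permuted counts: mean %.1f (range %d-%d, %d permutations)\n",
              mean(x$perm_counts), min(x$perm_counts), max(x$perm_counts),
              length(x$perm_counts)))
  cat(sprintf("  exceedance p = %.4f\n", x$p_exceed))
  invisible(x)
}
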
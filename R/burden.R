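# Per-sample structural-variation burden and global molecular correlates.

#' Collapse near-duplicate SSV calls
#'
#' Within each sample, calls whose two breakpoint ends are both strictly
#' less than `tol` bases apart (same chromosome pair, matching end
#' pairing) are single-linkage clustered and replaced by one
#' representative: the lowest-coordinate member. Cross-class merges are
#' allowed by default (calls of different SV classes may be duplicates
#' from different callers); set `same_class = TRUE` to forbid them.
#'
#' @param bps a [breakpoint_set()].
#' @param tol collapse tolerance in bp (default 10; strict `<`).
#' @param same_class require matching `sv_class` for merging.
#' @return collapsed [breakpoint_set()] with attribute `n_collapsed`
#'   (calls removed) and `counts` (per-sample totals after collapsing).
#' @export
collapse_ssvs <- function(bps, tol = 10, same_class = FALSE) {
  if (tol < 0) stop("tol must be non-negative")
  keep_rows <- integer(0)
  for (s in unique(bps$sample_id)) {
    rows <- which(bps$sample_id == s)
    b <- bps[rows, ]
    key <- paste(b$chrom1, b$chrom2)
    for (k in unique(key)) {
      idx <- which(key == k)
      n <- length(idx)
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      if (n > 1) {
        for (i in 1:(n - 1)) for (j in (i + 1):n) {
          if (abs(b$pos1[idx[i]] - b$pos1[idx[j]]) < tol &&
              abs(b$pos2[idx[i]] - b$pos2[idx[j]]) < tol &&
              (!same_class || b$sv_class[idx[i]] == b$sv_class[idx[j]])) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
      root <- vapply(seq_len(n), find, integer(1))
      for (r in unique(root)) {
        members <- idx[root == r]
        o <- order(b$pos1[members], b$pos2[members])
        keep_rows <- c(keep_rows, rows[members[o[1]]])
      }
    }
  }
  out <- bps[sort(keep_rows), ]
  class(out) <- c("breakpoint_set", "data.frame")
  rownames(out) <- NULL
  attr(out, "n_collapsed") <- nrow(bps) - nrow(out)
  attr(out, "counts") <- table(out$sample_id)
  out
}

#' Per-sample structural-variation burden profile
#'
#' The total SSV count per sample (after collapsing) is log2(n + 1)
#' transformed and standardised to SD-from-median units *within* each WGS
#' coverage stratum (low-pass samples first, then high-pass), giving the
#' global SSV index: samples sequenced at low coverage systematically
#' yield fewer calls, so the two strata are normalised separately. When
#' supplied, the overall-methylation index (median beta across all probes
#' of the sample) and overall-CNA index (SD of the gene-level log2 ratios)
#' are attached.
#'
#' @param bps a collapsed [breakpoint_set()] (see [collapse_ssvs()]).
#' @param sample_info sample metadata; every sample here gets a profile
#'   (zero counts for samples without calls).
#' @param meth optional methylation beta [omics_matrix()].
#' @param cna optional `cna_log2` [omics_matrix()].
#' @return a `burden_profile` data frame.
#' @export
burden_profile <- function(bps, sample_info, meth = NULL, cna = NULL) {
  counts <- table(factor(bps$sample_id, levels = sample_info$sample_id))
  df <- data.frame(sample_id = sample_info$sample_id,
                   wgs_pass = sample_info$wgs_pass,
                   total_ssv = as.integer(counts),
                   stringsAsFactors = FALSE)
  df$log_total <- log2(df$total_ssv + 1)
  df$global_ssv_index <- NA_real_
  for (st in unique(df$wgs_pass)) {
    sel <- df$wgs_pass == st
    x <- df$log_total[sel]
    s <- sd(x)
    if (is.na(s) || s == 0) {
      warning("zero-variance SSV counts in stratum '", st, "'; index set to 0")
      df$global_ssv_index[sel] <- 0
    } else {
      df$global_ssv_index[sel] <- (x - median(x)) / s
    }
  }
  if (!is.null(meth)) {
    mm <- meth[, intersect(colnames(meth), df$sample_id), drop = FALSE]
    om <- apply(mm, 2, median, na.rm = TRUE)
    df$overall_methylation <- om[df$sample_id]
  }
  if (!is.null(cna)) {
    cc <- cna[, intersect(colnames(cna), df$sample_id), drop = FALSE]
    oc <- apply(cc, 2, sd, na.rm = TRUE)
    df$overall_cna <- oc[df$sample_id]
  }
  class(df) <- c("burden_profile", "data.frame")
  df
}

#' Gene-set signature scores from normalised expression
#'
#' Expression values are log2(x + 1)-transformed and standardised per gene
#' to SD-from-median units, either across all samples or within each
#' cancer type (the convention for immune-cell signatures); the signature
#' score is each sample's mean over the set genes present in the matrix.
#'
#' @param expr expression [omics_matrix()].
#' @param gene_set character vector of gene ids.
#' @param sample_info sample metadata (required for within-type
#'   normalisation).
#' @param normalization `"across_samples"` or `"within_cancer_type"`.
#' @param samples optional sample subset.
#' @param set_name label attached to the output.
#' @return data frame (`sample_id`, `set_name`, `score`); absent set genes
#'   are reported via the `n_missing` attribute.
#' @export
signature_score <- function(expr, gene_set, sample_info = NULL,
                            normalization = c("across_samples", "within_cancer_type"),
                            samples = NULL, set_name = "signature") {
  normalization <- match.arg(normalization)
  common <- if (is.null(samples)) colnames(expr) else intersect(colnames(expr), samples)
  present <- intersect(gene_set, rownames(expr))
  if (!length(present)) stop("no gene of the set is present in the matrix")
  n_missing <- length(setdiff(gene_set, present))
  if (n_missing) svcis_log("signature '%s': %d set gene(s) absent", set_name, n_missing)
  v <- log2(expr[present, common, drop = FALSE] + 1)
  normalise <- function(m) {
    med <- apply(m, 1, median, na.rm = TRUE)
    s <- apply(m, 1, sd, na.rm = TRUE)
    sweep(m, 1, med, "-") / ifelse(s > 0, s, NA)
  }
  if (normalization == "across_samples") {
    z <- normalise(v)
  } else {
    if (is.null(sample_info)) stop("within-type normalisation needs sample_info")
    ty <- sample_info$cancer_type[match(common, sample_info$sample_id)]
    z <- v
    for (t in unique(ty)) z[, ty == t] <- normalise(v[, ty == t, drop = FALSE])
  }
  out <- data.frame(sample_id = common, set_name = set_name,
                    score = colMeans(z, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_missing") <- n_missing
  out
}

#' Association scan against the total SSV burden
#'
#' Delegates to [sv_scan()] with the per-sample log2(total SSV + 1) as the
#' predictor; the WGS coverage class and project covariates are mandatory
#' (detection sensitivity differs between low- and high-pass sequencing).
#' The feature's own closest-breakpoint distance can be included as the
#' `proximal_bp` covariate, and the sample's overall methylation as
#' `overall_methylation`.
#'
#' @param response an [omics_matrix()].
#' @param burden a [burden_profile()].
#' @param sample_info sample metadata table.
#' @param covariates additional covariates (wgs_pass and project are
#'   always added).
#' @param ... passed to [sv_scan()] (`cna`, `feature_map`, `proximal_bp`,
#'   `config`, ...).
#' @return an [sv_scan()] object.
#' @export
burden_scan <- function(response, burden, sample_info,
                        covariates = character(), ...) {
  pred <- setNames(burden$total_ssv, burden$sample_id)
  covs <- union(c("wgs_pass", "project"), covariates)
  extra <- list()
  if ("overall_methylation" %in% covs) {
    if (is.null(burden$overall_methylation)) {
      stop("overall_methylation covariate requested but not present in the burden profile")
    }
    extra$overall_methylation <- setNames(burden$overall_methylation, burden$sample_id)
  }
  if ("total_bp_count" %in% covs) {
    extra$total_bp_count <- setNames(burden$log_total, burden$sample_id)
  }
  args <- list(...)
  cfg <- args$config %||% scan_config(covariates = covs)
  cfg$covariates <- covs
  args$config <- cfg
  args$extra_covariates <- extra
  do.call(sv_scan, c(list(response = response, predictor = pred,
                          sample_info = sample_info), args))
}
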
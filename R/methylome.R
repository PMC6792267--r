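# Normal-tissue methylation of rearranged regions versus the CGI near the
# gene on the other side of the SSV breakpoint.

#' Construct a normal-tissue methylation panel
#'
#' @param probes data frame with `probe_id`, `chrom`, `pos`.
#' @param beta matrix (probes x tissues) of normal-tissue beta values.
#' @return a `normal_panel` list.
#' @export
normal_panel <- function(probes, beta) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(probes)))
  beta <- as.matrix(beta)
  if (nrow(beta) != nrow(probes)) stop("panel beta rows must match probes")
  if (any(!is.na(beta) & (beta < 0 | beta > 1))) {
    stop("normal panel beta values outside [0,1]")
  }
  rownames(beta) <- probes$probe_id
  structure(list(probes = probes, beta = beta), class = "normal_panel")
}

#' Read a normal-tissue methylation panel TSV
#'
#' Columns: `probe_id`, `chrom`, `pos`, then one beta column per tissue.
#'
#' @param path TSV path.
#' @return a [normal_panel()].
#' @export
read_normal_panel <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  probes <- df[, c("probe_id", "chrom", "pos")]
  beta <- as.matrix(df[, setdiff(names(df), c("probe_id", "chrom", "pos")),
                       drop = FALSE])
  normal_panel(probes, beta)
}

#' Write a normal-tissue methylation panel as TSV
#' @param panel a [normal_panel()].
#' @param path output path.
#' @export
write_normal_panel <- function(panel, path) {
  df <- cbind(panel$probes[, c("probe_id", "chrom", "pos")],
              as.data.frame(panel$beta))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean normal-tissue methylation of a rearranged region
#'
#' Averages the panel's beta values over all probes in a window anchored
#' at the mate breakpoint and extending into its retained flank
#' (orientation `+`: lower coordinates; `-`: higher), or centred on the
#' mate when `anchor = "center"`.
#'
#' @param chrom,pos mate breakpoint locus (0-based).
#' @param orient mate orientation.
#' @param panel a [normal_panel()].
#' @param tissue panel column name.
#' @param window window size in bp (default 50 kb).
#' @param anchor `"flank"` (default) or `"center"`.
#' @return mean beta, or NA when no probe falls in the window.
#' @export
rearranged_region_beta <- function(chrom, pos, orient, panel, tissue,
                                   window = 5e4, anchor = c("flank", "center")) {
  anchor <- match.arg(anchor)
  if (!tissue %in% colnames(panel$beta)) stop("unknown tissue: ", tissue)
  bounds <- if (anchor == "center") {
    c(pos - window / 2, pos + window / 2)
  } else if (orient == "+") c(pos - window, pos) else c(pos, pos + window)
  pgr <- granges_points(panel$probes$chrom, panel$probes$pos)
  wgr <- granges_0based(chrom, bounds[1], bounds[2] + 1)
  hits <- GenomicRanges::findOverlaps(pgr, wgr)
  sel <- S4Vectors::queryHits(hits)
  if (!length(sel)) return(NA_real_)
  mean(panel$beta[sel, tissue], na.rm = TRUE)
}

# Vectorised window means over the panel: per (chromosome, tissue) group
# the probes are sorted once and window sums come from cumulative sums.
# Agrees with rearranged_region_beta() on every record.
region_means_vec <- function(chrom, pos, orient, tissue, panel, window) {
  out <- rep(NA_real_, length(pos))
  lo <- ifelse(orient == "+", pos - window, pos)
  hi <- ifelse(orient == "+", pos, pos + window)
  key <- paste(chrom, tissue)
  for (k in unique(key)) {
    sel <- which(key == k)
    ch <- chrom[sel[1]]
    tis <- tissue[sel[1]]
    pr <- which(panel$probes$chrom == ch)
    if (!length(pr)) next
    o <- order(panel$probes$pos[pr])
    pp <- panel$probes$pos[pr][o]
    bb <- panel$beta[pr, tis][o]
    ok <- !is.na(bb)
    csum <- cumsum(c(0, ifelse(ok, bb, 0)))
    cnt <- cumsum(c(0, as.integer(ok)))
    i_hi <- findInterval(hi[sel], pp) + 1L
    i_lo <- findInterval(lo[sel] - 1e-9, pp) + 1L
    n_in <- cnt[i_hi] - cnt[i_lo]
    s_in <- csum[i_hi] - csum[i_lo]
    out[sel] <- ifelse(n_in > 0, s_in / n_in, NA_real_)
  }
  out
}

#' Closest-breakpoint CGI associations for the methylome-shift analysis
#'
#' For each CGI probe and sample, records the single breakpoint closest to
#' the probe's gene start within `max_dist` (only the closest breakpoint is
#' considered for each sample when multiple are detected), together with
#' the mate locus and orientation of that breakpoint.
#'
#' @param bps a [breakpoint_set()].
#' @param genes a [gene_table()].
#' @param probes a [probe_table()].
#' @param samples optional sample subset.
#' @param max_dist association radius around the gene start (1 Mb).
#' @return data frame of SSV-CGI associations.
#' @export
build_cgi_associations <- function(bps, genes, probes, samples = NULL,
                                   max_dist = 1e6) {
  ends <- explode_breakpoints(bps)
  if (!is.null(samples)) ends <- ends[ends$sample_id %in% samples, ]
  gi <- match(probes$gene_id, genes$gene_id)
  keep <- !is.na(gi)
  probes <- probes[keep, ]
  gi <- gi[keep]
  out <- vector("list", 0)
  ends_by_sample <- split(ends, ends$sample_id)
  for (s in names(ends_by_sample)) {
    es <- ends_by_sample[[s]]
    for (ch in unique(genes$chrom[gi])) {
      e <- es[es$chrom == ch, ]
      if (!nrow(e)) next
      o <- order(e$pos)
      e <- e[o, ]
      sel <- which(genes$chrom[gi] == ch)
      tss <- genes$tss[gi[sel]]
      k <- findInterval(tss, e$pos)
      kl <- pmax(k, 1)
      kr <- pmin(k + 1, nrow(e))
      d_left <- ifelse(k >= 1, tss - e$pos[kl], Inf)
      d_right <- ifelse(k < nrow(e), e$pos[kr] - tss, Inf)
      pick <- ifelse(d_left <= d_right, kl, kr)
      d <- pmin(d_left, d_right)
      ok <- is.finite(d) & d < max_dist
      if (!any(ok)) next
      b <- e[pick[ok], ]
      out[[length(out) + 1]] <- data.frame(
        probe_id = probes$probe_id[sel][ok], gene_id = probes$gene_id[sel][ok],
        sample_id = s, ssv_id = b$ssv_id, bp_chrom = b$chrom, bp_pos = b$pos,
        mate_chrom = b$mate_chrom, mate_pos = b$mate_pos,
        mate_orient = b$mate_orient, dist = d[ok],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(probe_id = character(), gene_id = character(),
                      sample_id = character(), ssv_id = character(),
                      bp_chrom = character(), bp_pos = numeric(),
                      mate_chrom = character(), mate_pos = numeric(),
                      mate_orient = character(), dist = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$probe_id, res$sample_id), ]
  rownames(res) <- NULL
  res
}

#' Normal-methylation difference between rearranged regions and CGIs
#'
#' For each SSV-CGI association the mean normal-tissue methylation of the
#' rearranged region (50 kb window at the mate breakpoint, retained flank)
#' is compared with the normal methylation of the CGI probe itself:
#' `delta = region_mean - cgi_beta`. Associations are labelled
#' `cancer_hyper` / `cancer_hypo` when the probe is a scan hit (q below
#' `fdr`) and the carrier sample deviates beyond the alteration threshold.
#' The subset summary reports per-subset mean delta with standard error, a
#' Spearman rank correlation between subset membership and delta, and a
#' Welch two-sample comparison against the remaining associations.
#'
#' @param associations data frame from [build_cgi_associations()].
#' @param panel a [normal_panel()].
#' @param tissue_map data frame (`cancer_type`, `tissue`) mapping cancer
#'   types to their normal-tissue surrogate columns.
#' @param sample_info sample metadata table.
#' @param window rearranged-region window in bp (default 50 kb).
#' @param scan optional methylation [sv_scan()] result.
#' @param alterations optional [alteration_calls()] on the beta matrix.
#' @param fdr q-value cutoff defining the altered subsets.
#' @return list with `records` (per-association deltas and subset labels)
#'   and `summary` (per-subset statistics).
#' @export
ssv_cgi_beta_shift <- function(associations, panel, tissue_map, sample_info,
                               window = 5e4, scan = NULL, alterations = NULL,
                               fdr = 0.05) {
  if (!nrow(associations)) stop("empty association list")
  ctype <- sample_info$cancer_type[match(associations$sample_id,
                                         sample_info$sample_id)]
  tissue <- tissue_map$tissue[match(ctype, tissue_map$cancer_type)]
  unresolved <- is.na(tissue) | !(tissue %in% colnames(panel$beta))
  if (any(unresolved)) {
    warning(sum(unresolved), " association(s) with no normal-tissue surrogate dropped")
  }
  df <- associations[!unresolved, , drop = FALSE]
  tissue <- tissue[!unresolved]
  if (!nrow(df)) stop("no associations with a resolvable normal tissue")
  ti <- match(tissue, colnames(panel$beta))
  pi <- match(df$probe_id, panel$probes$probe_id)
  cgi_beta <- panel$beta[cbind(pi, ti)]
  df$region_mean_beta <- region_means_vec(df$mate_chrom, df$mate_pos,
                                          df$mate_orient, tissue, panel, window)
  df$cgi_beta <- cgi_beta
  df$delta <- df$region_mean_beta - cgi_beta
  df$subset <- "all"
  if (!is.null(scan) && !is.null(alterations)) {
    r <- scan$results
    sig <- r$feature_id[r$status == "tested" & !is.na(r$q_value) & r$q_value < fdr]
    dev <- alterations$deviation
    idx <- cbind(match(df$probe_id, rownames(dev)),
                 match(df$sample_id, colnames(dev)))
    ok <- !is.na(idx[, 1]) & !is.na(idx[, 2]) & df$probe_id %in% sig
    d <- rep(NA_real_, nrow(df))
    d[ok] <- dev[idx[ok, , drop = FALSE]]
    df$subset[!is.na(d) & d > alterations$threshold_sd] <- "cancer_hyper"
    df$subset[!is.na(d) & d < -alterations$threshold_sd] <- "cancer_hypo"
  }
  usable <- !is.na(df$delta)
  summarise <- function(sel, name) {
    x <- df$delta[usable & sel]
    n <- length(x)
    spearman_p <- two_sample_p <- NA_real_
    if (name != "all" && n >= 2 && sum(usable & !sel) >= 2) {
      ind <- as.integer(sel[usable])
      spearman_p <- suppressWarnings(
        cor.test(df$delta[usable], ind, method = "spearman"))$p.value
      two_sample_p <- t.test(df$delta[usable & sel], df$delta[usable & !sel])$p.value
    }
    data.frame(subset = name, n = n, mean_delta = mean(x),
               se_delta = sd(x) / sqrt(n), spearman_p = spearman_p,
               two_sample_p = two_sample_p, stringsAsFactors = FALSE)
  }
  summ <- rbind(
    summarise(rep(TRUE, nrow(df)), "all"),
    if (any(df$subset == "cancer_hyper")) summarise(df$subset == "cancer_hyper", "cancer_hyper"),
    if (any(df$subset == "cancer_hypo")) summarise(df$subset == "cancer_hypo", "cancer_hypo")
  )
  list(records = df, summary = summ)
}
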
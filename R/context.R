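# TAD-disruption classification and enrichment; orientation-aware
# enhancer-hijacking tabulation; per-(feature, sample) alteration calls.

# TAD index (row of `tads`) containing each 0-based position; NA for
# positions in inter-TAD gaps. TADs are validated as disjoint per
# chromosome at load time.
tad_index <- function(chrom, pos, tads) {
  gr <- granges_points(chrom, pos)
  tgr <- granges_0based(tads$chrom, tads$start, tads$end)
  hits <- GenomicRanges::findOverlaps(gr, tgr)
  idx <- rep(NA_integer_, length(pos))
  idx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  idx
}

#' Classify SSVs as TAD-disrupting or non-disrupting
#'
#' An SSV is non-disrupting only when both of its breakpoints fall inside
#' the same TAD interval. Inter-chromosomal SSVs are always disrupting,
#' and a breakpoint landing in an inter-TAD gap counts as disrupting
#' (set `gap_category = TRUE` to report those as a third category).
#'
#' @param bps a [breakpoint_set()].
#' @param tads TAD BED data frame (disjoint per chromosome).
#' @param gap_category report gap-landing SSVs as `"gap"` instead of
#'   `"disrupting"`.
#' @return character vector, one entry per SSV.
#' @export
classify_tad_disruption <- function(bps, tads, gap_category = FALSE) {
  validate_tads(tads)
  i1 <- tad_index(bps$chrom1, bps$pos1, tads)
  i2 <- tad_index(bps$chrom2, bps$pos2, tads)
  same <- !is.na(i1) & !is.na(i2) & i1 == i2
  out <- ifelse(same, "non_disrupting", "disrupting")
  if (gap_category) out[is.na(i1) | is.na(i2)] <- "gap"
  out
}

#' Enrichment of TAD-disrupting SSVs in a subset
#'
#' Chi-squared test (2x2, no continuity correction) of the disrupting
#' fraction in a subset of SSVs against the remaining SSVs.
#'
#' @param disruption character vector from [classify_tad_disruption()]
#'   over all SSVs.
#' @param subset logical or integer index selecting the subset.
#' @return list with the two disrupting fractions, the 2x2 statistic and p.
#' @export
tad_enrichment_test <- function(disruption, subset) {
  sel <- if (is.logical(subset)) subset else seq_along(disruption) %in% subset
  if (!any(sel)) stop("empty SSV subset")
  d <- disruption == "disrupting"
  tab <- rbind(subset = c(sum(d[sel]), sum(!d[sel])),
               rest = c(sum(d[!sel]), sum(!d[!sel])))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(frac_subset = mean(d[sel]), frac_rest = mean(d[!sel]),
       n_subset = sum(sel), n_rest = sum(!sel),
       statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Per-(feature, sample) alteration calls from deviation off the median
#'
#' For every feature the transformed values are centred on the feature's
#' cross-sample median and scaled by the feature's standard deviation;
#' a sample is called `up` when its deviation exceeds `+threshold_sd` and
#' `down` below `-threshold_sd`. When a CNA matrix is supplied, samples are
#' also labelled amplified/deleted at |log2 tumor/normal ratio| > 1, so
#' that expression alterations explainable by copy number can be set aside.
#'
#' @param m an [omics_matrix()].
#' @param samples optional sample subset.
#' @param threshold_sd deviation threshold in SD units (default 0.4).
#' @param cna optional `cna_log2` matrix (rows matched via `feature_map`).
#' @param feature_map optional named map from `m` features to CNA rows.
#' @param cna_threshold |log2 ratio| defining amplification/deletion.
#' @param clamp_eps beta clamp width for methylation input.
#' @return an `alteration_calls` list: `deviation` matrix (SD units),
#'   `altered` matrix (+1/0/-1), optional `amp_del` matrix (+1/0/-1).
#' @export
alteration_calls <- function(m, samples = NULL, threshold_sd = 0.4,
                             cna = NULL, feature_map = NULL,
                             cna_threshold = 1, clamp_eps = 1e-3) {
  common <- if (is.null(samples)) colnames(m) else intersect(colnames(m), samples)
  v <- transform_values(m[, common, drop = FALSE],
                        attr(m, "transform") %||% "identity", clamp_eps)
  med <- apply(v, 1, median, na.rm = TRUE)
  sdv <- apply(v, 1, sd, na.rm = TRUE)
  dev <- sweep(v, 1, med, "-") / ifelse(sdv > 0, sdv, NA)
  altered <- matrix(0L, nrow(dev), ncol(dev), dimnames = dimnames(dev))
  altered[!is.na(dev) & dev > threshold_sd] <- 1L
  altered[!is.na(dev) & dev < -threshold_sd] <- -1L
  amp_del <- NULL
  if (!is.null(cna)) {
    map <- if (is.null(feature_map)) setNames(rownames(m), rownames(m))
           else feature_map[rownames(m)]
    amp_del <- matrix(0L, nrow(m), length(common),
                      dimnames = list(rownames(m), common))
    ok <- !is.na(map) & map %in% rownames(cna)
    cc <- intersect(common, colnames(cna))
    cv <- cna[map[ok], cc, drop = FALSE]
    sub <- amp_del[ok, cc, drop = FALSE]
    sub[!is.na(cv) & cv > cna_threshold] <- 1L
    sub[!is.na(cv) & cv < -cna_threshold] <- -1L
    amp_del[ok, cc] <- sub
  }
  structure(list(deviation = dev, altered = altered, amp_del = amp_del,
                 threshold_sd = threshold_sd),
            class = "alteration_calls")
}

# Applicable enhancer rows for one cancer type: ubiquitous plus any tag the
# type maps to.
applicable_enhancers <- function(enhancers, cancer_type, type_map = NULL) {
  tags <- "ubiquitous"
  if (!is.null(type_map)) {
    tags <- c(tags, type_map$tag[type_map$cancer_type == cancer_type])
  }
  enhancers[enhancers$specificity %in% tags, , drop = FALSE]
}

#' Upstream breakpoint-to-gene associations for hijack screening
#'
#' One association per (gene, sample): the closest breakpoint 0-`max_dist`
#' upstream of the gene start whose retained flank faces away from the
#' gene (gene on `+` strand: breakpoint orientation `-`; gene on `-`
#' strand: orientation `+`), so that the mate-side sequence is fused
#' toward the gene.
#'
#' @param bps a [breakpoint_set()].
#' @param genes a [gene_table()].
#' @param max_dist upstream window in bp (default 500 kb).
#' @return data frame of associations with mate locus and orientations.
#' @export
upstream_bp_associations <- function(bps, genes, max_dist = 5e5) {
  ends <- explode_breakpoints(bps)
  if (!nrow(ends)) stop("no breakpoints supplied")
  # upstream in distance space: 1 <= tss - pos <= max_dist ('+'),
  # mirrored for '-' genes
  gr_up_plus <- genes$strand == "+"
  lo <- ifelse(gr_up_plus, genes$tss - max_dist, genes$tss + 1)
  hi <- ifelse(gr_up_plus, genes$tss - 1, genes$tss + max_dist)
  ggr <- granges_0based(genes$chrom, lo, hi + 1)
  bgr <- granges_points(ends$chrom, ends$pos)
  hits <- GenomicRanges::findOverlaps(bgr, ggr)
  if (!length(hits)) return(empty_assoc_df())
  bi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  strand <- genes$strand[gi]
  want_orient <- ifelse(strand == "+", "-", "+")
  keep <- ends$orient[bi] == want_orient
  bi <- bi[keep]
  gi <- gi[keep]
  if (!length(bi)) return(empty_assoc_df())
  df <- data.frame(
    gene_id = genes$gene_id[gi], sample_id = ends$sample_id[bi],
    ssv_id = ends$ssv_id[bi], bp_chrom = ends$chrom[bi], bp_pos = ends$pos[bi],
    bp_orient = ends$orient[bi], mate_chrom = ends$mate_chrom[bi],
    mate_pos = ends$mate_pos[bi], mate_orient = ends$mate_orient[bi],
    dist = abs(genes$tss[gi] - ends$pos[bi]),
    stringsAsFactors = FALSE
  )
  # closest qualifying breakpoint per (gene, sample)
  df <- df[order(df$gene_id, df$sample_id, df$dist), ]
  df <- df[!duplicated(df[, c("gene_id", "sample_id")]), ]
  rownames(df) <- NULL
  df
}

empty_assoc_df <- function() {
  data.frame(gene_id = character(), sample_id = character(),
             ssv_id = character(), bp_chrom = character(), bp_pos = numeric(),
             bp_orient = character(), mate_chrom = character(),
             mate_pos = numeric(), mate_orient = character(),
             dist = numeric(), stringsAsFactors = FALSE)
}

#' Orientation-aware enhancer-hijacking scan
#'
#' For each upstream breakpoint-gene association, flags a putative
#' enhancer hijack when (a) the unaltered gene has no applicable enhancer
#' (ubiquitous or matching the sample's cancer type) within `native_budget`
#' of its start, and (b) an applicable enhancer lies on the retained flank
#' of the breakpoint mate with fused distance `|tss - breakpoint| +
#' |mate - enhancer|` at most `fusion_budget`. The fused distance treats
#' the junction as a simple splice of the two retained flanks.
#'
#' @param associations data frame from [upstream_bp_associations()].
#' @param genes a [gene_table()].
#' @param enhancers enhancer data frame (`chrom`, `start`, `end`,
#'   `specificity`).
#' @param sample_info sample metadata (for the cancer type of each sample).
#' @param type_map data frame (`cancer_type`, `tag`) mapping cancer types
#'   to applicable enhancer specificity tags; NULL = ubiquitous only.
#' @param fusion_budget maximum fused enhancer-to-gene distance (500 kb).
#' @param native_budget native-enhancer exclusion radius (1 Mb).
#' @return the association data frame with `native_enh`, `hijack` and
#'   `fused_dist` columns.
#' @export
enhancer_hijack_scan <- function(associations, genes, enhancers, sample_info,
                                 type_map = NULL, fusion_budget = 5e5,
                                 native_budget = 1e6) {
  if (any(is.na(associations$bp_orient)) || any(is.na(associations$mate_orient))) {
    stop("associations carry missing orientations")
  }
  df <- associations
  df$native_enh <- logical(nrow(df))
  df$hijack <- logical(nrow(df))
  df$fused_dist <- rep(NA_real_, nrow(df))
  if (!nrow(df)) return(df)
  enh_mid <- (enhancers$start + enhancers$end) / 2
  tss <- genes$tss[match(df$gene_id, genes$gene_id)]
  gchrom <- genes$chrom[match(df$gene_id, genes$gene_id)]
  ctype <- sample_info$cancer_type[match(df$sample_id, sample_info$sample_id)]
  for (i in seq_len(nrow(df))) {
    enh <- applicable_enhancers(enhancers, ctype[i], type_map)
    if (!nrow(enh)) next
    mid <- (enh$start + enh$end) / 2
    native <- enh$chrom == gchrom[i] & abs(mid - tss[i]) <= native_budget
    df$native_enh[i] <- any(native)
    if (df$native_enh[i]) next
    # retained flank of the mate: '+' keeps lower coordinates, '-' higher
    on_flank <- enh$chrom == df$mate_chrom[i] &
      (if (df$mate_orient[i] == "+") mid <= df$mate_pos[i] else mid >= df$mate_pos[i])
    if (!any(on_flank)) next
    d2 <- abs(df$mate_pos[i] - mid[on_flank])
    fused <- df$dist[i] + min(d2)
    df$fused_dist[i] <- fused
    df$hijack[i] <- fused <= fusion_budget
  }
  df
}

#' Hijack percentages overall and within altered subsets
#'
#' Tabulates the percentage of associations flagged as enhancer hijacks
#' for the full association set and for the subsets whose gene (or probe)
#' shows breakpoint-associated alteration: scan FDR below `fdr` plus a
#' carrier deviation beyond the alteration threshold.
#'
#' @param hijacks output of [enhancer_hijack_scan()].
#' @param scan optional [sv_scan()] result for the genes.
#' @param alterations optional [alteration_calls()] on the matching
#'   omics matrix.
#' @param fdr q-value cutoff defining the altered subsets.
#' @return data frame with one row per subset (`all`, `up`, `down`):
#'   n, hijack count and percentage, plus a chi-squared p versus `all`.
#' @export
hijack_summary <- function(hijacks, scan = NULL, alterations = NULL,
                           fdr = 0.05) {
  lab <- rep("none", nrow(hijacks))
  if (!is.null(scan) && !is.null(alterations)) {
    r <- scan$results
    sig <- r$feature_id[r$status == "tested" & !is.na(r$q_value) & r$q_value < fdr]
    alt <- alterations$altered
    idx <- cbind(match(hijacks$gene_id, rownames(alt)),
                 match(hijacks$sample_id, colnames(alt)))
    ok <- !is.na(idx[, 1]) & !is.na(idx[, 2]) & hijacks$gene_id %in% sig
    a <- rep(0L, nrow(hijacks))
    a[ok] <- alt[idx[ok, , drop = FALSE]]
    lab[ok & a == 1L] <- "up"
    lab[ok & a == -1L] <- "down"
  }
  one <- function(sel, name) {
    n <- sum(sel)
    h <- sum(hijacks$hijack[sel])
    p <- NA_real_
    if (name != "all" && n > 0) {
      tab <- rbind(c(h, n - h),
                   c(sum(hijacks$hijack), nrow(hijacks) - sum(hijacks$hijack)))
      if (all(tab >= 0) && sum(tab[1, ]) > 0) {
        p <- suppressWarnings(chisq.test(tab, correct = FALSE))$p.value
      }
    }
    data.frame(subset = name, n = n, n_hijack = h,
               pct_hijack = if (n > 0) 100 * h / n else NA_real_,
               p_vs_all = p, stringsAsFactors = FALSE)
  }
  rbind(one(rep(TRUE, nrow(hijacks)), "all"),
        one(lab == "up", "up"),
        one(lab == "down", "down"))
}
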
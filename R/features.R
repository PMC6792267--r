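# Gene x sample breakpoint predictor matrices.
#
# Two predictor encodings are supported, mirroring the two integration
# methods: a binary genomic-region-window matrix (presence/absence of at
# least one breakpoint in a fixed window relative to the gene) and a capped
# closest-breakpoint-distance matrix over the +/- 1 Mb region around the
# gene start.

#' Canonical genomic region windows
#'
#' The canonical window set is 0-20 kb, 20-50 kb and 50-100 kb on each of
#' the upstream and downstream sides, plus the gene body. Flank windows are
#' half-open in distance space (`near <= d < far`): a breakpoint exactly
#' 20,000 bp upstream belongs to the 20-50 kb window, so the flank windows
#' partition the flank disjointly. Upstream windows are anchored at the
#' strand-aware gene start, downstream windows at the strand-aware gene
#' end, and the gene body (which includes both boundaries) is never also
#' counted in a flank window.
#'
#' @return data frame with columns `name`, `side`, `near`, `far`.
#' @export
canonical_windows <- function() {
  data.frame(
    name = c("upstream_0_20kb", "upstream_20_50kb", "upstream_50_100kb",
             "downstream_0_20kb", "downstream_20_50kb", "downstream_50_100kb",
             "gene_body"),
    side = c(rep("upstream", 3), rep("downstream", 3), "gene_body"),
    near = c(0, 20000, 50000, 0, 20000, 50000, NA),
    far = c(20000, 50000, 100000, 20000, 50000, 100000, NA),
    stringsAsFactors = FALSE
  )
}

#' Split SSV calls into single-end breakpoints
#'
#' Every SSV yields exactly two single-end breakpoints, each retaining its
#' own orientation together with the mate locus and mate orientation, so
#' that orientation-aware analyses (enhancer hijacking, rearranged-region
#' methylation) can follow the retained flank across the junction.
#'
#' @param bps a [breakpoint_set()].
#' @return data frame with one row per breakpoint end.
#' @export
explode_breakpoints <- function(bps) {
  if (!nrow(bps)) {
    return(data.frame(ssv_id = character(), end = integer(),
                      sample_id = character(), chrom = character(),
                      pos = numeric(), orient = character(),
                      mate_chrom = character(), mate_pos = numeric(),
                      mate_orient = character(), sv_class = character(),
                      stringsAsFactors = FALSE))
  }
  rbind(
    data.frame(ssv_id = bps$ssv_id, end = 1L, sample_id = bps$sample_id,
               chrom = bps$chrom1, pos = bps$pos1, orient = bps$orient1,
               mate_chrom = bps$chrom2, mate_pos = bps$pos2,
               mate_orient = bps$orient2, sv_class = bps$sv_class,
               stringsAsFactors = FALSE),
    data.frame(ssv_id = bps$ssv_id, end = 2L, sample_id = bps$sample_id,
               chrom = bps$chrom2, pos = bps$pos2, orient = bps$orient2,
               mate_chrom = bps$chrom1, mate_pos = bps$pos1,
               mate_orient = bps$orient1, sv_class = bps$sv_class,
               stringsAsFactors = FALSE)
  )
}

# Inclusive 0-based position bounds [lo, hi] of a window for every gene.
# Flank windows live in distance space d in [max(near,1), far): the gene
# body owns d = 0 (a breakpoint exactly at a gene boundary).
window_bounds <- function(genes, side, near, far, stranded = TRUE) {
  strand <- if (stranded) genes$strand else rep("+", nrow(genes))
  lo <- hi <- numeric(nrow(genes))
  if (side == "gene_body") {
    lo <- genes$start
    hi <- genes$end
  } else {
    near1 <- max(near, 1)
    # "+" upstream and "-" downstream lie left of the gene; mirrored otherwise.
    left_of <- (strand == "+" & side == "upstream") |
      (strand == "-" & side == "downstream")
    anchor <- ifelse(left_of, genes$start, genes$end)
    lo <- ifelse(left_of, anchor - far + 1, anchor + near1)
    hi <- ifelse(left_of, anchor - near1, anchor + far - 1)
  }
  list(lo = lo, hi = hi)
}

#' Binary genomic-region-window breakpoint matrix
#'
#' Entry (gene, sample) is 1 if at least one breakpoint of the sample lies
#' in the given window of the gene (same chromosome), else 0.
#'
#' @param bps a [breakpoint_set()].
#' @param genes a [gene_table()].
#' @param window a window name from [canonical_windows()], or a one-row
#'   data frame with `name`, `side`, `near`, `far`.
#' @param stranded place upstream/downstream strand-aware (default) or as
#'   unstranded left/right of the gene.
#' @param samples sample (column) set; defaults to the samples present in
#'   `bps`. Samples without breakpoints get all-zero columns.
#' @return binary matrix (genes x samples) with class `bp_feature_matrix`,
#'   attributes `mode = "window"` and `window`.
#' @export
window_matrix <- function(bps, genes, window = "upstream_0_20kb",
                          stranded = TRUE, samples = NULL) {
  if (is.character(window)) {
    cw <- canonical_windows()
    if (!window %in% cw$name) stop("unknown window name: ", window)
    spec <- cw[cw$name == window, ]
  } else {
    spec <- as.data.frame(window)
  }
  b <- window_bounds(genes, spec$side, spec$near, spec$far, stranded)
  if (is.null(samples)) samples <- sort(unique(bps$sample_id))
  ends <- explode_breakpoints(bps)
  m <- matrix(0L, nrow(genes), length(samples),
              dimnames = list(genes$gene_id, samples))
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  ends_by_sample <- split(ends, factor(ends$sample_id, levels = samples))
  for (s in samples) {
    es <- ends_by_sample[[s]]
    if (is.null(es) || !nrow(es)) next
    pos_by_chrom <- split(es$pos, es$chrom)
    for (ch in names(by_chrom)) {
      pos <- pos_by_chrom[[ch]]
      if (is.null(pos) || !length(pos)) next
      pos <- sort(pos)
      gi <- by_chrom[[ch]]
      cnt <- findInterval(b$hi[gi], pos) - findInterval(b$lo[gi] - 1, pos)
      m[gi, s] <- as.integer(cnt > 0)
    }
  }
  structure(m, mode = "window", window = spec$name,
            class = c("bp_feature_matrix", class(m)))
}

#' Capped closest-breakpoint-distance matrix
#'
#' Entry (gene, sample) is the minimum absolute distance from the sample's
#' same-chromosome breakpoints to the gene start (strand-aware), capped at
#' `dmax`: where no breakpoint lies within `dmax` of the gene start, the
#' maximum distance `dmax` is imputed. A breakpoint exactly at the gene
#' start is stored as distance 1 bp so that the log2-distance predictor is
#' defined.
#'
#' @param bps a [breakpoint_set()].
#' @param genes a [gene_table()].
#' @param dmax distance cap in bp (default 1 Mb).
#' @param samples sample (column) set; defaults to the samples present in
#'   `bps`. Samples without breakpoints get all-`dmax` columns.
#' @return numeric matrix (genes x samples) with class `bp_feature_matrix`,
#'   attributes `mode = "distance"` and `dmax`.
#' @export
distance_matrix <- function(bps, genes, dmax = 1e6, samples = NULL) {
  if (dmax <= 0) stop("dmax must be positive")
  if (is.null(samples)) samples <- sort(unique(bps$sample_id))
  ends <- explode_breakpoints(bps)
  m <- matrix(dmax, nrow(genes), length(samples),
              dimnames = list(genes$gene_id, samples))
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  ends_by_sample <- split(ends, factor(ends$sample_id, levels = samples))
  for (s in samples) {
    es <- ends_by_sample[[s]]
    if (is.null(es) || !nrow(es)) next
    pos_by_chrom <- split(es$pos, es$chrom)
    for (ch in names(by_chrom)) {
      pos <- pos_by_chrom[[ch]]
      if (is.null(pos) || !length(pos)) next
      pos <- sort(pos)
      gi <- by_chrom[[ch]]
      tss <- genes$tss[gi]
      k <- findInterval(tss, pos)
      d_left <- ifelse(k >= 1, tss - pos[pmax(k, 1)], Inf)
      d_right <- ifelse(k < length(pos), pos[pmin(k + 1, length(pos))] - tss, Inf)
      d <- pmin(d_left, d_right)
      d <- pmax(d, 1)
      m[gi, s] <- ifelse(d >= dmax, dmax, d)
    }
  }
  structure(m, mode = "distance", dmax = dmax,
            class = c("bp_feature_matrix", class(m)))
}

#' @export
`[.bp_feature_matrix` <- function(x, ...) {
  out <- NextMethod()
  if (is.matrix(out)) {
    structure(out, mode = attr(x, "mode"), window = attr(x, "window"),
              dmax = attr(x, "dmax"),
              class = c("bp_feature_matrix", class(out)))
  } else {
    out
  }
}

#' @export
print.bp_feature_matrix <- function(x, ...) {
  md <- attr(x, "mode")
  cat(sprintf("bp_feature_matrix [%s%s]: %d genes x %d samples\n",
              md,
              if (md == "window") paste0(": ", attr(x, "window"))
              else sprintf(", dmax=%g", attr(x, "dmax")),
              nrow(x), ncol(x)))
  if (md == "window") {
    cat(sprintf("  carrier entries: %d (%.2f%%)\n", sum(x == 1), 100 * mean(x == 1)))
  } else {
    cat(sprintf("  entries below cap: %d (%.2f%%)\n",
                sum(x < attr(x, "dmax")), 100 * mean(x < attr(x, "dmax"))))
  }
  invisible(x)
}

#' Export a breakpoint feature matrix as TSV
#' @param m a `bp_feature_matrix`.
#' @param path output path.
#' @export
write_feature_matrix <- function(m, path) {
  write_omics_matrix(m, path)
}
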
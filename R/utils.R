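# Shared helpers: value transforms, logging, small assertions.

`%||%` <- function(a, b) if (is.null(a)) b else a

svcis_log <- function(...) {
  if (isTRUE(getOption("svcis.verbose", TRUE))) {
    message("[svcis] ", sprintf(...))
  }
  invisible(NULL)
}

#' Logit transform of methylation beta values with clamping
#'
#' Beta values are clamped into `[eps, 1 - eps]` before the logit so that
#' boundary values (fully unmethylated or fully methylated probes) remain
#' finite under the linear model.
#'
#' @param beta numeric vector of beta values in `[0, 1]` (NA allowed).
#' @param eps clamp width; default `1e-3`.
#' @return numeric vector on the logit scale.
#' @export
logit_clamped <- function(beta, eps = 1e-3) {
  stopifnot(eps > 0, eps < 0.5)
  qlogis(pmin(pmax(beta, eps), 1 - eps))
}

# Transform raw omics values onto the modelling scale declared for their kind.
transform_values <- function(x, transform, eps = 1e-3) {
  switch(transform,
    log2p1 = log2(x + 1),
    logit_clamped = logit_clamped(x, eps),
    identity = x,
    stop("unknown transform: ", transform)
  )
}

kind_transform <- function(kind) {
  switch(kind,
    expression = "log2p1",
    methylation_beta = "logit_clamped",
    cna_log2 = "identity",
    stop("unknown omics kind: ", kind)
  )
}

is_sex_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "Y", "x", "y")
}

# 1-based closed GRanges from internal 0-based half-open intervals.
granges_0based <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

# GRanges of single-base points from internal 0-based positions.
granges_points <- function(chrom, pos0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, pos0 + 1L))
}
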
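# Shared fixtures: all built in code, no stored data.

options(svcis.verbose = FALSE)

# Small cohort configuration for fast end-to-end tests.
small_cfg <- function(seed = 1, n_samples = 80, ...) {
  sim_config(n_samples = n_samples, n_genes = 150, ssv_rate = 25,
             n_chrom = 2, chrom_length = 1.2e8,
             planted = list(expr_up = 5, expr_down = 3, meth_up = 3,
                            meth_down = 3, burden_linked = 5, hijack = 2,
                            joint_per_type = 1),
             n_enhancers = 120, n_low_regions = 10, seed = seed, ...)
}

# Hand-built toy gene annotation: two chromosomes, mixed strands.
toy_genes <- function() {
  gene_table(data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000000, 2000000, 500000),
    end = c(1030000, 2010000, 620000),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE
  ))
}

# Breakpoint set builder from a compact spec.
toy_bps <- function(sample_id, chrom1, pos1, chrom2 = chrom1,
                    pos2 = pos1 + 5e4, orient1 = "+", orient2 = "-") {
  breakpoint_set(data.frame(
    sample_id = sample_id, chrom1 = chrom1, pos1 = pos1, orient1 = orient1,
    chrom2 = chrom2, pos2 = pos2, orient2 = orient2,
    stringsAsFactors = FALSE
  ))
}

# Independent brute-force oracle for the window rule: a breakpoint at
# position p hits gene g's window iff its distance from the strand-aware
# anchor lies in [max(near,1), far) on the correct side, and the gene body
# covers start <= p <= end.
oracle_window_hit <- function(p, gene, spec, stranded = TRUE) {
  strand <- if (stranded) gene$strand else "+"
  if (spec$side == "gene_body") return(p >= gene$start && p <= gene$end)
  d <- if (spec$side == "upstream") {
    if (strand == "+") gene$start - p else p - gene$end
  } else {
    if (strand == "+") p - gene$end else gene$start - p
  }
  near <- max(spec$near, 1)
  d >= near && d < spec$far
}

# Independent closed-form OLS via normal equations.
oracle_ols <- function(y, x, C = NULL) {
  X <- cbind(1, x, C)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  t <- beta[2] / se[2]
  list(coef = beta[2], se = se[2], t = t, p = 2 * pt(-abs(t), df))
}
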
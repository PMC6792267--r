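# End-to-end orchestration: features -> scans -> permutation -> overlaps ->
# rearrangement context -> methylome shift -> burden, from one config.

default_pipeline_config <- function() {
  list(
    seed = 1,
    stages = c("features", "expr_scan", "meth_scan", "overlap", "context",
               "methshift", "burden"),
    fdr = 0.05, fdr_per_type = 0.10, fdr_dm = 0.001,
    alteration_sd = 0.4, amp_del_log2 = 1,
    dmax = 1e6, fusion_budget = 5e5, native_budget = 1e6,
    meth_window = 5e4, collapse_tol = 10,
    covariates = c("cancer_type", "cna"),
    n_perm = 100, perm_alpha = 0.05
  )
}

validate_pipeline_config <- function(cohort, config) {
  known <- names(default_pipeline_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  ok_stages <- default_pipeline_config()$stages
  bad <- setdiff(cfg$stages, c(ok_stages, "permutation"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("methshift" %in% cfg$stages) {
    if (is.null(cohort$panel)) stop("config error: stage 'methshift' requires 'panel' (normal-tissue methylation)")
    if (is.null(cohort$tissue_map)) stop("config error: stage 'methshift' requires 'tissue_map'")
  }
  if ("context" %in% cfg$stages && is.null(cohort$tads)) {
    stop("config error: stage 'context' requires 'tads'")
  }
  cfg
}

#' Run the integration pipeline end to end
#'
#' Executes the requested stages in dependency order on a cohort bundle
#' (an `sv_cohort` from [simulate_cohort()]/[read_cohort()], or a bundle
#' directory path). The configuration is validated before any compute;
#' all randomness derives from the single `seed` entry, fanned out per
#' stage so that adding stages does not shift other stages' streams.
#'
#' @param cohort an `sv_cohort` or a bundle directory.
#' @param config named list overriding the default thresholds (FDR 5%
#'   pan-cancer, 10% per-type, 0.1% differential methylation, 0.4 SD
#'   alteration, 1 Mb distance cap, 500 kb hijack budget, 50 kb methylome
#'   window, 10 bp collapse), stage list and seed; or a YAML file path.
#' @return an `svcis_run` list: `manifest` (per-stage record) and
#'   `results` (per-stage outputs).
#' @export
run_pipeline <- function(cohort, config = list()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(cohort, config)
  manifest <- list(config = cfg, config_hash = object_hash(cfg),
                   input_hash = object_hash(lapply(
                     cohort[c("bps", "sample_info")], object_hash)),
                   stages = list())
  results <- list()
  record <- function(name, params, n_rows) {
    manifest$stages[[name]] <<- list(name = name, params = params,
                                     n_rows = n_rows,
                                     seed = cfg$seed + match(name, cfg$stages,
                                                             nomatch = 0L) * 1000L)
  }
  stage_on <- function(s) s %in% cfg$stages
  samples <- cohort$sample_info$sample_id
  sc <- scan_config(covariates = cfg$covariates)

  if (stage_on("features")) {
    results$dist <- distance_matrix(cohort$bps, cohort$genes, dmax = cfg$dmax,
                                    samples = samples)
    results$win <- window_matrix(cohort$bps, cohort$genes,
                                 window = "upstream_0_20kb", samples = samples)
    record("features", list(dmax = cfg$dmax), nrow(results$dist))
  }
  if (stage_on("expr_scan")) {
    if (is.null(results$dist)) stop("expr_scan requires the features stage")
    results$expr_scan <- sv_scan(cohort$expr, results$dist,
                                 cohort$sample_info, config = sc,
                                 cna = cohort$cna)
    record("expr_scan", list(fdr = cfg$fdr), nrow(results$expr_scan$results))
  }
  if (stage_on("meth_scan")) {
    if (is.null(results$dist)) stop("meth_scan requires the features stage")
    fmap <- setNames(cohort$probes$gene_id, cohort$probes$probe_id)
    results$meth_scan <- sv_scan(cohort$meth, results$dist,
                                 cohort$sample_info, config = sc,
                                 cna = cohort$cna, feature_map = fmap)
    record("meth_scan", list(fdr = cfg$fdr), nrow(results$meth_scan$results))
  }
  if (stage_on("permutation")) {
    results$permutation <- permutation_null(
      cohort$expr, results$dist, cohort$sample_info,
      n_perm = cfg$n_perm, alpha = cfg$perm_alpha,
      seed = cfg$seed + 1000L, config = sc, cna = cohort$cna)
    record("permutation", list(n_perm = cfg$n_perm), cfg$n_perm)
  }
  if (stage_on("overlap") && !is.null(results$expr_scan) &&
      !is.null(results$meth_scan)) {
    er <- results$expr_scan$results
    mr <- results$meth_scan$results
    fmap <- setNames(cohort$probes$gene_id, cohort$probes$probe_id)
    hits_e <- er$feature_id[er$status == "tested" & !is.na(er$q_value) &
                            er$q_value < cfg$fdr]
    hits_m_genes <- unique(fmap[mr$feature_id[mr$status == "tested" &
                                              !is.na(mr$q_value) &
                                              mr$q_value < cfg$fdr]])
    universe <- intersect(er$feature_id[er$status == "tested"],
                          unique(fmap[mr$feature_id[mr$status == "tested"]]))
    results$overlap <- set_overlap_test(hits_e, hits_m_genes, universe)
    record("overlap", list(fdr = cfg$fdr), 1L)
  }
  if (stage_on("context")) {
    results$tad_class <- classify_tad_disruption(cohort$bps, cohort$tads)
    alt_e <- alteration_calls(cohort$expr, samples,
                              threshold_sd = cfg$alteration_sd,
                              cna = cohort$cna,
                              cna_threshold = cfg$amp_del_log2)
    assoc <- upstream_bp_associations(cohort$bps, cohort$genes,
                                      max_dist = cfg$fusion_budget)
    hj <- enhancer_hijack_scan(assoc, cohort$genes, cohort$enhancers,
                               cohort$sample_info, cohort$type_map,
                               fusion_budget = cfg$fusion_budget,
                               native_budget = cfg$native_budget)
    results$hijack <- hj
    results$hijack_summary <- hijack_summary(hj, results$expr_scan, alt_e,
                                             fdr = cfg$fdr)
    record("context", list(fusion_budget = cfg$fusion_budget), nrow(hj))
  }
  if (stage_on("methshift")) {
    assoc_m <- build_cgi_associations(cohort$bps, cohort$genes, cohort$probes,
                                      samples, max_dist = cfg$dmax)
    alt_m <- alteration_calls(cohort$meth, samples,
                              threshold_sd = cfg$alteration_sd)
    results$methshift <- ssv_cgi_beta_shift(
      assoc_m, cohort$panel, cohort$tissue_map, cohort$sample_info,
      window = cfg$meth_window, scan = results$meth_scan,
      alterations = alt_m, fdr = cfg$fdr)
    record("methshift", list(window = cfg$meth_window),
           nrow(results$methshift$records))
  }
  if (stage_on("burden")) {
    collapsed <- collapse_ssvs(cohort$bps, tol = cfg$collapse_tol)
    results$burden <- burden_profile(collapsed, cohort$sample_info,
                                     meth = cohort$meth, cna = cohort$cna)
    results$burden_expr_scan <- burden_scan(
      cohort$expr, results$burden, cohort$sample_info,
      covariates = intersect(cfg$covariates, "cna"), cna = cohort$cna)
    record("burden", list(collapse_tol = cfg$collapse_tol),
           nrow(results$burden))
  }
  structure(list(manifest = manifest, results = results),
            class = "svcis_run")
}

# Deterministic content hash (md5 of the serialised object, version-pinned).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Human-readable run report
#'
#' Summarises a pipeline run: significant-feature counts by direction for
#' the expression and methylation scans, TAD-disruption fractions,
#' enhancer-hijack percentages by subset, methylome-shift subset means,
#' and burden-correlate counts.
#'
#' @param run an `svcis_run` from [run_pipeline()].
#' @param file connection or path for [cat()]; default prints to stdout.
#' @return the report lines, invisibly.
#' @export
write_report <- function(run, file = "") {
  res <- run$results
  cfg <- run$manifest$config
  lines <- c(sprintf("svcis run report (seed %d)", cfg$seed))
  count_dir <- function(scan, fdr) {
    r <- scan$results
    sig <- r$status == "tested" & !is.na(r$q_value) & r$q_value < fdr
    if (!any(r$status == "tested")) return("zero tested features")
    sprintf("%d significant at FDR<%g%% (+%d / -%d) of %d tested",
            sum(sig), 100 * fdr, sum(sig & r$direction == "+"),
            sum(sig & r$direction == "-"), sum(r$status == "tested"))
  }
  if (!is.null(res$expr_scan)) {
    lines <- c(lines, paste("expression ~ breakpoint distance:",
                            count_dir(res$expr_scan, cfg$fdr)))
  }
  if (!is.null(res$meth_scan)) {
    lines <- c(lines, paste("CGI methylation ~ breakpoint distance:",
                            count_dir(res$meth_scan, cfg$fdr)))
  }
  if (!is.null(res$overlap)) {
    o <- res$overlap
    lines <- c(lines, sprintf(
      "expression/methylation gene overlap: %d observed vs %.1f expected (p=%.3g)",
      o$n_overlap, o$expected_overlap, o$p_value))
  }
  if (!is.null(res$tad_class)) {
    lines <- c(lines, sprintf("TAD-disrupting SSVs: %.1f%% of %d",
                              100 * mean(res$tad_class == "disrupting"),
                              length(res$tad_class)))
  }
  if (!is.null(res$hijack_summary)) {
    h <- res$hijack_summary
    lines <- c(lines, paste0(
      "enhancer hijack: ",
      paste(sprintf("%s %.1f%% (%d/%d)", h$subset, h$pct_hijack,
                    h$n_hijack, h$n), collapse = "; ")))
  }
  if (!is.null(res$methshift)) {
    s <- res$methshift$summary
    lines <- c(lines, paste0(
      "rearranged-region beta shift: ",
      paste(sprintf("%s mean delta %+.3f (n=%d)", s$subset, s$mean_delta, s$n),
            collapse = "; ")))
  }
  if (!is.null(res$burden_expr_scan)) {
    lines <- c(lines, paste("expression ~ SSV burden:",
                            count_dir(res$burden_expr_scan, cfg$fdr)))
  }
  if (length(lines) == 1) lines <- c(lines, "zero tested features")
  cat(paste(lines, collapse = "\n"), "\n", sep = "", file = file)
  invisible(lines)
}

#' @export
print.svcis_run <- function(x, ...) {
  cat(sprintf("svcis_run: %d stage(s) completed\n",
              length(x$manifest$stages)))
  for (st in x$manifest$stages) {
    cat(sprintf("  %-12s rows=%d\n", st$name, st$n_rows))
  }
  invisible(x)
}
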
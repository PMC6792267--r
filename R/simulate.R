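# Synthetic multi-omic cohort generator.
#
# Emulates the statistical structure the integration analyses assume:
# per-sample SSV breakpoint sets with a class/size mix and coverage-
# dependent detection, cancer-type-structured expression and methylation
# baselines, CNA coupled to breakpoints with a linear dosage effect on
# expression, planted cis-effects of breakpoints on expression (log2
# scale) and CGI methylation (logit scale), TAD-spanning planted SSVs,
# orientation-consistent enhancer-hijack events, and burden-coupled
# global hypomethylation -- together with a ground-truth ledger for
# recovery scoring.

#' Simulation configuration
#'
#' Defaults describe a desk-scale cohort: 300 samples over three cancer
#' types, 2,000 genes with three CGI probes each (promoter, gene body,
#' flanking), ~60 SSVs per high-pass sample with a deletion-heavy class
#' mix and log-uniform sizes of 1 kb - 10 Mb, planted cis effects of 1.0
#' (log2 expression) and 1.0 (logit methylation) in 10% of samples, CNA
#' gains coupled to breakpoints, and a global methylation decrease with
#' SSV burden.
#'
#' @param n_samples cohort size.
#' @param cancer_types named proportions (must sum to 1).
#' @param n_genes autosomal gene count.
#' @param n_probes_per_gene CGI probes per gene (promoter/body/other cycle).
#' @param n_chrom,chrom_length synthetic autosome count and length (bp);
#'   the defaults give a 1 Gb genome so that ~60 SSVs per sample matches
#'   the breakpoint density of real pan-cancer WGS call sets.
#' @param ssv_rate expected SSV calls per high-pass sample.
#' @param burden_dispersion SD (log scale) of the per-sample rate mixing
#'   distribution: SSV counts are Poisson with log-normally varying
#'   per-sample rates, reflecting the orders-of-magnitude spread of
#'   structural-variation burden across real tumors.
#' @param lowpass_detection multiplier on `ssv_rate` for low-pass samples
#'   (low-coverage sequencing misses events).
#' @param lowpass_fraction fraction of samples with low-pass WGS.
#' @param class_mix named SSV class probabilities.
#' @param size_range intra-chromosomal SSV size range (log-uniform), bp.
#' @param planted named list of planted-feature counts: `expr_up`,
#'   `expr_down`, `meth_up`, `meth_down`, `burden_linked`, `hijack`
#'   (subset of `expr_up`), `joint_per_type` (per-cancer-type genes with
#'   both type-high methylation and a type-restricted expression effect).
#' @param carrier_fraction fraction of samples carrying each planted SSV.
#' @param effect_expr planted expression effect, log2 units.
#' @param effect_meth planted methylation effect, logit units.
#' @param joint_effect_expr expression effect of joint (per-type) genes.
#' @param joint_shift_meth type-wide logit shift of joint genes' probes.
#' @param cna_coupling probability that a gene with a breakpoint within
#'   100 kb gains copy; `cna_gain` the log2 gain; `dosage_effect` the
#'   log2-expression change per CNA unit.
#' @param cna_gain,dosage_effect see `cna_coupling`.
#' @param burden_slope global logit-methylation decrease per SD of
#'   log2 SSV count.
#' @param burden_slope_expr log2-expression increase of burden-linked
#'   genes per SD of log2 SSV count.
#' @param tad_span_prob probability a planted-effect SSV spans TADs.
#' @param noise_sd_expr,type_sd_expr residual and cancer-type SDs of log2
#'   expression.
#' @param noise_sd_meth,type_sd_meth,probe_sd_meth residual, cancer-type
#'   and per-probe baseline SDs on the logit scale.
#' @param n_enhancers,n_low_regions enhancer count and count of 100 kb
#'   low-methylation genomic segments in the normal panel.
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 300,
                       cancer_types = c(breast = 0.4, lung = 0.35, colorectal = 0.25),
                       n_genes = 2000, n_probes_per_gene = 3,
                       n_chrom = 4, chrom_length = 2.5e8,
                       ssv_rate = 60, burden_dispersion = 0.5,
                       lowpass_detection = 0.5,
                       lowpass_fraction = 0.45,
                       class_mix = c(deletion = 0.35, duplication = 0.25,
                                     inversion = 0.2, translocation = 0.2),
                       size_range = c(1e3, 1e7),
                       planted = list(expr_up = 15, expr_down = 5,
                                      meth_up = 10, meth_down = 10,
                                      burden_linked = 20, hijack = 4,
                                      joint_per_type = 2),
                       carrier_fraction = 0.1,
                       effect_expr = 1.0, effect_meth = 1.0,
                       joint_effect_expr = 2.0, joint_shift_meth = 1.8,
                       cna_coupling = 0.3, cna_gain = 1.2, dosage_effect = 0.9,
                       burden_slope = 0.2, burden_slope_expr = 0.5,
                       tad_span_prob = 0.9,
                       noise_sd_expr = 1.0, type_sd_expr = 0.6,
                       noise_sd_meth = 0.5, type_sd_meth = 0.3,
                       probe_sd_meth = 0.4,
                       n_enhancers = 400, n_low_regions = 30,
                       seed = 1) {
  cfg <- as.list(environment())
  if (abs(sum(cancer_types) - 1) > 1e-8) stop("cancer_types proportions must sum to 1")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (carrier_fraction <= 0 || carrier_fraction > 1) {
    stop("carrier_fraction must lie in (0, 1]")
  }
  if (round(carrier_fraction * n_samples) < 1) stop("carrier count rounds to zero")
  if (any(unlist(planted) < 0) || ssv_rate < 0 || burden_slope < 0) {
    stop("rates and planted counts must be non-negative")
  }
  n_planted_genes <- planted$expr_up + planted$expr_down + planted$meth_up +
    planted$meth_down + planted$burden_linked +
    planted$joint_per_type * length(cancer_types)
  if (n_planted_genes > n_genes / 4) stop("too many planted genes for n_genes")
  if ((planted$hijack %||% 0) > planted$expr_up) {
    stop("hijack genes must be a subset of expr_up genes")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Zero-effect configuration for null calibration
#'
#' The same cohort structure with no planted effects and no
#' burden-methylation coupling; breakpoint-coupled CNA (and its dosage
#' effect on expression) is retained, since the scans adjust for it.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
null_sim_config <- function(...) {
  sim_config(planted = list(expr_up = 0, expr_down = 0, meth_up = 0,
                            meth_down = 0, burden_linked = 0, hijack = 0,
                            joint_per_type = 0),
             burden_slope = 0, burden_slope_expr = 0, ...)
}

#' Simulate a multi-omic cohort with a ground-truth ledger
#'
#' @param cfg a [sim_config()].
#' @return a `sv_cohort` list with elements `bps`, `expr`, `meth`, `cna`
#'   ([omics_matrix()]s), `genes`, `probes`, `tads`, `enhancers`,
#'   `type_map`, `tissue_map`, `panel`, `sample_info`, `truth` (list with
#'   `features` and `ssvs` data frames) and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  chrom_len <- setNames(rep(cfg$chrom_length, cfg$n_chrom), chroms)

  ## TADs: sequential blocks with 50 kb gaps
  tads <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- ends <- numeric(0)
    pos <- 0
    while (pos < chrom_len[ch] - 1.5e6) {
      len <- runif(1, 6e5, 1.4e6)
      starts <- c(starts, pos)
      ends <- c(ends, pos + len)
      pos <- pos + len + 5e4
    }
    data.frame(chrom = ch, start = round(starts), end = round(ends),
               stringsAsFactors = FALSE)
  }))

  ## genes
  margin <- 1.5e6
  g_chrom <- sample(chroms, cfg$n_genes, replace = TRUE)
  g_len <- round(runif(cfg$n_genes, 5e3, 1e5))
  g_start <- round(runif(cfg$n_genes, margin, chrom_len[g_chrom] - margin - g_len))
  genes <- data.frame(gene_id = "", chrom = g_chrom, start = g_start,
                      end = g_start + g_len,
                      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), ]
  genes$gene_id <- sprintf("gene%04d", seq_len(cfg$n_genes))
  genes <- gene_table(genes)

  ## CGI probes: promoter / gene body / flanking per gene
  classes <- rep(c("promoter", "gene_body", "other"),
                 length.out = cfg$n_probes_per_gene)
  upstream_sign <- ifelse(genes$strand == "+", -1, 1)
  probes <- do.call(rbind, lapply(seq_along(classes), function(k) {
    pos <- switch(classes[k],
      promoter = genes$tss + upstream_sign * 300,
      gene_body = round((genes$start + genes$end) / 2),
      other = genes$end * (genes$strand == "+") +
        genes$start * (genes$strand == "-") - upstream_sign * 3e4)
    data.frame(probe_id = "", chrom = genes$chrom, pos = round(pos),
               cgi_id = paste0("cgi_", genes$gene_id),
               gene_id = genes$gene_id, region_class = classes[k],
               stringsAsFactors = FALSE)
  }))
  probes <- probes[order(probes$gene_id, probes$region_class), ]
  probes$probe_id <- sprintf("probe%05d", seq_len(nrow(probes)))
  probes <- probe_table(probes)

  ## samples
  types <- names(cfg$cancer_types)
  sample_type <- sample(types, cfg$n_samples, replace = TRUE,
                        prob = cfg$cancer_types)
  project <- paste0(sample_type, "_proj1")
  split2 <- sample_type == types[1] & runif(cfg$n_samples) < 0.5
  project[split2] <- paste0(types[1], "_proj2")
  purity <- round(runif(cfg$n_samples, 0.3, 0.95), 3)
  purity[runif(cfg$n_samples) < 0.05] <- NA
  sample_info <- data.frame(
    sample_id = sprintf("s%04d", seq_len(cfg$n_samples)),
    project = project, cancer_type = sample_type,
    wgs_pass = ifelse(runif(cfg$n_samples) < cfg$lowpass_fraction, "low", "high"),
    purity = purity,
    ploidy = round(rnorm(cfg$n_samples, 2.1, 0.4), 3),
    age = sample(35:85, cfg$n_samples, replace = TRUE),
    stringsAsFactors = FALSE
  )

  ## planted feature assignment (disjoint gene sets)
  pl <- cfg$planted
  n_joint <- pl$joint_per_type * length(types)
  pool <- sample(genes$gene_id)
  take <- function(n) {
    if (n == 0) return(character(0))
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  g_expr_up <- take(pl$expr_up)
  g_hijack <- head(g_expr_up, pl$hijack %||% 0)
  g_expr_down <- take(pl$expr_down)
  g_meth_up <- take(pl$meth_up)
  g_meth_down <- take(pl$meth_down)
  g_burden <- take(pl$burden_linked)
  g_joint <- take(n_joint)
  joint_type <- rep(types, each = pl$joint_per_type)

  ## low-methylation genomic segments (for the normal panel and as the
  ## source regions of meth_down rearrangements)
  low_regions <- data.frame(
    chrom = sample(chroms, cfg$n_low_regions, replace = TRUE),
    start = 0, end = 0, stringsAsFactors = FALSE)
  low_regions$start <- round(runif(cfg$n_low_regions, 0,
                                   chrom_len[low_regions$chrom] - 1e5))
  low_regions$end <- low_regions$start + 1e5

  ## background SSVs (coverage-dependent detection)
  rate <- cfg$ssv_rate *
    exp(rnorm(cfg$n_samples, -cfg$burden_dispersion^2 / 2,
              cfg$burden_dispersion)) *
    ifelse(sample_info$wgs_pass == "low", cfg$lowpass_detection, 1)
  n_bg <- rpois(cfg$n_samples, rate)
  tot <- sum(n_bg)
  bg_class <- sample(names(cfg$class_mix), tot, replace = TRUE, prob = cfg$class_mix)
  bg_chrom1 <- sample(chroms, tot, replace = TRUE)
  bg_size <- round(10^runif(tot, log10(cfg$size_range[1]), log10(cfg$size_range[2])))
  inter <- bg_class == "translocation"
  bg_pos1 <- round(runif(tot, 0, chrom_len[bg_chrom1] - ifelse(inter, 0, bg_size)))
  bg_chrom2 <- bg_chrom1
  bg_chrom2[inter] <- vapply(bg_chrom1[inter], function(ch)
    sample(setdiff(chroms, ch), 1), character(1))
  bg_pos2 <- bg_pos1 + bg_size
  bg_pos2[inter] <- round(runif(sum(inter), 0, chrom_len[bg_chrom2[inter]]))
  o1 <- ifelse(bg_class == "deletion", "+",
        ifelse(bg_class == "duplication", "-",
        sample(c("+", "-"), tot, replace = TRUE)))
  o2 <- ifelse(bg_class == "deletion", "-",
        ifelse(bg_class == "duplication", "+",
        ifelse(bg_class == "inversion", o1,
        sample(c("+", "-"), tot, replace = TRUE))))
  background <- data.frame(
    ssv_id = sprintf("b%06d", seq_len(tot)),
    sample_id = rep(sample_info$sample_id, n_bg),
    chrom1 = bg_chrom1, pos1 = bg_pos1, orient1 = o1,
    chrom2 = bg_chrom2, pos2 = bg_pos2, orient2 = o2,
    sv_class = bg_class, stringsAsFactors = FALSE
  )

  ## planted cis SSVs
  planted_rows <- list()
  truth_ssv <- list()
  hijack_enh <- list()
  carriers_of <- list()
  plant <- function(gene_ids, effect_type, restrict_type = NULL) {
    for (k in seq_along(gene_ids)) {
      g <- gene_ids[k]
      gi <- match(g, genes$gene_id)
      eligible <- if (is.null(restrict_type)) sample_info$sample_id
        else sample_info$sample_id[sample_info$cancer_type == restrict_type[k]]
      n_car <- max(1, round(cfg$carrier_fraction * length(eligible)))
      if (n_car > length(eligible)) stop("infeasible config: carriers exceed samples")
      car <- sample(eligible, n_car)
      carriers_of[[paste(effect_type, g)]] <<- car
      up <- ifelse(genes$strand[gi] == "+", -1, 1)
      d <- round(runif(n_car, 1e3, 1.8e4))
      pos1 <- genes$tss[gi] + up * d
      span <- runif(n_car) < cfg$tad_span_prob
      is_hijack <- effect_type == "expr_up" && g %in% g_hijack
      # a hijack needs a distal mate: a short-range rearrangement cannot
      # translocate an enhancer toward a gene lacking one within 1 Mb
      if (is_hijack) span <- rep(TRUE, n_car)
      chrom2 <- rep(genes$chrom[gi], n_car)
      pos2 <- numeric(n_car)
      if (effect_type == "meth_down") {
        # mate lands in a normally low-methylated segment
        reg <- sample(nrow(low_regions), n_car, replace = TRUE)
        chrom2 <- low_regions$chrom[reg]
        pos2 <- round(runif(n_car, low_regions$start[reg] + 2e4,
                            low_regions$end[reg] - 2e4))
        span <- rep(TRUE, n_car)
      } else {
        far <- round(pos1 + sample(c(-1, 1), n_car, TRUE) * runif(n_car, 3e6, 8e6))
        far <- pmin(pmax(far, 1e4), chrom_len[genes$chrom[gi]] - 1e4)
        near <- round(pos1 + runif(n_car, 1e3, 6e4))
        pos2 <- ifelse(span, far, near)
      }
      orient1 <- if (is_hijack) rep(ifelse(genes$strand[gi] == "+", "-", "+"), n_car)
        else sample(c("+", "-"), n_car, replace = TRUE)
      orient2 <- sample(c("+", "-"), n_car, replace = TRUE)
      if (is_hijack) {
        orient2 <- rep("+", n_car)  # retained flank = lower coordinates
        emid <- pmax(pos2 - round(runif(n_car, 5e4, 2e5)), 1e3)
        hijack_enh[[g]] <<- data.frame(
          chrom = chrom2, start = emid - 500, end = emid + 500,
          specificity = "ubiquitous", stringsAsFactors = FALSE)
      }
      ids <- sprintf("p_%s_%s_%02d", effect_type, g, seq_len(n_car))
      planted_rows[[length(planted_rows) + 1]] <<- data.frame(
        ssv_id = ids, sample_id = car,
        chrom1 = genes$chrom[gi], pos1 = pos1, orient1 = orient1,
        chrom2 = chrom2, pos2 = pos2, orient2 = orient2,
        sv_class = NA_character_, stringsAsFactors = FALSE)
      truth_ssv[[length(truth_ssv) + 1]] <<- data.frame(
        ssv_id = ids, feature_gene = g, effect_type = effect_type,
        sample_id = car, span_intended = span, stringsAsFactors = FALSE)
    }
  }
  plant(g_expr_up, "expr_up")
  plant(g_expr_down, "expr_down")
  plant(g_meth_up, "meth_up")
  plant(g_meth_down, "meth_down")
  if (n_joint) plant(g_joint, "joint", restrict_type = joint_type)

  planted_df <- if (length(planted_rows)) do.call(rbind, planted_rows) else NULL
  if (!is.null(planted_df)) {
    planted_df$sv_class <- infer_sv_class(planted_df$chrom1, planted_df$chrom2,
                                          planted_df$orient1, planted_df$orient2)
  }
  bps <- breakpoint_set(rbind(background, planted_df))

  ## enhancers: random plus the planted hijack sources; hijack genes'
  ## 1 Mb neighbourhoods are kept enhancer-free
  e_chrom <- sample(chroms, cfg$n_enhancers, replace = TRUE)
  e_start <- round(runif(cfg$n_enhancers, 0, chrom_len[e_chrom] - 1e3))
  tags <- c("ubiquitous", paste0(types, "_cells"))
  enh <- data.frame(chrom = e_chrom, start = e_start, end = e_start + 1e3,
                    specificity = sample(tags, cfg$n_enhancers, replace = TRUE,
                                         prob = c(0.3, rep(0.7 / length(types),
                                                           length(types)))),
                    stringsAsFactors = FALSE)
  if (length(g_hijack)) {
    hz <- genes[match(g_hijack, genes$gene_id), ]
    emid <- (enh$start + enh$end) / 2
    clear <- rep(TRUE, nrow(enh))
    for (i in seq_len(nrow(hz))) {
      clear <- clear & !(enh$chrom == hz$chrom[i] & abs(emid - hz$tss[i]) <= 1.05e6)
    }
    enh <- rbind(enh[clear, ], do.call(rbind, hijack_enh))
  }
  enh <- enh[order(enh$chrom, enh$start), ]
  rownames(enh) <- NULL
  type_map <- data.frame(cancer_type = types, tag = paste0(types, "_cells"),
                         stringsAsFactors = FALSE)

  ## burden (uses detected counts, i.e. the emitted call set)
  counts <- table(factor(bps$sample_id, levels = sample_info$sample_id))
  log_total <- log2(as.numeric(counts) + 1)
  z_burden <- as.numeric(scale(log_total))

  ## CNA coupled to breakpoints
  sn <- sample_info$sample_id
  cna_vals <- matrix(rnorm(cfg$n_genes * cfg$n_samples, 0, 0.2),
                     cfg$n_genes, cfg$n_samples,
                     dimnames = list(genes$gene_id, sn))
  near_bp <- distance_matrix(bps, genes, dmax = 1e5, samples = sn)
  gained <- near_bp[, sn] < 1e5 &
    matrix(runif(cfg$n_genes * cfg$n_samples) < cfg$cna_coupling,
           cfg$n_genes, cfg$n_samples)
  cna_vals <- cna_vals + gained * cfg$cna_gain
  cna <- omics_matrix(round(cna_vals, 4), "cna_log2")

  ## expression (log2 scale, then back-transformed)
  mu_g <- rnorm(cfg$n_genes, 6, 1.5)
  type_eff <- matrix(rnorm(cfg$n_genes * length(types), 0, cfg$type_sd_expr),
                     cfg$n_genes, length(types), dimnames = list(genes$gene_id, types))
  ev <- mu_g + type_eff[, sample_type] + cfg$dosage_effect * cna_vals +
    matrix(rnorm(cfg$n_genes * cfg$n_samples, 0, cfg$noise_sd_expr),
           cfg$n_genes, cfg$n_samples)
  dimnames(ev) <- list(genes$gene_id, sn)
  add_expr <- function(g, car, eff) ev[g, car] <<- ev[g, car] + eff
  for (g in g_expr_up) add_expr(g, carriers_of[[paste("expr_up", g)]], cfg$effect_expr)
  for (g in g_expr_down) add_expr(g, carriers_of[[paste("expr_down", g)]], -cfg$effect_expr)
  for (g in g_joint) add_expr(g, carriers_of[[paste("joint", g)]], cfg$joint_effect_expr)
  if (length(g_burden)) {
    ev[g_burden, ] <- ev[g_burden, ] +
      rep(cfg$burden_slope_expr * z_burden, each = length(g_burden))
  }
  expr <- omics_matrix(round(pmax(2^ev - 1, 0), 4), "expression")

  ## methylation (logit scale)
  class_mean <- c(promoter = qlogis(0.1), gene_body = qlogis(0.5),
                  other = qlogis(0.8))
  n_probes <- nrow(probes)
  probe_base <- class_mean[probes$region_class] +
    rnorm(n_probes, 0, cfg$probe_sd_meth)
  type_eff_m <- matrix(rnorm(n_probes * length(types), 0, cfg$type_sd_meth),
                       n_probes, length(types), dimnames = list(probes$probe_id, types))
  mv <- probe_base + type_eff_m[, sample_type] +
    matrix(rnorm(n_probes * cfg$n_samples, 0, cfg$noise_sd_meth),
           n_probes, cfg$n_samples) -
    rep(cfg$burden_slope * z_burden, each = n_probes)
  dimnames(mv) <- list(probes$probe_id, sn)
  probe_of <- function(g, cls) {
    pr <- probes$probe_id[probes$gene_id == g & probes$region_class == cls][1]
    if (is.na(pr)) pr <- probes$probe_id[probes$gene_id == g][1]
    pr
  }
  planted_probes <- list()
  for (g in g_meth_up) {
    pr <- probe_of(g, "promoter")
    car <- carriers_of[[paste("meth_up", g)]]
    mv[pr, car] <- mv[pr, car] + cfg$effect_meth
    planted_probes[[g]] <- pr
  }
  for (g in g_meth_down) {
    pr <- probe_of(g, "gene_body")
    car <- carriers_of[[paste("meth_down", g)]]
    mv[pr, car] <- mv[pr, car] - cfg$effect_meth
    planted_probes[[g]] <- pr
  }
  for (k in seq_along(g_joint)) {
    g <- g_joint[k]
    pr <- probes$probe_id[probes$gene_id == g]
    in_type <- sn[sample_type == joint_type[k]]
    mv[pr, in_type] <- mv[pr, in_type] + cfg$joint_shift_meth
    planted_probes[[g]] <- probe_of(g, "promoter")
  }
  meth <- omics_matrix(round(pmin(pmax(plogis(mv), 0.001), 0.999), 4),
                       "methylation_beta")

  ## normal-tissue methylation panel: cohort probes plus a genome-wide
  ## background grid with high baseline methylation outside CGIs and
  ## designated low-methylation segments
  grid_step <- 2e4
  bg_probes <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- seq(1e4, chrom_len[ch] - 1e4, by = grid_step)
    data.frame(probe_id = sprintf("bg_%s_%07d", ch, seq_along(pos)),
               chrom = ch, pos = round(pos), stringsAsFactors = FALSE)
  }))
  in_low <- rep(FALSE, nrow(bg_probes))
  for (i in seq_len(nrow(low_regions))) {
    in_low <- in_low | (bg_probes$chrom == low_regions$chrom[i] &
                        bg_probes$pos >= low_regions$start[i] &
                        bg_probes$pos < low_regions$end[i])
  }
  tissues <- paste0(types, "_normal")
  panel_probes <- rbind(probes[, c("probe_id", "chrom", "pos")],
                        bg_probes)
  base_logit <- c(class_mean[probes$region_class],
                  ifelse(in_low, qlogis(0.1), qlogis(0.8)))
  pb <- matrix(plogis(base_logit +
                      rnorm(nrow(panel_probes) * length(tissues), 0, 0.25)),
               nrow(panel_probes), length(tissues),
               dimnames = list(NULL, tissues))
  panel <- normal_panel(panel_probes, round(pb, 4))
  tissue_map <- data.frame(cancer_type = types, tissue = tissues,
                           stringsAsFactors = FALSE)

  ## ground-truth ledger
  feat_row <- function(g, type, eff, probe = NA_character_,
                       jtype = NA_character_) {
    car <- carriers_of[[paste(type, g)]]
    data.frame(feature_id = if (type %in% c("meth_up", "meth_down")) probe else g,
               gene_id = g, effect_type = type, effect_size = eff,
               n_carriers = length(car),
               carriers = paste(sort(car), collapse = ","),
               hijack = type == "expr_up" && g %in% g_hijack,
               joint_type = jtype, probe_id = probe,
               stringsAsFactors = FALSE)
  }
  truth_features <- rbind(
    do.call(rbind, lapply(g_expr_up, feat_row, type = "expr_up", eff = cfg$effect_expr)),
    do.call(rbind, lapply(g_expr_down, feat_row, type = "expr_down", eff = -cfg$effect_expr)),
    do.call(rbind, lapply(g_meth_up, function(g)
      feat_row(g, "meth_up", cfg$effect_meth, planted_probes[[g]]))),
    do.call(rbind, lapply(g_meth_down, function(g)
      feat_row(g, "meth_down", -cfg$effect_meth, planted_probes[[g]]))),
    if (length(g_burden)) data.frame(
      feature_id = g_burden, gene_id = g_burden, effect_type = "burden_linked",
      effect_size = cfg$burden_slope_expr, n_carriers = cfg$n_samples,
      carriers = "", hijack = FALSE, joint_type = NA_character_,
      probe_id = NA_character_, stringsAsFactors = FALSE),
    if (n_joint) do.call(rbind, lapply(seq_along(g_joint), function(k)
      feat_row(g_joint[k], "joint", cfg$joint_effect_expr,
               probe = planted_probes[[g_joint[k]]], jtype = joint_type[k])))
  )
  if (is.null(truth_features)) {
    truth_features <- data.frame(
      feature_id = character(), gene_id = character(),
      effect_type = character(), effect_size = numeric(),
      n_carriers = integer(), carriers = character(), hijack = logical(),
      joint_type = character(), probe_id = character(),
      stringsAsFactors = FALSE)
  }
  truth_ssvs <- if (length(truth_ssv)) do.call(rbind, truth_ssv) else
    data.frame(ssv_id = character(), feature_gene = character(),
               effect_type = character(), sample_id = character(),
               span_intended = logical(), stringsAsFactors = FALSE)

  structure(list(bps = bps, expr = expr, meth = meth, cna = cna,
                 genes = genes, probes = probes, tads = tads,
                 enhancers = enh, type_map = type_map,
                 tissue_map = tissue_map, panel = panel,
                 sample_info = sample_info,
                 truth = list(features = truth_features, ssvs = truth_ssvs),
                 config = cfg),
            class = "sv_cohort")
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat(sprintf("sv_cohort: %d samples, %d genes, %d probes, %d SSVs\n",
              nrow(x$sample_info), nrow(x$genes), nrow(x$probes), nrow(x$bps)))
  if (!is.null(x$truth$features)) {
    tab <- table(x$truth$features$effect_type)
    cat("  planted:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a simulated cohort as a plain-text file bundle
#'
#' Emits the full input bundle (BEDPE, TSV matrices, BED annotation,
#' sample table, normal panel, truth ledger) in the formats the loaders
#' read back.
#'
#' @param cohort an `sv_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_ssv_bedpe(cohort$bps, p("ssvs.bedpe"))
  write_omics_matrix(cohort$expr, p("expression.tsv"))
  write_omics_matrix(cohort$meth, p("methylation.tsv"))
  write_omics_matrix(cohort$cna, p("cna.tsv"))
  write_gene_table(cohort$genes, p("genes.tsv"))
  write.table(cohort$probes, p("probes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bed(cohort$tads, p("tads.bed"))
  write_bed(cohort$enhancers, p("enhancers.bed"), extra_cols = "specificity")
  write.table(cohort$sample_info, p("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$type_map, p("type_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$tissue_map, p("tissue_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_normal_panel(cohort$panel, p("normal_panel.tsv"))
  write.table(cohort$truth$features, p("truth_features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth$ssvs, p("truth_ssvs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir bundle directory.
#' @return an `sv_cohort` (without the generating config).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  truth <- NULL
  if (file.exists(p("truth_features.tsv"))) {
    truth <- list(
      features = read.delim(p("truth_features.tsv"), stringsAsFactors = FALSE),
      ssvs = read.delim(p("truth_ssvs.tsv"), stringsAsFactors = FALSE))
  }
  structure(list(
    bps = read_ssv_bedpe(p("ssvs.bedpe")),
    expr = read_omics_matrix(p("expression.tsv"), "expression"),
    meth = read_omics_matrix(p("methylation.tsv"), "methylation_beta"),
    cna = read_omics_matrix(p("cna.tsv"), "cna_log2"),
    genes = read_gene_table(p("genes.tsv")),
    probes = read_probe_table(p("probes.tsv")),
    tads = read_bed(p("tads.bed")),
    enhancers = read_bed(p("enhancers.bed"), extra_names = "specificity"),
    type_map = read.delim(p("type_map.tsv"), stringsAsFactors = FALSE),
    tissue_map = read.delim(p("tissue_map.tsv"), stringsAsFactors = FALSE),
    panel = read_normal_panel(p("normal_panel.tsv")),
    sample_info = read_sample_table(p("samples.tsv")),
    truth = truth), class = "sv_cohort")
}

#' Score recovery of planted effects by a scan
#'
#' Compares a scan's discoveries (tested features with q below the
#' threshold) against the truth ledger. Recall and sign accuracy are
#' computed over the planted features of the requested effect types;
#' the empirical FDR counts as false only those discoveries with no
#' planted effect of *any* type (a burden-linked gene picked up by a
#' cis scan carries a real simulated signal and is not a false positive).
#'
#' @param truth the `truth` element of an `sv_cohort`.
#' @param scan an [sv_scan()] result.
#' @param q_threshold discovery cutoff (default 0.05).
#' @param effect_types which planted types the scan is expected to
#'   recover (e.g. `c("expr_up", "expr_down")`).
#' @return list with `recall`, `precision`, `sign_accuracy`,
#'   `empirical_fdr`, `n_discoveries`, `n_true`.
#' @export
evaluate_recovery <- function(truth, scan, q_threshold = 0.05,
                              effect_types = c("expr_up", "expr_down")) {
  r <- scan$results
  tf <- truth$features
  relevant <- tf[tf$effect_type %in% effect_types, , drop = FALSE]
  if (nrow(relevant) && !any(relevant$feature_id %in% r$feature_id)) {
    stop("disjoint feature universes between truth and scan")
  }
  disc <- r$feature_id[r$status == "tested" & !is.na(r$q_value) &
                       r$q_value < q_threshold]
  true_ids <- intersect(relevant$feature_id, r$feature_id)
  any_planted <- unique(c(tf$feature_id, tf$gene_id))
  n_disc <- length(disc)
  false_disc <- setdiff(disc, any_planted)
  hit <- intersect(disc, true_ids)
  expected_dir <- setNames(ifelse(relevant$effect_size >= 0, "+", "-"),
                           relevant$feature_id)
  dirs <- setNames(r$direction, r$feature_id)[hit]
  list(
    recall = if (length(true_ids)) length(hit) / length(true_ids) else NA_real_,
    precision = if (n_disc) length(intersect(disc, any_planted)) / n_disc else NA_real_,
    sign_accuracy = if (length(hit)) mean(dirs == expected_dir[hit]) else NA_real_,
    empirical_fdr = if (n_disc) length(false_disc) / n_disc else NA_real_,
    n_discoveries = n_disc, n_true = length(true_ids)
  )
}
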
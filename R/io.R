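# Data model and readers/writers for the standard formats the pipeline touches.
#
# Internal coordinate convention: 0-based half-open for intervals, 0-based
# positions for breakpoints.  BED/BEDPE files are read and written in the
# native 0-based half-open dialect; tabular gene/probe files carry the same
# internal coordinates.

## ---- breakpoint sets (BEDPE) -------------------------------------------

#' Construct a breakpoint set from a data frame of SSV calls
#'
#' An SSV (somatic structural variant) joins two genomic coordinates at a
#' breakpoint junction; each call contributes two breakpoints with
#' orientations denoting which flank of each breakpoint is retained in the
#' derivative junction (`+` = upstream/lower coordinates retained, `-` =
#' downstream retained). Intra-chromosomal calls are normalised so that
#' `pos1 <= pos2` (orientations travel with their ends).
#'
#' @param df data frame with columns `sample_id`, `chrom1`, `pos1`,
#'   `orient1`, `chrom2`, `pos2`, `orient2` and optionally `sv_class`.
#' @return a `breakpoint_set` data frame with an `ssv_id` column and a
#'   `size` column (`NA` for inter-chromosomal calls).
#' @export
breakpoint_set <- function(df) {
  need <- c("sample_id", "chrom1", "pos1", "orient1", "chrom2", "pos2", "orient2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("breakpoint_set: missing columns: ", paste(miss, collapse = ", "))
  df$pos1 <- as.numeric(df$pos1)
  df$pos2 <- as.numeric(df$pos2)
  if (any(is.na(df$pos1)) || any(is.na(df$pos2))) {
    stop("breakpoint_set: non-numeric breakpoint positions (rows ",
         paste(which(is.na(df$pos1) | is.na(df$pos2)), collapse = ", "), ")")
  }
  bad <- !(df$orient1 %in% c("+", "-")) | !(df$orient2 %in% c("+", "-"))
  if (any(bad)) stop("breakpoint_set: invalid orientations (rows ",
                     paste(which(bad), collapse = ", "), ")")
  if (is.null(df$sv_class)) {
    df$sv_class <- infer_sv_class(df$chrom1, df$chrom2, df$orient1, df$orient2)
  }
  swap <- df$chrom1 == df$chrom2 & df$pos1 > df$pos2
  if (any(swap)) {
    tmp <- df[swap, c("pos1", "orient1")]
    df$pos1[swap] <- df$pos2[swap]
    df$orient1[swap] <- df$orient2[swap]
    df$pos2[swap] <- tmp$pos1
    df$orient2[swap] <- tmp$orient1
  }
  df$size <- ifelse(df$chrom1 == df$chrom2, df$pos2 - df$pos1, NA_real_)
  if (is.null(df$ssv_id)) df$ssv_id <- sprintf("ssv%06d", seq_len(nrow(df)))
  keep <- c("ssv_id", "sample_id", "chrom1", "pos1", "orient1",
            "chrom2", "pos2", "orient2", "sv_class", "size")
  df <- df[, keep]
  rownames(df) <- NULL
  class(df) <- c("breakpoint_set", "data.frame")
  df
}

# Junction-geometry heuristic used only when no class column is supplied.
infer_sv_class <- function(chrom1, chrom2, orient1, orient2) {
  out <- rep("other", length(chrom1))
  inter <- chrom1 != chrom2
  out[inter] <- "translocation"
  key <- paste0(orient1, orient2)
  out[!inter & key == "+-"] <- "deletion"
  out[!inter & key == "-+"] <- "duplication"
  out[!inter & key %in% c("++", "--")] <- "inversion"
  out
}

#' Read SSV calls from a BEDPE file
#'
#' Expects 10+ columns: two 0-based half-open intervals (columns 1-6), name
#' (7), score (8), and the two breakpoint orientations (9-10). Column 11, if
#' present, carries the sample id (otherwise the name field is used) and
#' column 12 the SV class. The breakpoint position of each end is the
#' interval start.
#'
#' @param path path to a BEDPE file.
#' @return a [breakpoint_set()].
#' @export
read_ssv_bedpe <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 10) {
    stop("BEDPE must have >= 10 columns (strand columns 9-10 are required ",
         "for orientation-aware analyses); got ", ncol(df))
  }
  for (j in c(2, 3, 5, 6)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (any(is.na(v))) {
      stop("BEDPE: non-numeric coordinate in column ", j, " (rows ",
           paste(which(is.na(v)), collapse = ", "), ")")
    }
    df[[j]] <- v
  }
  bad1 <- df[[2]] > df[[3]]
  bad2 <- df[[5]] > df[[6]]
  if (any(bad1 | bad2)) {
    stop("BEDPE: interval with start > end (rows ",
         paste(which(bad1 | bad2), collapse = ", "), ")")
  }
  if (!all(df[[9]] %in% c("+", "-")) || !all(df[[10]] %in% c("+", "-"))) {
    stop("BEDPE: strand columns 9-10 must be '+' or '-'")
  }
  out <- data.frame(
    sample_id = if (ncol(df) >= 11) as.character(df[[11]]) else as.character(df[[7]]),
    chrom1 = as.character(df[[1]]), pos1 = df[[2]], orient1 = as.character(df[[9]]),
    chrom2 = as.character(df[[4]]), pos2 = df[[5]], orient2 = as.character(df[[10]]),
    stringsAsFactors = FALSE
  )
  if (ncol(df) >= 12) out$sv_class <- as.character(df[[12]])
  if (ncol(df) >= 11) out$ssv_id <- as.character(df[[7]])
  breakpoint_set(out)
}

#' Write a breakpoint set as 12-column BEDPE
#'
#' @param bps a [breakpoint_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ssv_bedpe <- function(bps, path) {
  out <- data.frame(
    bps$chrom1, format_pos(bps$pos1), format_pos(bps$pos1 + 1),
    bps$chrom2, format_pos(bps$pos2), format_pos(bps$pos2 + 1),
    bps$ssv_id, 0L, bps$orient1, bps$orient2, bps$sample_id, bps$sv_class,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_pos <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' @export
print.breakpoint_set <- function(x, ...) {
  cat(sprintf("breakpoint_set: %d SSV calls, %d samples\n",
              nrow(x), length(unique(x$sample_id))))
  tab <- table(x$sv_class)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

## ---- omics matrices -----------------------------------------------------

#' Construct an omics matrix with a declared kind and transform
#'
#' The (kind, transform) pairing is fixed: expression values are
#' log2(x + 1)-transformed, methylation beta values are logit-transformed
#' after clamping, and gene-level copy-number log2 ratios are used as is.
#' The transform is recorded here but applied inside the association engine,
#' not at load time.
#'
#' @param values numeric matrix (features x samples) with row/col names.
#' @param kind one of `"expression"`, `"methylation_beta"`, `"cna_log2"`.
#' @return the matrix with `kind`/`transform` attributes and class
#'   `omics_matrix`.
#' @export
omics_matrix <- function(values, kind = c("expression", "methylation_beta", "cna_log2")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("omics_matrix: values must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("omics_matrix: duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (kind == "methylation_beta") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad)) {
      cells <- apply(head(bad, 10), 1, function(ij)
        paste0(rownames(values)[ij[1]], "/", colnames(values)[ij[2]]))
      stop("methylation beta values outside [0,1] at: ",
           paste(cells, collapse = ", "),
           if (nrow(bad) > 10) sprintf(" (and %d more)", nrow(bad) - 10) else "")
    }
  }
  values <- unclass(values)
  attr(values, "kind") <- NULL
  attr(values, "transform") <- NULL
  structure(values, kind = kind, transform = kind_transform(kind),
            class = c("omics_matrix", class(values)))
}

#' @export
`[.omics_matrix` <- function(x, ...) {
  out <- NextMethod()
  if (is.matrix(out)) {
    structure(out, kind = attr(x, "kind"), transform = attr(x, "transform"),
              class = c("omics_matrix", class(out)))
  } else {
    out
  }
}

#' Read a features-x-samples TSV matrix
#'
#' First column holds feature ids, header row holds sample ids; empty cells
#' are missing values.
#'
#' @param path TSV path.
#' @inheritParams omics_matrix
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, kind) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  omics_matrix(m, kind)
}

#' Write an omics matrix as TSV
#' @param m matrix with feature rownames and sample colnames.
#' @param path output path.
#' @export
write_omics_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s, transform=%s]: %d features x %d samples (%.1f%% missing)\n",
              attr(x, "kind"), attr(x, "transform"), nrow(x), ncol(x),
              100 * mean(is.na(x))))
  invisible(x)
}

## ---- annotation tables --------------------------------------------------

#' Build a gene table with strand-aware transcription start sites
#'
#' Coordinates are 0-based half-open. The gene start (`tss`) used by all
#' breakpoint-distance computations is `start` for `+`-strand genes and
#' `end` for `-`-strand genes.
#'
#' @param df data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @return a `gene_table` data frame with a `tss` column.
#' @export
gene_table <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene_table: missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("gene_table: empty gene annotation")
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (anyDuplicated(df$gene_id)) {
    stop("gene_table: duplicate gene ids: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (any(df$start >= df$end)) {
    stop("gene_table: start >= end (rows ",
         paste(which(df$start >= df$end), collapse = ", "), ")")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("gene_table: strand must be '+' or '-'")
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df <- df[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Read a gene model file (tabular TSV or BED12)
#'
#' A file whose header contains a `gene_id` column is read as a TSV with
#' columns `gene_id, chrom, start, end, strand`; otherwise a 12-column
#' headerless file is read as BED12 (name column as gene id).
#'
#' @param path input path.
#' @return a [gene_table()].
#' @export
read_gene_table <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("gene_id", first)) {
    df <- read.delim(path, stringsAsFactors = FALSE)
  } else {
    bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(bed) < 6) stop("read_gene_table: BED gene model needs >= 6 columns")
    df <- data.frame(gene_id = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
                     start = as.numeric(bed[[2]]), end = as.numeric(bed[[3]]),
                     strand = as.character(bed[[6]]), stringsAsFactors = FALSE)
  }
  gene_table(df)
}

#' Write a gene table as TSV
#' @param genes a [gene_table()].
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a CpG-island probe table
#'
#' Each methylation array probe carries its CGI, its associated gene and a
#' region class (`promoter`, `gene_body`, `other`).
#'
#' @param df data frame with `probe_id`, `chrom`, `pos`, `cgi_id`,
#'   `gene_id`, `region_class`.
#' @return a `probe_table` data frame.
#' @export
probe_table <- function(df) {
  need <- c("probe_id", "chrom", "pos", "cgi_id", "gene_id", "region_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("probe_table: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) {
    stop("probe_table: duplicate probe ids: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  }
  if (!all(df$region_class %in% c("promoter", "gene_body", "other"))) {
    stop("probe_table: region_class must be promoter/gene_body/other")
  }
  df$pos <- as.numeric(df$pos)
  df <- df[, need]
  rownames(df) <- NULL
  class(df) <- c("probe_table", "data.frame")
  df
}

#' Read a probe annotation TSV
#' @param path input path.
#' @return a [probe_table()].
#' @export
read_probe_table <- function(path) {
  probe_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Read a BED interval file (0-based half-open)
#'
#' @param path input path.
#' @param extra_names names for columns beyond chrom/start/end, if any.
#' @return data frame with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path, extra_names = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(df$start >= df$end)) {
    stop("BED: interval with start >= end in ", path, " (rows ",
         paste(which(df$start >= df$end), collapse = ", "), ")")
  }
  if (!is.null(extra_names) && ncol(df) >= 3 + length(extra_names)) {
    names(df)[seq_along(extra_names) + 3] <- extra_names
  }
  df
}

write_bed <- function(df, path, extra_cols = character()) {
  cols <- c("chrom", "start", "end", extra_cols)
  out <- df[, cols]
  out$start <- format_pos(out$start)
  out$end <- format_pos(out$end)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `project`, `cancer_type`, `wgs_pass`
#' (`low`/`high` sequencing coverage class); optional numeric `purity`,
#' `ploidy`, `age`.
#'
#' @param path input path.
#' @return data frame of per-sample metadata.
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "project", "cancer_type", "wgs_pass")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample table: duplicate sample ids")
  if (!all(df$wgs_pass %in% c("low", "high"))) {
    stop("sample table: wgs_pass must be 'low' or 'high'")
  }
  df
}

## ---- annotation bundle --------------------------------------------------

#' Load and cross-reference the genome annotation bundle
#'
#' Assembles genes, CGI probes, TAD intervals, enhancer intervals and the
#' sample table into one cross-checked bundle. Probes whose associated gene
#' is absent from the gene annotation are dropped with a warning; TADs must
#' be non-overlapping within each chromosome; sex-chromosome genes and
#' probes are excluded by default from all downstream scans.
#'
#' @param genes gene table (path or data frame).
#' @param probes probe table (path or data frame), or NULL.
#' @param tads TAD BED (path or data frame), or NULL.
#' @param enhancers enhancer BED with a 4th `specificity` column (path or
#'   data frame), or NULL.
#' @param samples sample table (path or data frame), or NULL.
#' @param exclude_sex drop chrX/chrY genes and probes (default TRUE).
#' @return a `genome_annotation` list.
#' @export
load_annotation <- function(genes, probes = NULL, tads = NULL, enhancers = NULL,
                            samples = NULL, exclude_sex = TRUE) {
  genes <- if (is.character(genes)) read_gene_table(genes) else gene_table(as.data.frame(genes))
  if (!is.null(probes)) {
    probes <- if (is.character(probes)) read_probe_table(probes) else probe_table(as.data.frame(probes))
  }
  if (!is.null(tads)) {
    tads <- if (is.character(tads)) read_bed(tads) else as.data.frame(tads)
    validate_tads(tads)
  }
  if (!is.null(enhancers)) {
    enhancers <- if (is.character(enhancers)) {
      read_bed(enhancers, extra_names = "specificity")
    } else as.data.frame(enhancers)
    if (is.null(enhancers$specificity)) {
      stop("enhancer annotation needs a 'specificity' column (tissue/cell tag or 'ubiquitous')")
    }
  }
  if (!is.null(samples)) {
    samples <- if (is.character(samples)) read_sample_table(samples) else as.data.frame(samples)
  }
  if (exclude_sex) {
    n_sex <- sum(is_sex_chrom(genes$chrom))
    if (n_sex) svcis_log("excluding %d sex-chromosome genes", n_sex)
    genes <- genes[!is_sex_chrom(genes$chrom), ]
    if (!nrow(genes)) stop("no genes left after sex-chromosome exclusion")
    class(genes) <- c("gene_table", "data.frame")
    if (!is.null(probes)) probes <- probes[!is_sex_chrom(probes$chrom), ]
  }
  if (!is.null(probes)) {
    unknown <- !(probes$gene_id %in% genes$gene_id)
    if (any(unknown)) {
      warning(sum(unknown), " probe(s) reference unknown genes and were dropped")
      probes <- probes[!unknown, ]
    }
    class(probes) <- c("probe_table", "data.frame")
  }
  structure(list(genes = genes, probes = probes, tads = tads,
                 enhancers = enhancers, samples = samples,
                 exclude_sex = exclude_sex),
            class = "genome_annotation")
}

validate_tads <- function(tads) {
  if (any(tads$start >= tads$end)) stop("TADs: interval with start >= end")
  for (ch in unique(tads$chrom)) {
    t <- tads[tads$chrom == ch, ]
    t <- t[order(t$start), ]
    if (nrow(t) > 1 && any(t$start[-1] < t$end[-nrow(t)])) {
      stop("TADs overlap on ", ch, "; TAD intervals must be disjoint per chromosome")
    }
  }
  invisible(tads)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes", nrow(x$genes)))
  if (!is.null(x$probes)) cat(sprintf(", %d probes", nrow(x$probes)))
  if (!is.null(x$tads)) cat(sprintf(", %d TADs", nrow(x$tads)))
  if (!is.null(x$enhancers)) cat(sprintf(", %d enhancers", nrow(x$enhancers)))
  if (!is.null(x$samples)) cat(sprintf(", %d samples", nrow(x$samples)))
  cat("\n")
  invisible(x)
}
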
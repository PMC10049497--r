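# Tabular IO for the five artifact types: per-contrast DE summaries,
# contrast metadata, gene annotation, ortholog maps and count matrices.
# Canonical on-disk dialect: tab-delimited UTF-8 with a header row; "." or
# an empty field denotes missing.

.cell_fractions <- c("chromatin", "nucleus", "whole_cell", "other")
.sexes <- c("male", "female", "mixed", "unknown")
.model_classes <- c("loss_of_function", "gain_of_function")

#' The eight broad gene-function super-categories
#'
#' Gene biotypes (GENCODE-style) are condensed into eight broad classes for
#' composition summaries. The closed set used throughout the package.
#'
#' @return Character vector of the eight category names.
#' @export
gene_categories <- function() {
  c("protein_coding", "lncRNA", "pseudogene", "miRNA",
    "snRNA_snoRNA", "rRNA_tRNA", "ig_tr", "other")
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("", "."), stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

# Parse a character column to numeric; report 1-based data line numbers
# (header excluded) of unparseable values.
parse_numeric_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(sprintf("%s: non-numeric value in column '%s' at line %d ('%s')",
                 path, col, bad[1L] + 1L, x[bad[1L]]), call. = FALSE)
  out
}

strip_gene_version <- function(g) sub("\\.[0-9]+$", "", g)

#' Construct and validate a contrast table
#'
#' A contrast table holds one two-group comparison's per-gene differential
#' expression summary: log2 fold change (case over control), raw p-value and
#' Benjamini-Hochberg adjusted p-value (FDR).
#'
#' @param gene Character vector of unique gene identifiers.
#' @param log2fc Finite numeric log2 fold changes.
#' @param pvalue Numeric p-values in [0,1] (NA allowed).
#' @param fdr Numeric adjusted p-values in [0,1] (NA allowed).
#' @param contrast_id Single string naming the contrast.
#' @return A data.frame of class `contrast_table` with attribute
#'   `contrast_id`.
#' @export
contrast_table <- function(gene, log2fc, pvalue, fdr, contrast_id) {
  x <- data.frame(gene = as.character(gene), log2fc = as.numeric(log2fc),
                  pvalue = as.numeric(pvalue), fdr = as.numeric(fdr),
                  stringsAsFactors = FALSE)
  attr(x, "contrast_id") <- as.character(contrast_id)
  class(x) <- c("contrast_table", "data.frame")
  validate_contrast_table(x)
}

#' @rdname contrast_table
#' @param x Object to validate.
#' @export
validate_contrast_table <- function(x) {
  stopifnot(is.data.frame(x), all(c("gene", "log2fc", "pvalue", "fdr") %in% names(x)))
  if (anyNA(x$gene) || any(x$gene == ""))
    stop("contrast table contains missing gene ids", call. = FALSE)
  dup <- x$gene[duplicated(x$gene)]
  if (length(dup))
    stop(sprintf("duplicate gene id(s) in contrast table: %s",
                 paste(unique(dup)[seq_len(min(3, length(unique(dup))))],
                       collapse = ", ")), call. = FALSE)
  if (any(!is.finite(x$log2fc)))
    stop("non-finite log2fc values in contrast table", call. = FALSE)
  rng_bad <- function(v) any(!is.na(v) & (v < 0 | v > 1))
  if (rng_bad(x$fdr)) stop("fdr values outside [0,1]", call. = FALSE)
  if (rng_bad(x$pvalue)) stop("pvalue values outside [0,1]", call. = FALSE)
  x
}

#' Read a per-contrast differential-expression summary table
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param contrast_id Identifier to attach to the table.
#' @param columns Named character vector mapping the canonical names
#'   `gene`, `log2fc`, `pvalue`, `fdr` to the column names used in the file.
#' @param strip_versions If TRUE, trailing `.N` version suffixes are removed
#'   from gene ids (Ensembl-style versioned identifiers).
#' @return A [contrast_table()].
#' @seealso [read_column_config()] to load a `columns` mapping from YAML.
#' @export
read_contrast_table <- function(path, contrast_id,
                                columns = c(gene = "gene", log2fc = "log2fc",
                                            pvalue = "pvalue", fdr = "fdr"),
                                strip_versions = FALSE) {
  df <- read_tsv_raw(path)
  require_columns(df, unname(columns), path)
  gene <- df[[columns[["gene"]]]]
  if (isTRUE(strip_versions)) gene <- strip_gene_version(gene)
  contrast_table(
    gene = gene,
    log2fc = parse_numeric_col(df[[columns[["log2fc"]]]], columns[["log2fc"]], path),
    pvalue = parse_numeric_col(df[[columns[["pvalue"]]]], columns[["pvalue"]], path),
    fdr = parse_numeric_col(df[[columns[["fdr"]]]], columns[["fdr"]], path),
    contrast_id = contrast_id
  )
}

#' Write a contrast table as TSV
#'
#' Numeric values are written with full double precision so a write/read
#' round trip preserves at least 12 significant digits.
#'
#' @param x A [contrast_table()].
#' @param path Output path.
#' @export
write_contrast_table <- function(x, path) {
  validate_contrast_table(x)
  out <- data.frame(gene = x$gene,
                    log2fc = format(x$log2fc, digits = 17, trim = TRUE, scientific = NA),
                    pvalue = format(x$pvalue, digits = 17, trim = TRUE, scientific = NA),
                    fdr = format(x$fdr, digits = 17, trim = TRUE, scientific = NA))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a column-name mapping from a YAML config file
#'
#' The file holds key: value pairs mapping the canonical column names
#' (`gene`, `log2fc`, `pvalue`, `fdr`) to the names used in nonstandard
#' dumps.
#'
#' @param path Path to a YAML file.
#' @return Named character vector suitable for `read_contrast_table(columns=)`.
#' @export
read_column_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("package 'yaml' is required for read_column_config()", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- c(gene = "gene", log2fc = "log2fc", pvalue = "pvalue", fdr = "fdr")
  for (k in names(cfg)) defaults[[k]] <- as.character(cfg[[k]])
  defaults
}

normalize_enum <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[ -]+", "_", x)
}

#' Read a contrast metadata table
#'
#' Required columns: `contrast_id`, `study_id`, `tissue`, `cell_fraction`,
#' `sex`, `species`, `model_class`, `n_case`, `n_control`. Enum columns are
#' normalised case-insensitively ("Whole Cell" becomes `whole_cell`);
#' unrecognised cell fractions map to `other` with a warning. `model_class`
#' (loss_of_function / gain_of_function) must be present for every contrast
#' as it drives direction harmonisation.
#'
#' @param path Path to a tab-delimited file.
#' @return A data.frame, one row per contrast.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_raw(path)
  req <- c("contrast_id", "study_id", "tissue", "cell_fraction", "sex",
           "species", "model_class", "n_case", "n_control")
  require_columns(df, req, path)
  if (anyDuplicated(df$contrast_id))
    stop(sprintf("%s: duplicate contrast_id: %s", path,
                 df$contrast_id[duplicated(df$contrast_id)][1L]), call. = FALSE)
  cf <- normalize_enum(df$cell_fraction)
  unknown <- !(cf %in% .cell_fractions) & !is.na(cf)
  if (any(unknown)) {
    warning(sprintf("unrecognised cell_fraction value(s) mapped to 'other': %s",
                    paste(unique(df$cell_fraction[unknown]), collapse = ", ")),
            call. = FALSE)
    cf[unknown] <- "other"
  }
  cf[is.na(cf)] <- "other"
  sex <- normalize_enum(df$sex)
  sex[!(sex %in% .sexes) | is.na(sex)] <- "unknown"
  mc <- normalize_enum(df$model_class)
  if (anyNA(mc) || any(!(mc %in% .model_classes)))
    stop(sprintf("%s: model_class must be one of %s for every contrast", path,
                 paste(.model_classes, collapse = "/")), call. = FALSE)
  n_case <- parse_numeric_col(df$n_case, "n_case", path)
  n_control <- parse_numeric_col(df$n_control, "n_control", path)
  if (any(is.na(n_case)) || any(is.na(n_control)) ||
      any(n_case < 1) || any(n_control < 1))
    stop(sprintf("%s: n_case/n_control must be positive", path), call. = FALSE)
  data.frame(contrast_id = df$contrast_id, study_id = df$study_id,
             tissue = normalize_enum(df$tissue), cell_fraction = cf, sex = sex,
             species = normalize_enum(df$species), model_class = mc,
             n_case = as.integer(n_case), n_control = as.integer(n_control),
             stringsAsFactors = FALSE)
}

#' Read a gene annotation table
#'
#' Required columns: `gene`, `biotype`, `category`, `chromosome`, `tss`.
#' `category` must be one of the eight classes in [gene_categories()]
#' (case-insensitive); `tss` is a 1-based transcription start site.
#'
#' @param path Path to a tab-delimited file.
#' @return A data.frame, one row per gene.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_raw(path)
  req <- c("gene", "biotype", "category", "chromosome", "tss")
  require_columns(df, req, path)
  if (anyDuplicated(df$gene))
    stop(sprintf("%s: duplicate gene id: %s", path,
                 df$gene[duplicated(df$gene)][1L]), call. = FALSE)
  cat <- normalize_enum(df$category)
  # gene_categories() contains mixed-case names; compare case-insensitively
  canon <- gene_categories()
  idx <- match(cat, tolower(canon))
  if (anyNA(idx))
    stop(sprintf("%s: category not in the closed 8-class set: %s", path,
                 df$category[which(is.na(idx))[1L]]), call. = FALSE)
  tss <- parse_numeric_col(df$tss, "tss", path)
  if (any(is.na(tss)) || any(tss < 1))
    stop(sprintf("%s: tss must be a positive 1-based coordinate", path), call. = FALSE)
  data.frame(gene = df$gene, biotype = df$biotype, category = canon[idx],
             chromosome = as.character(df$chromosome), tss = as.integer(tss),
             stringsAsFactors = FALSE)
}

#' Read an ortholog mapping table
#'
#' Required columns: `source_gene`, `target_gene`, `score`. Typically a
#' pre-fetched DIOPT-style export; reduce with [best_match_reduce()] before
#' use in [translate_contrast()].
#'
#' @param path Path to a tab-delimited file.
#' @return A data.frame with the three columns.
#' @export
read_ortholog_map <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("source_gene", "target_gene", "score"), path)
  score <- parse_numeric_col(df$score, "score", path)
  if (anyNA(score)) stop(sprintf("%s: score must be present for all rows", path),
                         call. = FALSE)
  data.frame(source_gene = df$source_gene, target_gene = df$target_gene,
             score = score, stringsAsFactors = FALSE)
}

#' Construct and validate a two-group count matrix
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns (colnames are sample ids).
#' @param group Character vector over samples with values `case`/`control`;
#'   both groups must be non-empty.
#' @return A list of class `count_matrix` with elements `counts` and `group`.
#' @export
count_matrix <- function(counts, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene rownames", call. = FALSE)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "double"  # keeps >2^31 safe; values remain integral
  group <- as.character(group)
  if (length(group) != ncol(counts))
    stop("length(group) must equal ncol(counts)", call. = FALSE)
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  if (!all(c("case", "control") %in% group))
    stop("both groups must be non-empty", call. = FALSE)
  structure(list(counts = counts, group = group), class = "count_matrix")
}

#' Read a count matrix (and group labels) from TSV
#'
#' The counts file has a `gene` first column then one column per sample;
#' the groups file has columns `sample` and `group`.
#'
#' @param counts_path Path to the counts TSV.
#' @param groups_path Path to the sample-group TSV (or NULL if `group` given).
#' @param group Optional character vector of group labels in column order.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, groups_path = NULL, group = NULL) {
  df <- read_tsv_raw(counts_path)
  require_columns(df, "gene", counts_path)
  genes <- df$gene
  m <- as.matrix(df[setdiff(names(df), "gene")])
  m <- apply(m, 2, function(col) parse_numeric_col(col, "counts", counts_path))
  rownames(m) <- genes
  if (is.null(group)) {
    if (is.null(groups_path)) stop("provide groups_path or group", call. = FALSE)
    g <- read_tsv_raw(groups_path)
    require_columns(g, c("sample", "group"), groups_path)
    group <- g$group[match(colnames(m), g$sample)]
    if (anyNA(group))
      stop(sprintf("%s: missing group label for sample(s): %s", groups_path,
                   paste(colnames(m)[is.na(group)], collapse = ", ")), call. = FALSE)
  }
  count_matrix(m, normalize_enum(group))
}

#' Read a count matrix from MatrixMarket (MTX) files
#'
#' @param mtx_path Path to the MTX file (genes x samples).
#' @param genes_path,samples_path Paths to one-id-per-line text files.
#' @param group Character vector of group labels in sample order.
#' @return A [count_matrix()].
#' @export
read_count_matrix_mtx <- function(mtx_path, genes_path, samples_path, group) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("package 'Matrix' is required for MTX input", call. = FALSE)
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(genes_path)
  colnames(m) <- readLines(samples_path)
  count_matrix(m, group)
}

#' Write a count matrix (counts + group labels) as TSV
#'
#' @param x A [count_matrix()].
#' @param counts_path,groups_path Output paths.
#' @export
write_count_matrix <- function(x, counts_path, groups_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(x$counts), group = x$group),
                     groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Reduce an ortholog map to best matches
#'
#' Keeps, per source gene, exactly the highest-scoring row; score ties are
#' broken by lexicographically smallest target gene. Idempotent.
#'
#' @param map Data.frame with columns `source_gene`, `target_gene`, `score`.
#' @return The reduced map (each source gene appears once).
#' @export
best_match_reduce <- function(map) {
  stopifnot(all(c("source_gene", "target_gene", "score") %in% names(map)))
  if (nrow(map) == 0L) return(map)
  if (anyNA(map$score)) stop("score must be present for all rows", call. = FALSE)
  o <- order(map$source_gene, -map$score, map$target_gene, method = "radix")
  m <- map[o, , drop = FALSE]
  m <- m[!duplicated(m$source_gene), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Translate a contrast table into ortholog target gene space
#'
#' Genes without a mapping are dropped. When two source genes map to the
#' same target, the row with the smaller FDR wins (ties: smaller source
#' gene id). The map must already be best-match reduced.
#'
#' @param t A [contrast_table()].
#' @param map A best-match-reduced ortholog map.
#' @return A [contrast_table()] with target-space gene ids.
#' @export
translate_contrast <- function(t, map) {
  validate_contrast_table(t)
  if (anyDuplicated(map$source_gene))
    stop("map must be best-match reduced (duplicate source_gene)", call. = FALSE)
  idx <- match(t$gene, map$source_gene)
  keep <- !is.na(idx)
  tt <- t[keep, , drop = FALSE]
  target <- map$target_gene[idx[keep]]
  if (nrow(tt) == 0L)
    return(contrast_table(character(), numeric(), numeric(), numeric(),
                          attr(t, "contrast_id") %||% "translated"))
  o <- order(target, tt$fdr, tt$gene, method = "radix")
  tt <- tt[o, , drop = FALSE]
  target <- target[o]
  first <- !duplicated(target)
  contrast_table(gene = target[first], log2fc = tt$log2fc[first],
                 pvalue = tt$pvalue[first], fdr = tt$fdr[first],
                 contrast_id = attr(t, "contrast_id") %||% "translated")
}
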
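# Consensus common-core identification across many DE contrasts.
#
# Pipeline: mask fold changes at an FDR threshold, sign-harmonise
# gain-of-function contrasts, drop contrasts left with no significant
# genes, then keep genes supported (non-zero masked fold change) in at
# least k contrasts and split them into up/down cores by mean significant
# fold change.

# Resolve the support threshold k. When given as a fraction of contrasts
# we round half *down* (so 10% of 43 contrasts gives k = 4, the operating
# point large compendia actually use), with a floor of 1.
resolve_k <- function(min_contrasts = NULL, min_fraction = NULL, n_contrasts) {
  if (is.null(min_contrasts) == is.null(min_fraction))
    stop("specify exactly one of min_contrasts / min_fraction", call. = FALSE)
  if (!is.null(min_contrasts)) {
    k <- as.integer(min_contrasts)
    if (k < 1L) stop("min_contrasts must be >= 1", call. = FALSE)
    return(k)
  }
  stopifnot_scalar_prob(min_fraction, "min_fraction", open_lower = TRUE,
                        open_upper = FALSE)
  max(1L, as.integer(floor(min_fraction * n_contrasts + 0.5 - 1e-9)))
}

#' Build a significance-masked fold-change matrix
#'
#' Entry (g, c) is the contrast's log2 fold change when its FDR is at most
#' `alpha`, else 0. The gene universe is the union over contrasts (sorted
#' for order invariance); a gene absent from a contrast's table is treated
#' as non-significant there (entry 0).
#'
#' @param tables List of [contrast_table()] objects.
#' @param alpha FDR significance threshold (default 0.01).
#' @return Numeric matrix, genes x contrasts, with dimnames.
#' @export
build_fc_matrix <- function(tables, alpha = 0.01) {
  stopifnot(length(tables) >= 1L)
  stopifnot_scalar_prob(alpha, "alpha")
  ids <- vapply(seq_along(tables), function(i)
    attr(tables[[i]], "contrast_id") %||% paste0("contrast_", i), character(1))
  if (anyDuplicated(ids)) stop("duplicate contrast ids", call. = FALSE)
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  m <- matrix(0, nrow = length(genes), ncol = length(tables),
              dimnames = list(genes, ids))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    sig <- !is.na(t$fdr) & t$fdr <= alpha
    if (any(sig)) m[match(t$gene[sig], genes), i] <- t$log2fc[sig]
  }
  m
}

#' Remove contrasts with no significant genes
#'
#' Columns whose masked fold changes are all zero are dropped; column
#' order is preserved.
#'
#' @param m Matrix from [build_fc_matrix()].
#' @return Matrix without all-zero columns.
#' @export
drop_empty_contrasts <- function(m) {
  keep <- colSums(m != 0) > 0
  if (!any(keep)) stop("all contrasts are empty after masking", call. = FALSE)
  m[, keep, drop = FALSE]
}

#' Sign-harmonise gain-of-function contrasts
#'
#' Negates the fold changes of the listed contrasts so that
#' gain-of-function (overexpression / duplication) models point the same
#' way as loss-of-function models. Applying it twice is the identity.
#'
#' @param m Matrix from [build_fc_matrix()].
#' @param invert_ids Character vector of contrast ids to negate.
#' @return The matrix with listed columns negated.
#' @export
invert_gain_of_function <- function(m, invert_ids) {
  invert_ids <- as.character(invert_ids)
  if (length(invert_ids) == 0L) return(m)
  missing <- setdiff(invert_ids, colnames(m))
  if (length(missing))
    stop(sprintf("unknown contrast id(s) in invert_ids: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  m[, invert_ids] <- -m[, invert_ids, drop = FALSE]
  m
}

#' Identify the consensus core from a finalized fold-change matrix
#'
#' A gene's support is its number of contrasts with non-zero masked fold
#' change; genes with support >= k form the core. Mean fold change is taken
#' over supporting (significant) contrasts only, and splits the core into
#' `up` (mean > 0; an exact 0 mean ties to `up` and is messaged) and
#' `down`.
#'
#' @param m Matrix from [build_fc_matrix()], inversions applied and empty
#'   contrasts dropped.
#' @param min_contrasts Integer support threshold k (use exactly one of
#'   this and `min_fraction`).
#' @param min_fraction Support threshold as a fraction of contrasts;
#'   converted to k by rounding half down with a floor of 1.
#' @param alpha The masking threshold used to build `m` (recorded only).
#' @return An object of class `core_result`; see [consensus_core()].
#' @export
identify_core <- function(m, min_contrasts = NULL, min_fraction = NULL,
                          alpha = NA_real_) {
  k <- resolve_k(min_contrasts, min_fraction, ncol(m))
  support <- rowSums(m != 0)
  mean_lfc <- ifelse(support > 0, rowSums(m) / support, NA_real_)
  names(mean_lfc) <- names(support) <- rownames(m)
  core <- rownames(m)[support >= k]
  dir_vals <- mean_lfc[core]
  if (any(dir_vals == 0, na.rm = TRUE))
    message(sprintf("%d core gene(s) with mean fold change exactly 0 assigned 'up'",
                    sum(dir_vals == 0)))
  direction <- ifelse(dir_vals >= 0, "up", "down")
  names(direction) <- core
  structure(list(core_genes = core, support = support, mean_lfc = mean_lfc,
                 direction = direction, k = k, n_contrasts = ncol(m),
                 alpha = alpha, fc_matrix = NULL),
            class = "core_result")
}

#' Consensus core identification across differential-expression contrasts
#'
#' The package's central fitting function. Runs the full pipeline on a list
#' of per-contrast DE tables: FDR-mask fold changes at `alpha`, negate the
#' gain-of-function contrasts in `invert_ids`, drop contrasts left with no
#' significant genes, and call the consensus core at the support threshold.
#'
#' @inheritParams build_fc_matrix
#' @inheritParams identify_core
#' @param invert_ids Contrast ids whose fold-change direction is inverted
#'   (gain-of-function models).
#' @param keep_matrix If TRUE (default) the masked fold-change matrix is
#'   stored on the result (needed by [build_track()] plotting and
#'   [concordance_profile()]).
#' @return An object of class `core_result` with elements `core_genes`,
#'   `support` (per gene), `mean_lfc` (over significant contrasts),
#'   `direction` (`up`/`down` per core gene), `k`, `n_contrasts`, `alpha`
#'   and (optionally) `fc_matrix`.
#' @examples
#' tabs <- generate_multi_contrast(n_genes = 300, n_contrasts = 10,
#'                                 n_core_up = 15, n_core_down = 10, seed = 1)
#' fit <- consensus_core(tabs$tables, alpha = 0.01, min_contrasts = 4,
#'                       invert_ids = tabs$truth$inverted_contrasts)
#' fit
#' @export
consensus_core <- function(tables, alpha = 0.01, min_contrasts = NULL,
                           min_fraction = NULL, invert_ids = character(),
                           keep_matrix = TRUE) {
  if (is.null(min_contrasts) && is.null(min_fraction)) min_contrasts <- 4L
  m <- build_fc_matrix(tables, alpha)
  m <- invert_gain_of_function(m, invert_ids)
  m <- drop_empty_contrasts(m)
  res <- identify_core(m, min_contrasts, min_fraction, alpha = alpha)
  if (keep_matrix) res$fc_matrix <- m
  res$invert_ids <- as.character(invert_ids)
  res
}

#' Per-gene direction concordance profile
#'
#' For each gene with support >= 1, the fraction of its non-zero masked
#' fold changes that are positive; 0 or 1 indicates complete directional
#' consistency. Genes with no significant appearance get NA.
#'
#' @param m Matrix from [build_fc_matrix()].
#' @return Named numeric vector in [0,1] (NA where support is 0).
#' @export
concordance_profile <- function(m) {
  support <- rowSums(m != 0)
  out <- ifelse(support > 0, rowSums(m > 0) / support, NA_real_)
  names(out) <- rownames(m)
  out
}

#' Core sizes over a grid of FDR and support thresholds
#'
#' Runs the full pipeline at every (alpha, k) combination and tabulates
#' core / up / down counts, the threshold-sensitivity summary used to pick
#' an operating point.
#'
#' @inheritParams consensus_core
#' @param alphas Numeric vector of FDR thresholds in (0,1).
#' @param ks Integer vector of support thresholds (>= 1).
#' @return data.frame with columns alpha, k, n_core, n_up, n_down.
#' @export
grid_core_counts <- function(tables, alphas, ks, invert_ids = character()) {
  stopifnot(all(alphas > 0 & alphas < 1), all(ks >= 1))
  out <- expand.grid(alpha = alphas, k = as.integer(ks),
                     KEEP.OUT.ATTRS = FALSE)
  out$n_core <- out$n_up <- out$n_down <- 0L
  for (a in alphas) {
    m <- build_fc_matrix(tables, a)
    m <- invert_gain_of_function(m, invert_ids)
    if (!any(colSums(m != 0) > 0)) next  # no usable contrasts at this alpha
    m <- drop_empty_contrasts(m)
    for (k in ks) {
      res <- identify_core(m, min_contrasts = k, alpha = a)
      i <- out$alpha == a & out$k == k
      out$n_core[i] <- length(res$core_genes)
      out$n_up[i] <- sum(res$direction == "up")
      out$n_down[i] <- sum(res$direction == "down")
    }
  }
  out[c("alpha", "k", "n_core", "n_up", "n_down")]
}

#' Consensus core within a metadata-defined subgroup of contrasts
#'
#' Restricts the pipeline to contrasts whose metadata `feature` equals
#' `value` (e.g. cell_fraction = nucleus, tissue = cortex) with the support
#' threshold re-derived from `min_fraction` of the selected contrasts.
#'
#' @inheritParams consensus_core
#' @param metadata Data.frame from [read_metadata()].
#' @param feature Metadata column to select on.
#' @param value Value the column must equal.
#' @return A `core_result` restricted to the subgroup; the selected
#'   contrast ids are stored as `$contrast_ids`.
#' @export
subgroup_core <- function(tables, metadata, feature, value, alpha = 0.01,
                          min_fraction = 0.10, invert_ids = character()) {
  if (!feature %in% names(metadata))
    stop(sprintf("unknown metadata feature: %s", feature), call. = FALSE)
  sel_ids <- metadata$contrast_id[metadata[[feature]] == value]
  ids <- vapply(seq_along(tables), function(i)
    attr(tables[[i]], "contrast_id") %||% paste0("contrast_", i), character(1))
  keep <- ids %in% sel_ids
  if (!any(keep))
    stop(sprintf("no contrasts match %s = %s", feature, value), call. = FALSE)
  res <- consensus_core(tables[keep], alpha = alpha, min_fraction = min_fraction,
                        invert_ids = intersect(invert_ids, ids[keep]),
                        keep_matrix = FALSE)
  res$contrast_ids <- ids[keep]
  res$selector <- c(feature = feature, value = value)
  res
}

#' @export
print.core_result <- function(x, ...) {
  cat("Consensus core DEG result\n")
  cat(sprintf("  contrasts: %d   FDR threshold: %s   support threshold k: %d\n",
              x$n_contrasts, format(x$alpha), x$k))
  cat(sprintf("  core genes: %d  (up %d / down %d)\n", length(x$core_genes),
              sum(x$direction == "up"), sum(x$direction == "down")))
  if (length(x$invert_ids %||% character()))
    cat(sprintf("  inverted (gain-of-function) contrasts: %s\n",
                paste(x$invert_ids, collapse = ", ")))
  invisible(x)
}

#' @export
summary.core_result <- function(object, ...) {
  sup <- object$support[object$core_genes]
  cat("Consensus core DEG result\n")
  print(object)
  if (length(sup)) {
    cat("  support over core genes:\n")
    print(summary(as.numeric(sup)))
    cat("  mean |log2FC| over core genes:",
        format(mean(abs(object$mean_lfc[object$core_genes])), digits = 4), "\n")
  }
  invisible(object)
}

#' @export
plot.core_result <- function(x, ...) {
  sup <- x$support[x$support > 0]
  graphics::hist(sup, breaks = seq(0.5, max(sup) + 0.5, by = 1),
                 main = "Support distribution (genes significant >= 1 contrast)",
                 xlab = "number of supporting contrasts", ...)
  graphics::abline(v = x$k - 0.5, lty = 2)
  invisible(x)
}

#' Export a core result as a data.frame
#'
#' @param x A `core_result`.
#' @param row.names,optional Ignored (S3 signature compatibility).
#' @param core_only If TRUE (default) only core genes are returned.
#' @param ... Unused.
#' @return data.frame with gene, support, mean_lfc and direction columns.
#' @export
as.data.frame.core_result <- function(x, row.names = NULL, optional = FALSE,
                                      core_only = TRUE, ...) {
  genes <- if (core_only) x$core_genes else names(x$support)
  data.frame(gene = genes, support = as.integer(x$support[genes]),
             mean_lfc = x$mean_lfc[genes],
             direction = ifelse(genes %in% x$core_genes,
                                x$direction[genes], NA_character_),
             row.names = NULL, stringsAsFactors = FALSE)
}
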
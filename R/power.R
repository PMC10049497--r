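# Replicate down-sampling power analysis: repeated subsampling of a large
# two-group count matrix, DEG counting under fold-change cutoffs, and
# Rand-index stability of the DEG calls against the full-data reference.

#' Rand index between two binary membership vectors
#'
#' Fraction of pairs of elements whose co-membership agrees between the
#' two partitions (both together or both apart in both vectors).
#' Symmetric and invariant to complementing both vectors.
#'
#' @param a,b Logical (or 0/1) vectors of equal length >= 2.
#' @return Value in [0,1]; 1 means identical partitions.
#' @examples
#' rand_index(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 2/6
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 elements", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  if (anyNA(a) || anyNA(b)) stop("NA in membership vectors", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  s <- sum(comb2(tab))
  ra <- sum(comb2(rowSums(tab)))
  cb <- sum(comb2(colSums(tab)))
  tot <- comb2(n)
  (tot + 2 * s - ra - cb) / tot
}

#' Percentage of DEGs surviving fold-change cutoffs
#'
#' For a DE result, the percentage of its DEGs (FDR <= threshold) whose
#' |log2FC| is at least each cutoff in `grid`; non-increasing in the
#' cutoff. The attribute `cross50` reports the first grid cutoff at which
#' fewer than 50% of DEGs remain (NA if never reached).
#'
#' @param de An `nb_de` result (or any data.frame with log2fc and fdr).
#' @param fdr_threshold DEG threshold (default 0.01).
#' @param grid Increasing numeric vector of |log2FC| cutoffs.
#' @return data.frame with columns cutoff, pct_remaining.
#' @export
fc_survival_curve <- function(de, fdr_threshold = 0.01,
                              grid = seq(0, 2, by = 0.05)) {
  deg <- !is.na(de$fdr) & de$fdr <= fdr_threshold
  if (!any(deg)) stop("no DEGs at the given threshold", call. = FALSE)
  alfc <- abs(de$log2fc[deg])
  pct <- vapply(grid, function(cut) 100 * mean(alfc >= cut), numeric(1))
  out <- data.frame(cutoff = grid, pct_remaining = pct)
  below <- which(pct < 50)
  attr(out, "cross50") <- if (length(below)) grid[below[1L]] else NA_real_
  out
}

#' Replicate down-sampling experiment
#'
#' For each per-group sample size and each replicate drawing, samples are
#' drawn without replacement from each group (independent seeded
#' sub-streams per (n, rep), so adding replicates never perturbs earlier
#' ones), size factors are recomputed within the drawing, the NB Wald test
#' is run, and DEG counts at the FDR threshold are recorded for each
#' fold-change cutoff together with the Rand index between the drawing's
#' DEG indicator (over all genes) and the full-data reference (any fold
#' change, same FDR threshold).
#'
#' @param c A [count_matrix()]; both groups must have at least
#'   `max(sample_sizes)` samples.
#' @param sample_sizes Integer vector of per-group sizes (e.g. 10:3).
#' @param n_reps Drawings per size (default 100).
#' @param fdr_threshold DEG threshold (default 0.01).
#' @param fc_cutoffs Fold-change ratio cutoffs; 1 means any fold change,
#'   1.1 means |log2FC| >= log2(1.1), etc. (default c(1, 1.1, 1.2)).
#' @param seed Master RNG seed (required).
#' @param min_count,min_fraction Passed to [nb_wald_test()].
#' @return data.frame of class `power_curve`: n_per_group, rep, one
#'   `deg_fc<cutoff>` count column per cutoff, and rand_index. The
#'   full-data reference result is attached as attribute `reference`.
#' @export
downsampling_experiment <- function(c, sample_sizes, n_reps = 100,
                                    fdr_threshold = 0.01,
                                    fc_cutoffs = c(1, 1.1, 1.2), seed,
                                    min_count = 10, min_fraction = 0.5) {
  stopifnot(inherits(c, "count_matrix"))
  sample_sizes <- as.integer(sample_sizes)
  if (min(sample_sizes) < 2) stop("sample sizes must be >= 2", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (any(fc_cutoffs < 1)) stop("fc_cutoffs are ratios >= 1", call. = FALSE)
  case_idx <- which(c$group == "case"); ctrl_idx <- which(c$group == "control")
  if (max(sample_sizes) > min(length(case_idx), length(ctrl_idx)))
    stop("a requested size exceeds a group's sample count", call. = FALSE)
  lfc_cuts <- log2(fc_cutoffs)
  cut_names <- paste0("deg_fc", format(fc_cutoffs, trim = TRUE))
  deg_calls <- function(de) {
    deg <- !is.na(de$fdr) & de$fdr <= fdr_threshold
    counts <- vapply(lfc_cuts, function(cut)
      sum(deg & abs(de$log2fc) >= cut, na.rm = TRUE), numeric(1))
    list(any = deg, counts = counts)
  }
  full <- nb_wald_test(c, min_count, min_fraction)
  ref <- deg_calls(full)$any
  rows <- vector("list", length(sample_sizes) * n_reps)
  r <- 0L
  for (n in sample_sizes) {
    for (rep in seq_len(n_reps)) {
      sub <- with_seed(substream_seed(seed, n, rep), {
        ci <- sample(case_idx, n); oi <- sample(ctrl_idx, n)
        c(ci, oi)
      })
      cm <- count_matrix(c$counts[, sub, drop = FALSE], c$group[sub])
      de <- nb_wald_test(cm, min_count, min_fraction)
      calls <- deg_calls(de)
      r <- r + 1L
      row <- as.list(c(n_per_group = n, rep = rep, calls$counts,
                       rand_index = rand_index(calls$any, ref)))
      names(row) <- c("n_per_group", "rep", cut_names, "rand_index")
      rows[[r]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  attr(out, "reference") <- full
  attr(out, "fc_cutoffs") <- fc_cutoffs
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Per-size summary of a power curve
#'
#' Box-plot statistics (minimum, first quartile, median, third quartile,
#' maximum) of the DEG counts per sample size, for each fold-change
#' cutoff, plus the mean Rand index.
#'
#' @param object A `power_curve`.
#' @param ... Unused.
#' @return data.frame with one row per (n_per_group, cutoff).
#' @export
summary.power_curve <- function(object, ...) {
  cut_cols <- grep("^deg_fc", names(object), value = TRUE)
  out <- list()
  for (n in sort(unique(object$n_per_group), decreasing = TRUE)) {
    sel <- object$n_per_group == n
    for (cc in cut_cols) {
      q <- stats::quantile(object[[cc]][sel], c(0, 0.25, 0.5, 0.75, 1))
      out[[length(out) + 1L]] <- data.frame(
        n_per_group = n, cutoff = sub("^deg_fc", "", cc),
        min = q[[1]], q1 = q[[2]], median = q[[3]], q3 = q[[4]], max = q[[5]],
        mean_rand_index = mean(object$rand_index[sel]))
    }
  }
  do.call(rbind, out)
}

#' @export
plot.power_curve <- function(x, ...) {
  cut_cols <- grep("^deg_fc", names(x), value = TRUE)
  graphics::boxplot(x[[cut_cols[1]]] ~ x$n_per_group,
                    xlab = "samples per group",
                    ylab = sprintf("DEGs at FDR<=%s (%s)",
                                   format(attr(x, "fdr_threshold")),
                                   cut_cols[1]), ...)
  invisible(x)
}
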
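# Desk-scale two-group negative-binomial differential expression:
# median-of-ratios normalisation, moment dispersion with trend shrinkage,
# Wald test on the log2 group-mean ratio, BH adjustment over tested genes.

#' Loose expression filter
#'
#' A gene passes when at least `ceiling(min_fraction * n_samples)` samples
#' have a raw count of at least `min_count` (defaults 10 and 0.5: 10 counts
#' in at least half the samples).
#'
#' @param c A [count_matrix()].
#' @param min_count Per-sample count required (default 10).
#' @param min_fraction Fraction of samples that must reach it (default 0.5).
#' @return Named logical vector over genes.
#' @export
expression_filter <- function(c, min_count = 10, min_fraction = 0.5) {
  stopifnot(inherits(c, "count_matrix"), min_count >= 0)
  need <- ceiling(min_fraction * ncol(c$counts))
  rowSums(c$counts >= min_count) >= need
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalisation: each sample's factor is the median over
#' reference genes of its counts divided by the gene's geometric mean
#' across samples. Reference genes are those with non-zero counts in all
#' samples; if none exist, the geometric mean is taken over positive
#' counts only (messaged). Factors are rescaled so their geometric mean
#' is exactly 1.
#'
#' @param c A [count_matrix()].
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(c) {
  stopifnot(inherits(c, "count_matrix"))
  k <- c$counts
  if (ncol(k) == 1L) return(stats::setNames(1, colnames(k)))
  allpos <- rowSums(k > 0) == ncol(k)
  if (any(allpos)) {
    lk <- log(k[allpos, , drop = FALSE])
    lgm <- rowMeans(lk)
    sf <- apply(lk - lgm, 2, stats::median)
  } else {
    anypos <- rowSums(k > 0) > 0
    if (!any(anypos)) stop("no usable genes for size factors", call. = FALSE)
    message("no gene has positive counts in every sample; ",
            "using positive counts only for the geometric means")
    lk <- log(k[anypos, , drop = FALSE])
    lgm <- apply(lk, 1, function(r) mean(r[is.finite(r)]))
    sf <- apply(lk - lgm, 2, function(col) stats::median(col[is.finite(col)]))
  }
  sf <- sf - mean(sf)              # geometric mean of factors = 1
  stats::setNames(exp(sf), colnames(k))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values with monotone enforcement, clipped at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector in [0,1] (NA passed through).
#' @return Adjusted p-values, same length.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0,1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-group negative-binomial Wald test
#'
#' A deliberately simple NB caller for desk-scale work: counts are
#' normalised with [size_factors()]; per-gene dispersion is the moment
#' estimate (pooled within-group variance minus mean)/mean^2, floored at
#' 1e-8 and shrunk halfway toward a fitted a0 + a1/mean trend; the log2
#' ratio of (prior-count-damped) group means is tested with a Wald z under
#' the NB variance; BH adjustment runs over filter-passing genes only.
#' Identical case/control columns give log2 fold changes of exactly 0.
#'
#' @param c A [count_matrix()]; both groups need >= 2 samples.
#' @param min_count,min_fraction Passed to [expression_filter()].
#' @param prior_count Damping constant added to both group means before the
#'   ratio (default 0.5 on the normalised scale).
#' @param shrink_weight Weight on the per-gene moment dispersion in the
#'   shrinkage average (default 0.4; the rest goes to the trend).
#' @return Object of class `nb_de`: a data.frame over all genes with
#'   columns gene, base_mean, log2fc, lfc_se, stat, pvalue, fdr,
#'   dispersion, filter_pass (statistics NA for genes failing the filter),
#'   plus attributes `size_factors` and `groups`.
#' @export
nb_wald_test <- function(c, min_count = 10, min_fraction = 0.5,
                         prior_count = 0.5, shrink_weight = 0.4) {
  stopifnot(inherits(c, "count_matrix"))
  case <- c$group == "case"; ctrl <- !case
  n1 <- sum(case); n0 <- sum(ctrl)
  if (n1 < 2 || n0 < 2) stop("both groups need at least 2 samples", call. = FALSE)
  if (any(colSums(c$counts[, case, drop = FALSE]) == 0) ||
      any(colSums(c$counts[, ctrl, drop = FALSE]) == 0))
    stop("a sample has an all-zero library", call. = FALSE)
  sf <- size_factors(c)
  pass <- expression_filter(c, min_count, min_fraction)
  q <- sweep(c$counts, 2, sf, "/")
  mu1 <- rowMeans(q[, case, drop = FALSE])
  mu0 <- rowMeans(q[, ctrl, drop = FALSE])
  base_mean <- rowMeans(q)
  v1 <- apply(q[, case, drop = FALSE], 1, stats::var)
  v0 <- apply(q[, ctrl, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  minv <- mean(1 / sf)
  mu_bar <- (n1 * mu1 + n0 * mu0) / (n1 + n0)
  disp_raw <- pmax((sp2 - mu_bar * minv) / mu_bar^2, 1e-8)
  disp_raw[!is.finite(disp_raw)] <- 1e-8
  # a0 + a1/mu trend fitted on filter-passing genes, robustly via medians
  # of the raw estimates in mean bins; degenerate fits fall back to the
  # overall median.
  disp <- disp_raw
  fit_genes <- pass & mu_bar > 0
  if (sum(fit_genes) >= 50) {
    x <- 1 / mu_bar[fit_genes]; y <- disp_raw[fit_genes]
    co <- tryCatch(stats::coef(stats::lm(y ~ x)), error = function(e) c(NA, NA))
    a0 <- co[1]; a1 <- co[2]
    if (!is.finite(a0) || a0 < 1e-8) a0 <- max(stats::median(y), 1e-8)
    if (!is.finite(a1) || a1 < 0) a1 <- 0
    trend <- pmax(a0 + a1 / mu_bar, 1e-8)
    disp <- pmax(shrink_weight * disp_raw + (1 - shrink_weight) * trend, 1e-8)
  }
  m1 <- mu1 + prior_count
  m0 <- mu0 + prior_count
  log2fc <- log2(m1 / m0)
  # Var of a normalised group mean under NB: (1/n^2) sum_j (mu/s_j + a mu^2)
  s1 <- sum(1 / sf[case]); s0 <- sum(1 / sf[ctrl])
  vm1 <- (m1 * s1 + disp * m1^2 * n1) / n1^2
  vm0 <- (m0 * s0 + disp * m0^2 * n0) / n0^2
  se <- sqrt(vm1 / m1^2 + vm0 / m0^2) / log(2)
  stat <- log2fc / se
  pvalue <- 2 * stats::pnorm(-abs(stat))
  out <- data.frame(gene = rownames(c$counts), base_mean = base_mean,
                    log2fc = log2fc, lfc_se = se, stat = stat,
                    pvalue = pvalue, fdr = NA_real_, dispersion = disp,
                    filter_pass = pass, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$log2fc[!pass] <- NA_real_
  out$lfc_se[!pass] <- out$stat[!pass] <- out$pvalue[!pass] <- NA_real_
  out$fdr[pass] <- bh_adjust(out$pvalue[pass])
  attr(out, "size_factors") <- sf
  attr(out, "groups") <- c(case = n1, control = n0)
  class(out) <- c("nb_de", "data.frame")
  out
}

#' @export
print.nb_de <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("NB Wald DE result: %d genes (%d pass filter), %d case vs %d control\n",
              nrow(x), sum(x$filter_pass), g[["case"]], g[["control"]]))
  cat(sprintf("  DEGs at FDR<=0.01: %d; at FDR<=0.05: %d\n",
              sum(x$fdr <= 0.01, na.rm = TRUE), sum(x$fdr <= 0.05, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.nb_de <- function(object, ...) {
  print(object)
  ok <- object$filter_pass
  cat("  log2FC quartiles (tested genes): ",
      paste(format(stats::quantile(object$log2fc[ok]), digits = 3),
            collapse = " "), "\n")
  invisible(object)
}

#' MA-style plot for an NB DE result
#'
#' @param x An `nb_de` object.
#' @param alpha FDR threshold used to colour significant genes.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nb_de <- function(x, alpha = 0.01, ...) {
  ok <- x$filter_pass
  sig <- !is.na(x$fdr) & x$fdr <= alpha
  graphics::plot(log10(x$base_mean[ok] + 1), x$log2fc[ok],
                 col = ifelse(sig[ok], "red", "grey40"), pch = 20,
                 xlab = "log10(base mean + 1)", ylab = "log2 fold change", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Convert an NB DE result to a contrast table
#'
#' Keeps filter-passing genes only (those with defined statistics).
#'
#' @param de An `nb_de` object.
#' @param contrast_id Identifier for the resulting table.
#' @return A [contrast_table()].
#' @export
as_contrast_table <- function(de, contrast_id = "de") {
  stopifnot(inherits(de, "nb_de"))
  keep <- de$filter_pass
  contrast_table(de$gene[keep], de$log2fc[keep], de$pvalue[keep],
                 de$fdr[keep], contrast_id)
}
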
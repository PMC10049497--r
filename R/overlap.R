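# Overlap significance between gene sets: Fisher's exact test (two-sided),
# upper-tail hypergeometric, and direction-stratified variants against a
# consensus core.

#' Overlap significance between two gene sets
#'
#' Partitions the universe into the 2x2 table (in both / A only / B only /
#' neither) and reports the two-sided Fisher exact p, the upper-tail
#' hypergeometric p (probability of an overlap at least this large), and
#' the sample cross-product odds ratio (with a 0.5 Haldane correction only
#' when a cell is zero).
#'
#' @param setA,setB Character vectors; must be subsets of `universe`.
#' @param universe Character vector of all eligible genes (non-empty).
#' @return List of class `overlap_result`: n_universe, n_setA, n_setB,
#'   n_overlap, odds_ratio, p_fisher, p_hypergeom.
#' @examples
#' u <- paste0("g", 1:10)
#' overlap_test(u[1:5], u[1:5], u)  # p_hypergeom = 1/choose(10,5)
#' @export
overlap_test <- function(setA, setB, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
    stop("setA and setB must be subsets of the universe", call. = FALSE)
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  c <- length(setB) - a
  d <- length(universe) - a - b - c
  tab <- matrix(c(a, b, c, d), nrow = 2)
  p_fisher <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  p_hyper <- stats::phyper(a - 1, length(setA),
                           length(universe) - length(setA), length(setB),
                           lower.tail = FALSE)
  if (any(tab == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    if (a == 0) or <- 0          # no overlap at all: report 0, not a corrected ratio
  } else or <- (a * d) / (b * c)
  structure(list(n_universe = length(universe), n_setA = length(setA),
                 n_setB = length(setB), n_overlap = a, odds_ratio = or,
                 p_fisher = min(1, p_fisher), p_hypergeom = min(1, p_hyper)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Overlap: %d of |A|=%d, |B|=%d in universe %d  (OR %.3g, Fisher p %.3g, hypergeom p %.3g)\n",
    x$n_overlap, x$n_setA, x$n_setB, x$n_universe, x$odds_ratio,
    x$p_fisher, x$p_hypergeom))
  invisible(x)
}

#' Direction-stratified overlap of a contrast with a consensus core
#'
#' The contrast's DEGs (FDR <= alpha, restricted to the universe) are
#' tested against the whole core ignoring direction (`both`), and the
#' up-/down-regulated DEGs against the matching up/down core (`up_only`,
#' `down_only`) — i.e. genes changed in the same direction in both sets.
#'
#' @param t A [contrast_table()].
#' @param core A `core_result` with direction labels.
#' @param alpha DEG threshold on the contrast's FDR.
#' @param universe Character vector of eligible genes.
#' @return List with elements `both`, `up_only`, `down_only`, each an
#'   [overlap_test()] result.
#' @export
directional_overlap <- function(t, core, alpha = 0.01, universe) {
  validate_contrast_table(t)
  universe <- unique(as.character(universe))
  deg <- t$gene[!is.na(t$fdr) & t$fdr <= alpha]
  deg_up <- t$gene[!is.na(t$fdr) & t$fdr <= alpha & t$log2fc > 0]
  deg_down <- t$gene[!is.na(t$fdr) & t$fdr <= alpha & t$log2fc < 0]
  core_all <- intersect(core$core_genes, universe)
  core_up <- intersect(names(core$direction)[core$direction == "up"], universe)
  core_down <- intersect(names(core$direction)[core$direction == "down"], universe)
  list(
    both = overlap_test(intersect(deg, universe), core_all, universe),
    up_only = overlap_test(intersect(deg_up, universe), core_up, universe),
    down_only = overlap_test(intersect(deg_down, universe), core_down, universe)
  )
}
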
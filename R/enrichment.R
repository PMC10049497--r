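# Pre-ranked gene-set enrichment with the weighted Kolmogorov-Smirnov
# running-sum statistic and a gene-permutation null, plus ranking helpers.

#' Rank genes by signed significance-weighted fold change
#'
#' Per-gene score is -log10(max(fdr, pseudocount)) * log2fc, sorted
#' descending; score ties are broken lexicographically by gene id so the
#' ordering (and hence any permutation null) is deterministic.
#'
#' @param t A [contrast_table()].
#' @param pseudocount Lower clamp applied to the FDR before the log so that
#'   reported zero FDRs still give finite scores (default 1e-300).
#' @return data.frame of class `ranked_list` with columns gene, score.
#' @export
rank_genes <- function(t, pseudocount = 1e-300) {
  validate_contrast_table(t)
  score <- -log10(pmax(t$fdr, pseudocount)) * t$log2fc
  o <- order(-score, t$gene, method = "radix")
  structure(data.frame(gene = t$gene[o], score = score[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Invert a ranked list
#'
#' Negates every score and re-sorts. Used to harmonise gain-of-function
#' contrasts at the ranking stage so downstream enrichment scores inherit
#' the inversion; applying it twice restores the original list.
#'
#' @param r A `ranked_list`.
#' @return The inverted `ranked_list`.
#' @export
invert_scores <- function(r) {
  o <- order(-(-r$score), r$gene, method = "radix")
  structure(data.frame(gene = r$gene[o], score = -r$score[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# ES from sorted hit positions only (O(|S|)); identical statistic to the
# full running-sum walk, used for the permutation null.
es_from_hits <- function(hits_sorted, w_all, n) {
  s <- length(hits_sorted)
  wsum <- sum(w_all[hits_sorted])
  winc <- if (wsum > 0) w_all[hits_sorted] / wsum else rep(1 / s, s)
  dec <- 1 / (n - s)
  k <- seq_len(s)
  cumw <- cumsum(winc)
  top <- cumw - (hits_sorted - k) * dec          # running sum just after hit k
  bot <- c(0, cumw[-s]) - (hits_sorted - k) * dec # just before hit k
  hi <- max(top); lo <- min(bot)
  if (hi >= -lo) hi else lo
}

#' Weighted KS enrichment score of a gene set in a ranked list
#'
#' Walks the ranked list: at genes in the set the running sum rises by
#' |score|^weight / sum of hit |score|^weight, at other genes it falls by
#' 1/(N - number of hits). The enrichment score is the running sum's
#' maximum deviation from zero (signed); the walk always returns to 0.
#' If every hit score is 0 the hit increments fall back to equal weights.
#'
#' @param r A `ranked_list`.
#' @param gene_set Character vector; must intersect the ranked genes and
#'   must not cover them entirely (no misses would make the statistic
#'   degenerate).
#' @param weight Exponent on |score| for hit increments (default 1, the
#'   conventional pre-ranked weighting; 0 gives the classic KS statistic).
#' @return List with elements `es` (in [-1, 1]) and `running_sum`.
#' @export
enrichment_score <- function(r, gene_set, weight = 1) {
  stopifnot(inherits(r, "ranked_list"), weight >= 0)
  hit <- r$gene %in% gene_set
  nh <- sum(hit)
  n <- nrow(r)
  if (nh == 0L) stop("gene set does not intersect the ranked list", call. = FALSE)
  if (nh == n) stop("gene set covers the entire ranked list (no misses)",
                    call. = FALSE)
  w <- abs(r$score)^weight
  wh <- sum(w[hit])
  inc <- numeric(n)
  inc[hit] <- if (wh > 0) w[hit] / wh else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  run <- cumsum(inc)
  es <- run[which.max(abs(run))]
  list(es = es, running_sum = run)
}

#' Permutation enrichment of gene sets in a ranked list
#'
#' For each gene set, a null distribution of enrichment scores is built
#' from `n_perm` random same-size gene-label sets. The p-value is
#' sign-stratified, (1 + #same-sign nulls at least as extreme) /
#' (1 + #same-sign nulls); NES divides the ES by the mean |null ES| of the
#' same sign; FDR is the conventional ratio of null-vs-observed NES tail
#' fractions (pooled across sets), clipped to [0,1]. Deterministic given
#' `seed`.
#'
#' @param r A `ranked_list`.
#' @param gene_sets Named list of character vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param weight Hit-weight exponent, as in [enrichment_score()].
#' @param seed RNG seed.
#' @return data.frame of class `enrichment_result`: gene_set_name, es,
#'   nes, pvalue, fdr, n_hits.
#' @export
permutation_enrichment <- function(r, gene_sets, n_perm = 1000, weight = 1,
                                   seed) {
  stopifnot(inherits(r, "ranked_list"), is.list(gene_sets))
  if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
    stop("gene_sets must be a named list", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  n <- nrow(r)
  w <- abs(r$score)^weight
  sizes <- vapply(gene_sets, function(s) sum(r$gene %in% s), integer(1))
  if (any(vapply(gene_sets, length, integer(1)) > n))
    stop("gene set larger than the ranked list", call. = FALSE)
  if (any(sizes == 0L)) stop("a gene set does not intersect the ranked list",
                             call. = FALSE)
  if (any(sizes == n)) stop("a gene set covers the entire ranked list",
                            call. = FALSE)
  obs <- vapply(gene_sets, function(s) enrichment_score(r, s, weight)$es,
                numeric(1))
  null_es <- with_seed(seed, lapply(sizes, function(sz) {
    vapply(seq_len(n_perm), function(b)
      es_from_hits(sort.int(sample.int(n, sz)), w, n), numeric(1))
  }))
  res <- data.frame(gene_set_name = names(gene_sets), es = obs,
                    nes = NA_real_, pvalue = NA_real_, fdr = NA_real_,
                    n_hits = sizes, row.names = NULL, stringsAsFactors = FALSE)
  null_nes <- vector("list", length(gene_sets))
  for (i in seq_along(gene_sets)) {
    nul <- null_es[[i]]
    same <- if (obs[i] >= 0) nul >= 0 else nul <= 0
    ns <- sum(same)
    res$pvalue[i] <- (1 + sum(abs(nul[same]) >= abs(obs[i]))) / (1 + ns)
    mpos <- mean(abs(nul[nul >= 0])); mneg <- mean(abs(nul[nul < 0]))
    res$nes[i] <- obs[i] / if (obs[i] >= 0) mpos else mneg
    nn <- ifelse(nul >= 0, nul / mpos, nul / mneg)
    null_nes[[i]] <- nn[is.finite(nn)]
  }
  pool <- unlist(null_nes)
  for (i in seq_along(gene_sets)) {
    nes <- res$nes[i]
    if (!is.finite(nes)) { res$fdr[i] <- 1; next }
    if (nes >= 0) {
      num <- mean(pool[pool >= 0] >= nes)
      den <- mean(res$nes[res$nes >= 0] >= nes)
    } else {
      num <- mean(pool[pool < 0] <= nes)
      den <- mean(res$nes[res$nes < 0] <= nes)
    }
    res$fdr[i] <- min(1, max(0, if (den > 0) num / den else 0))
  }
  class(res) <- c("enrichment_result", "data.frame")
  res
}
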
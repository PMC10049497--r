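# Shared fixture builders. Everything is generated in code at test time.

make_track <- function(levels, chromosome = "chr8") {
  structure(list(chromosome = chromosome,
                 genes = paste0("g", seq_along(levels)),
                 positions = seq_along(levels) * 1000L,
                 levels = as.numeric(levels)),
            class = "position_track")
}

make_ranked <- function(genes, scores) {
  o <- order(-scores, genes, method = "radix")
  structure(data.frame(gene = genes[o], score = scores[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# A 6-gene x 10-contrast fixture with two planted concordant genes
# (gA up, gB down) significant in 8 contrasts each; gC..gF are background
# with supports 3, 2, 1, 1 — enumerable by hand.
tiny_multi_contrast <- function(alpha = 0.01) {
  genes <- c("gA", "gB", "gC", "gD", "gE", "gF")
  support <- c(gA = 8, gB = 8, gC = 3, gD = 2, gE = 1, gF = 1)
  sig_in <- list(gA = 1:8, gB = 2:9, gC = c(1, 4, 7), gD = c(2, 5),
                 gE = 3, gF = 10)
  lfc_sign <- c(gA = 1, gB = -1, gC = 1, gD = -1, gE = 1, gF = 1)
  tables <- lapply(1:10, function(j) {
    sig <- vapply(genes, function(g) j %in% sig_in[[g]], logical(1))
    contrast_table(
      gene = genes,
      log2fc = ifelse(sig, lfc_sign * 0.8, 0.05),
      pvalue = ifelse(sig, 1e-4, 0.5),
      fdr = ifelse(sig, 0.005, 0.5),
      contrast_id = sprintf("t%02d", j))
  })
  list(tables = tables, support = support, sig_in = sig_in,
       lfc_sign = lfc_sign)
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Brute-force max-|t| split search used as the segmentation oracle:
# direct t.test-style computation over every candidate arc (i, j].
brute_force_max_t <- function(x, min_len, circular = FALSE) {
  n <- length(x)
  best <- list(stat = -Inf, i = NA, j = NA)
  i_range <- if (circular) 0:(n - 1) else 0
  for (i in i_range) {
    for (j in seq_len(n)) {
      arc_len <- j - i
      if (j <= i) next
      if (arc_len < min_len || (n - arc_len) < min_len) next
      if (i == 0 && j == n) next  # the whole track is not a split
      arc <- x[(i + 1):j]
      rest <- x[setdiff(seq_len(n), (i + 1):j)]
      m1 <- mean(arc); m2 <- mean(rest)
      sp2 <- (sum((arc - m1)^2) + sum((rest - m2)^2)) / (n - 2)
      t <- if (sp2 <= 0) {
        if (m1 == m2) NA_real_ else Inf
      } else abs((m1 - m2) / sqrt(sp2 * (1 / arc_len + 1 / (n - arc_len))))
      if (!is.na(t) && t > best$stat) best <- list(stat = t, i = i, j = j)
    }
  }
  if (!is.finite(best$stat) && best$stat == -Inf) list(stat = NA_real_) else best
}

# Exhaustive weighted-KS ES by literal running-sum walk (independent of
# the package's implementation).
walk_es <- function(scores, hit, weight = 1) {
  n <- length(scores)
  nh <- sum(hit)
  w <- abs(scores)^weight
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - nh))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}
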
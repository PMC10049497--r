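# Biotype composition of gene sets and chromosome-positional analysis.
#
# Positional analysis encodes core-up / background / core-down genes along
# a chromosome as levels 6 / 3 / 0 at their TSS and looks for contiguous
# stretches of shifted level with a simplified circular-binary-segmentation
# style recursive split: max two-sample t statistic over candidate
# boundaries, accepted by a within-interval permutation p-value.

#' Biotype composition of a gene set
#'
#' Counts and fractions of the eight broad gene categories
#' ([gene_categories()]) within a gene set. Genes absent from the
#' annotation are tallied in an `unannotated` bucket with a warning.
#'
#' @param genes Character vector (a gene set); must be non-empty.
#' @param ann Annotation data.frame from [read_annotation()] /
#'   [generate_annotation()].
#' @return data.frame with columns category, count, fraction; fractions sum
#'   to 1 over the set.
#' @examples
#' ann <- generate_annotation(n_genes = 100, seed = 1)
#' composition(ann$gene[1:10], ann)
#' @export
composition <- function(genes, ann) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("empty gene set", call. = FALSE)
  idx <- match(genes, ann$gene)
  cats <- gene_categories()
  if (anyNA(idx)) {
    warning(sprintf("%d gene(s) not in annotation counted as 'unannotated'",
                    sum(is.na(idx))), call. = FALSE)
    cats <- c(cats, "unannotated")
  }
  gc <- ifelse(is.na(idx), "unannotated", ann$category[idx])
  count <- as.integer(table(factor(gc, levels = cats)))
  data.frame(category = cats, count = count,
             fraction = count / length(genes), stringsAsFactors = FALSE)
}

#' Build a 6/3/0 positional track for one chromosome
#'
#' Core-up genes are encoded as level 6, core-down as 0 and background
#' (non-core) genes as 3, ordered by TSS. TSS ties are broken
#' deterministically by gene id so the ordering is strict; positions are
#' reported unmodified.
#'
#' @param core A `core_result` (see [consensus_core()]).
#' @param ann Annotation data.frame with `gene`, `chromosome`, `tss`.
#' @param chromosome Chromosome to build the track for.
#' @param background Character vector of non-core genes to include at
#'   level 3, or NULL to sample them.
#' @param n_background If `background` is NULL, how many background genes
#'   to draw (without replacement) from non-core genes on the chromosome;
#'   NULL means all of them.
#' @param seed RNG seed for background sampling.
#' @return List of class `position_track` with `chromosome`, `genes`,
#'   `positions` (TSS order) and `levels` (6/3/0).
#' @export
build_track <- function(core, ann, chromosome, background = NULL,
                        n_background = NULL, seed = NULL) {
  on_chrom <- ann[ann$chromosome == chromosome, , drop = FALSE]
  if (nrow(on_chrom) == 0L)
    stop(sprintf("no genes on chromosome %s", chromosome), call. = FALSE)
  core_here <- intersect(core$core_genes, on_chrom$gene)
  if (is.null(background)) {
    pool <- setdiff(on_chrom$gene, core$core_genes)
    if (!is.null(n_background)) {
      if (n_background > length(pool))
        stop("n_background exceeds available non-core genes", call. = FALSE)
      background <- with_seed(seed, sample(pool, n_background))
    } else background <- pool
  }
  background <- setdiff(intersect(background, on_chrom$gene), core_here)
  genes <- c(core_here, background)
  if (length(genes) == 0L)
    stop(sprintf("no usable genes on chromosome %s", chromosome), call. = FALSE)
  lev <- ifelse(genes %in% core_here,
                ifelse(core$direction[genes] == "up", 6, 0), 3)
  tss <- on_chrom$tss[match(genes, on_chrom$gene)]
  o <- order(tss, genes, method = "radix")
  structure(list(chromosome = chromosome, genes = genes[o],
                 positions = tss[o], levels = as.numeric(lev[o])),
            class = "position_track")
}

#' @export
print.position_track <- function(x, ...) {
  cat(sprintf("Positional track on %s: %d genes (up %d / down %d / background %d)\n",
              x$chromosome, length(x$genes), sum(x$levels == 6),
              sum(x$levels == 0), sum(x$levels == 3)))
  invisible(x)
}

# Max pooled-variance two-sample t over all candidate splits of x.
# Linear mode: splits after position i (left 1..i vs right). Circular mode:
# arcs (i+1)..j against their complement. Returns max |t|, and the split.
max_t_split <- function(x, min_len, circular = FALSE) {
  n <- length(x)
  S <- cumsum(x); Q <- cumsum(x^2)
  tot <- S[n]; qtot <- Q[n]
  tstat <- function(s1, q1, n1) {
    n2 <- n - n1
    m1 <- s1 / n1; m2 <- (tot - s1) / n2
    sp2 <- (qtot - n1 * m1^2 - n2 * m2^2) / (n - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    t[sp2 <= 0 & m1 != m2] <- Inf
    t[sp2 <= 0 & m1 == m2] <- NA_real_
    abs(t)
  }
  if (!circular) {
    if (n < 2 * min_len) return(list(stat = NA_real_))
    i <- min_len:(n - min_len)
    tv <- tstat(S[i], Q[i], i)
    if (all(is.na(tv))) return(list(stat = NA_real_))
    b <- which.max(tv)  # ties: first (leftmost) boundary, deterministic
    list(stat = tv[b], i = i[b], j = n)
  } else {
    if (n < 2 * min_len) return(list(stat = NA_real_))
    best <- list(stat = NA_real_)
    for (i in 0:(n - 1)) {
      # arc (i+1)..j, j from i+min_len to min(n, i + n - min_len)
      j <- seq.int(i + min_len, min(n, i + n - min_len))
      if (i == 0 && length(j)) j <- j[j < n]  # arc = whole track is no split
      if (!length(j)) next
      s1 <- S[j] - if (i > 0) S[i] else 0
      q1 <- Q[j] - if (i > 0) Q[i] else 0
      tv <- tstat(s1, q1, j - i)
      if (all(is.na(tv))) next
      b <- which.max(tv)
      if (is.na(best$stat) || (!is.na(tv[b]) && tv[b] > best$stat))
        best <- list(stat = tv[b], i = i, j = j[b])
    }
    best
  }
}

# Permutation p-value for the max-t statistic within an interval.
perm_pvalue <- function(x, obs, min_len, n_perm, circular) {
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    st <- max_t_split(sample(x), min_len, circular)$stat
    if (!is.na(st) && st >= obs) cnt <- cnt + 1L
  }
  (1 + cnt) / (n_perm + 1)
}

#' Segment a positional track by recursive max-t splitting
#'
#' Within each interval the boundary (linear mode) or arc boundary pair
#' (`circular = TRUE`) maximising the pooled two-sample t statistic between
#' the two parts is found; the split is accepted when its within-interval
#' label-permutation p-value (of the max statistic, so the search is
#' accounted for) is at most `alpha_split`, and accepted parts are
#' recursively re-segmented. Constant intervals and intervals shorter than
#' `2 * min_len` are never split.
#'
#' @param track A `position_track` from [build_track()].
#' @param alpha_split Acceptance threshold for the permutation p (default
#'   0.01).
#' @param n_perm Number of within-interval permutations (default 1000; a
#'   warning is issued below 100).
#' @param min_len Minimum segment length in genes (default 5).
#' @param seed RNG seed (required for reproducible permutations).
#' @param circular If TRUE candidate splits are circular arcs; default
#'   FALSE (linear boundaries), sufficient for detecting a contiguous
#'   stretch.
#' @return data.frame of class `cbs_segments`: one row per segment with
#'   start_index/end_index (1-based inclusive into the track),
#'   start_pos/end_pos (TSS of first/last gene), n, mean_level and the
#'   permutation p-value of the accepted split that created the segment
#'   (NA for an unsplit interval).
#' @export
cbs_segment <- function(track, alpha_split = 0.01, n_perm = 1000, min_len = 5,
                        seed, circular = FALSE) {
  stopifnot(inherits(track, "position_track"))
  stopifnot_scalar_prob(alpha_split, "alpha_split")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse permutation p-value",
                            call. = FALSE)
  x <- track$levels
  n <- length(x)
  boundaries <- integer(0)     # accepted split points (end index of left part)
  pvals <- list()
  with_seed(seed, {
    recurse <- function(lo, hi) {
      len <- hi - lo + 1L
      if (len < 2 * min_len) return(invisible())
      seg <- x[lo:hi]
      if (max(seg) == min(seg)) return(invisible())  # constant: t undefined
      sp <- max_t_split(seg, min_len, circular)
      if (is.na(sp$stat)) return(invisible())
      p <- perm_pvalue(seg, sp$stat, min_len, n_perm, circular)
      if (p > alpha_split) return(invisible())
      cuts <- integer(0)
      if (sp$i > 0) cuts <- c(cuts, lo + sp$i - 1L)
      if (sp$j < len) cuts <- c(cuts, lo + sp$j - 1L)
      if (!length(cuts)) return(invisible())
      boundaries <<- c(boundaries, cuts)
      for (cut in cuts) pvals[[as.character(cut)]] <<- p
      starts <- c(lo, cuts + 1L)
      ends <- c(cuts, hi)
      for (s in seq_along(starts)) recurse(starts[s], ends[s])
    }
    recurse(1L, n)
  })
  boundaries <- sort(unique(boundaries))
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  data.frame(
    chromosome = track$chromosome,
    start_index = starts, end_index = ends,
    start_pos = track$positions[starts], end_pos = track$positions[ends],
    n = ends - starts + 1L,
    mean_level = vapply(seq_along(starts),
                        function(i) mean(x[starts[i]:ends[i]]), numeric(1)),
    pvalue = vapply(seq_along(starts), function(i) {
      p <- pvals[[as.character(ends[i])]]
      if (is.null(p)) NA_real_ else p
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Write segments as a BED-like TSV
#'
#' Default output uses 1-based inclusive coordinates (chrom, start_pos,
#' end_pos, mean_level, pvalue); `bed = TRUE` emits true BED (0-based
#' half-open).
#'
#' @param segments Output of [cbs_segment()].
#' @param path Output path.
#' @param bed Emit true BED coordinates (default FALSE).
#' @export
write_segments <- function(segments, path, bed = FALSE) {
  out <- segments[c("chromosome", "start_pos", "end_pos", "mean_level", "pvalue")]
  if (bed) out$start_pos <- out$start_pos - 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !bed)
  invisible(path)
}
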
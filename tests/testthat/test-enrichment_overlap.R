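test_that("ranking scores follow the signed -log10(FDR) x log2FC formula", {
  t <- contrast_table(c("g1", "g2", "g3"), c(2, 1, -1), c(0.001, 0.5, 0.001),
                      c(0.01, 1.0, 0.01), "c")
  r <- rank_genes(t)
  expect_equal(r$score[r$gene == "g1"], 4)      # -log10(0.01) * 2
  expect_equal(r$score[r$gene == "g2"], 0)      # fdr 1 scores 0
  expect_equal(r$score[r$gene == "g3"], -2)
  expect_equal(r$gene, c("g1", "g2", "g3"))     # descending

  # zero FDR stays finite through the pseudocount clamp
  t2 <- contrast_table("g1", 1, 0, 0, "c")
  expect_true(is.finite(rank_genes(t2)$score))

  # ties break lexicographically by gene id
  t3 <- contrast_table(c("b", "a"), c(1, 1), c(0.5, 0.5), c(0.5, 0.5), "c")
  expect_equal(rank_genes(t3)$gene, c("a", "b"))
})

test_that("score inversion negates, re-sorts, and is an involution", {
  r <- make_ranked(c("g1", "g2"), c(3, -1))
  ri <- invert_scores(r)
  expect_equal(ri$score, c(1, -3))
  expect_equal(ri$gene, c("g2", "g1"))
  expect_equal(invert_scores(ri)$score, r$score)
  expect_equal(invert_scores(ri)$gene, r$gene)

  # all-zero scores: ordering falls back to the gene-id tie-break
  r0 <- make_ranked(c("b", "a"), c(0, 0))
  expect_equal(invert_scores(r0)$gene, c("a", "b"))
})

test_that("enrichment score matches the hand-walked running sum", {
  r <- make_ranked(paste0("g", 1:5), c(5, 4, 3, 2, 1))
  es <- enrichment_score(r, c("g1", "g3"), weight = 1)
  # hand walk: +5/8, -1/3, +3/8, -1/3, -1/3
  expect_equal(es$running_sum,
               cumsum(c(5 / 8, -1 / 3, 3 / 8, -1 / 3, -1 / 3)))
  expect_equal(es$es, 2 / 3)
  expect_equal(es$running_sum[5], 0, tolerance = 1e-9)

  # single top-ranked hit: ES exactly 1 for any weight
  expect_equal(enrichment_score(r, "g1", weight = 1)$es, 1)
  expect_equal(enrichment_score(r, "g1", weight = 0)$es, 1)

  # degenerate sets error
  expect_error(enrichment_score(r, paste0("g", 1:5)), "entire")
  expect_error(enrichment_score(r, "absent"), "intersect")
})

test_that("ES stays in [-1,1], ends at zero, and agrees with the independent walk", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    r <- make_ranked(sprintf("g%03d", 1:n), rnorm(n, 0, 2))
    s <- sample(r$gene, sample(2:(n - 1), 1))
    w <- sample(c(0, 0.5, 1, 1.5), 1)
    es <- enrichment_score(r, s, weight = w)
    expect_gte(es$es, -1); expect_lte(es$es, 1)
    expect_equal(es$running_sum[n], 0, tolerance = 1e-9)
    expect_equal(es$es, walk_es(r$score, r$gene %in% s, w), tolerance = 1e-12)
    # hits-only fast path computes the identical statistic
    expect_equal(concore:::es_from_hits(which(r$gene %in% s),
                                        abs(r$score)^w, n),
                 es$es, tolerance = 1e-12)
  }
})

test_that("ES agrees with the reference GSEA statistic implementation", {
  set.seed(7)
  r <- make_ranked(sprintf("g%04d", 1:500), sort(rnorm(500, 0, 2), decreasing = TRUE))
  for (sz in c(5, 30, 120)) {
    s <- sample(r$gene, sz)
    expect_equal(enrichment_score(r, s, weight = 1)$es,
                 fgsea::calcGseaStat(r$score,
                                     selectedStats = which(r$gene %in% s),
                                     gseaParam = 1, scoreType = "std"),
                 tolerance = 1e-10)
  }
})

test_that("inverting the ranking flips the enrichment score sign exactly", {
  set.seed(13)
  r <- make_ranked(sprintf("g%03d", 1:80), rnorm(80, 0.3, 1.5))
  for (rep in 1:10) {
    s <- sample(r$gene, 12)
    expect_equal(enrichment_score(invert_scores(r), s)$es,
                 -enrichment_score(r, s)$es, tolerance = 1e-12)
  }
})

test_that("permutation p-values match exhaustive enumeration on small lists", {
  r <- make_ranked(paste0("g", 1:8), c(4, 3, 2.5, 2, 1.5, 1, 0.5, 0.2))
  s <- c("g1", "g2", "g5")
  obs <- enrichment_score(r, s)$es
  # exhaustive null over all C(8,3) same-size gene-label sets
  combs <- combn(8, 3)
  null_es <- apply(combs, 2, function(idx)
    concore:::es_from_hits(sort(idx), abs(r$score)^1, 8))
  same <- if (obs >= 0) null_es >= 0 else null_es <= 0
  exact_p <- sum(same & abs(null_es) >= abs(obs)) / sum(same)
  res <- permutation_enrichment(r, list(s = s), n_perm = 2000, seed = 5)
  # Monte-Carlo estimate within binomial error of the exhaustive value
  mc_se <- sqrt(exact_p * (1 - exact_p) / 2000)
  expect_lt(abs(res$pvalue - exact_p), 4 * mc_se + 2 / 2000)
  expect_equal(sign(res$nes), sign(res$es))
  expect_gte(res$pvalue, 1 / 2001)
})

test_that("planted concordant enrichment is detected and nulls are calibrated", {
  sim <- generate_multi_contrast(n_genes = 800, n_contrasts = 6,
                                 n_core_up = 50, n_core_down = 40,
                                 inverted_ids = character(0), seed = 23)
  fit <- consensus_core(sim$tables, min_contrasts = 2)
  up <- names(fit$direction)[fit$direction == "up"]
  down <- names(fit$direction)[fit$direction == "down"]
  r <- rank_genes(sim$tables[[1]])
  res <- permutation_enrichment(r, list(up = up, down = down),
                                n_perm = 500, seed = 29)
  expect_gt(res$es[res$gene_set_name == "up"], 0)
  expect_lt(res$es[res$gene_set_name == "down"], 0)
  expect_lte(res$pvalue[res$gene_set_name == "up"], 0.01)
  expect_lte(res$pvalue[res$gene_set_name == "down"], 0.01)

  # null calibration: random sets give roughly uniform p
  set.seed(41)
  rr <- make_ranked(sprintf("g%04d", 1:600), rnorm(600))
  hits <- 0L
  for (i in 1:60) {
    gs <- sample(rr$gene, 40)
    p <- permutation_enrichment(rr, list(x = gs), n_perm = 100,
                                seed = 7000 + i)$pvalue
    hits <- hits + (p <= 0.05)
  }
  expect_gte(hits / 60, 0.005)
  expect_lte(hits / 60, 0.15)
})

test_that("overlap tests agree with exhaustive enumeration and closed forms", {
  u <- paste0("g", 1:10)
  r <- overlap_test(u[1:5], u[1:5], u)
  expect_equal(r$p_hypergeom, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(r$n_overlap, 5L)

  # disjoint sets covering the universe: odds ratio 0
  expect_equal(overlap_test(u[1:5], u[6:10], u)$odds_ratio, 0)

  # B = universe: overlap is |A| and both p-values are 1
  r2 <- overlap_test(u[1:4], u, u)
  expect_equal(r2$n_overlap, 4L)
  expect_equal(r2$p_fisher, 1)
  expect_equal(r2$p_hypergeom, 1)

  # hypergeometric upper tail vs direct enumeration for all small tables
  for (nu in c(6, 9)) {
    uu <- paste0("x", seq_len(nu))
    for (na in 1:4) for (nb in 1:4) {
      A <- uu[seq_len(na)]
      B <- uu[nu - seq_len(nb) + 1]
      res <- overlap_test(A, B, uu)
      k <- res$n_overlap
      # direct sum over the hypergeometric pmf
      p_direct <- sum(dhyper(k:min(na, nb), na, nu - na, nb))
      expect_equal(res$p_hypergeom, p_direct, tolerance = 1e-12)
      expect_equal(res$p_fisher,
                   fisher.test(matrix(c(k, na - k, nb - k, nu - na - nb + k),
                                      2))$p.value, tolerance = 1e-12)
    }
  }
  expect_error(overlap_test("g1", "g1", character(0)), "universe")
  expect_error(overlap_test("zz", u[1], u), "subsets")
})

test_that("direction-stratified overlap separates concordant from inverted contrasts", {
  u <- sprintf("g%03d", 1:200)
  core <- structure(list(
    core_genes = u[1:40],
    support = setNames(rep(5, 40), u[1:40]),
    mean_lfc = setNames(c(rep(1, 20), rep(-1, 20)), u[1:40]),
    direction = setNames(c(rep("up", 20), rep("down", 20)), u[1:40]),
    k = 4L, n_contrasts = 10L, alpha = 0.01), class = "core_result")
  # contrast concordant with the core on every core gene
  t <- contrast_table(u, c(rep(1, 20), rep(-1, 20), rep(0.1, 160)),
                      c(rep(1e-5, 40), rep(0.8, 160)),
                      c(rep(1e-4, 40), rep(0.9, 160)), "asd")
  dov <- directional_overlap(t, core, alpha = 0.01, universe = u)
  expect_equal(dov$up_only$n_overlap, 20L)
  expect_equal(dov$down_only$n_overlap, 20L)
  expect_equal(dov$both$n_overlap, 40L)
  expect_lte(dov$both$p_fisher, 0.05)
  expect_lte(dov$up_only$p_fisher, 0.05)
  expect_lte(dov$down_only$p_fisher, 0.05)

  # sign-inverted contrast: large undirected overlap, empty directional one
  t2 <- contrast_table(u, c(rep(-1, 20), rep(1, 20), rep(0.1, 160)),
                       c(rep(1e-5, 40), rep(0.8, 160)),
                       c(rep(1e-4, 40), rep(0.9, 160)), "inv")
  dov2 <- directional_overlap(t2, core, alpha = 0.01, universe = u)
  expect_equal(dov2$both$n_overlap, 40L)
  expect_equal(dov2$up_only$n_overlap, 0L)
  expect_equal(dov2$down_only$n_overlap, 0L)
})
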
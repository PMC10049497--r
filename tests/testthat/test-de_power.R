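test_that("the expression filter requires min_count in at least half the samples", {
  k <- rbind(g1 = c(12, 0, 15, 0), g2 = c(9, 9, 9, 9), g3 = c(0, 0, 0, 0),
             g4 = c(10, 10, 0, 0))
  colnames(k) <- paste0("s", 1:4)
  cm <- count_matrix(k, c("case", "case", "control", "control"))
  mask <- expression_filter(cm)
  expect_true(mask[["g1"]])    # 2 of 4 samples at >= 10
  expect_false(mask[["g2"]])   # 9 < 10 everywhere
  expect_false(mask[["g3"]])
  expect_true(mask[["g4"]])
  # knobs reachable: a "sum of 10 in half the samples" reading via min_count
  expect_true(expression_filter(cm, min_count = 5, min_fraction = 1)[["g2"]])
})

test_that("size factors implement median-of-ratios with unit geometric mean", {
  k <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  cm <- count_matrix(k, c("case", "control"))
  sf <- size_factors(cm)
  # exact doubling recovers (1/sqrt(2), sqrt(2)) under the unit-geomean convention
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # identical columns give unit factors
  k2 <- matrix(c(5, 8, 13, 5, 8, 13), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(count_matrix(k2, c("case", "control")))),
               c(1, 1))

  # single sample: factor 1
  k3 <- matrix(c(3, 4), ncol = 1, dimnames = list(c("g1", "g2"), "a"))
  cm3 <- structure(list(counts = k3 * 1.0, group = "case"), class = "count_matrix")
  expect_equal(unname(size_factors(cm3)), 1)

  # column scalar multiples recovered exactly for any scalars
  set.seed(2)
  base <- 2 * (rpois(50, 20) + 1)
  scal <- c(0.5, 1, 2, 4)
  k4 <- outer(base, scal)
  rownames(k4) <- paste0("g", 1:50); colnames(k4) <- paste0("s", 1:4)
  sf4 <- size_factors(count_matrix(k4, c("case", "case", "control", "control")))
  expect_equal(unname(sf4), scal / exp(mean(log(scal))), tolerance = 1e-12)
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  sim <- generate_counts(n_genes = 300, n_per_group = 4, de_fraction = 0.1,
                         seed = 77)
  ours <- size_factors(sim$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts$counts)
  # identical up to the unit-geometric-mean rescaling convention
  expect_equal(unname(ours), unname(ref / exp(mean(log(ref)))),
               tolerance = 1e-10)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  # closed form on sorted distinct p-values with monotone enforcement
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(bh_adjust(p), cummax(rev(cummin(rev(p * 4 / 1:4)))) ,
               tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")
})

test_that("identical groups give exactly zero fold changes", {
  set.seed(5)
  half <- matrix(rpois(200 * 3, 50), nrow = 200)
  k <- cbind(half, half)
  rownames(k) <- paste0("g", 1:200); colnames(k) <- paste0("s", 1:6)
  cm <- count_matrix(k, rep(c("case", "control"), each = 3))
  de <- nb_wald_test(cm)
  expect_true(all(de$log2fc[de$filter_pass] == 0))
  expect_true(all(de$pvalue[de$filter_pass] == 1))
})

test_that("the NB Wald test is calibrated under the null and powered for planted DE", {
  sim <- generate_counts(n_genes = 2500, n_per_group = 10, de_fraction = 0,
                         seed = 7)
  de <- nb_wald_test(sim$counts)
  frac <- mean(de$pvalue[de$filter_pass] <= 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.08)

  sim2 <- generate_counts(n_genes = 2000, n_per_group = 10, de_fraction = 0.05,
                          lfc_distribution = function(n)
                            sample(c(-2, 2), n, replace = TRUE),
                          dispersion_mean = 0.05, seed = 11)
  de2 <- nb_wald_test(sim2$counts)
  deg <- de2$gene[!is.na(de2$fdr) & de2$fdr <= 0.01]
  # recall over testable planted genes: genes below the expression floor
  # are undetectable by construction
  testable <- intersect(sim2$truth$de_genes, de2$gene[de2$filter_pass])
  expect_gte(mean(testable %in% deg), 0.9)

  # all-zero library rejected
  k <- matrix(c(0, 0, 5, 6, 4, 7, 3, 8), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  cm <- count_matrix(k, rep(c("case", "control"), each = 2))
  expect_error(nb_wald_test(cm), "all-zero")
})

test_that("rand index counts agreeing pairs and is label-invariant", {
  expect_equal(rand_index(c(1, 1, 0, 0), c(1, 0, 1, 0)), 2 / 6)
  expect_equal(rand_index(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1)
  a <- c(1, 0, 1, 1, 0)
  expect_equal(rand_index(a, 1 - a), 1)  # complement invariance
  set.seed(3)
  x <- runif(30) > 0.5; y <- runif(30) > 0.5
  expect_equal(rand_index(x, y), rand_index(y, x))
  expect_gte(rand_index(x, y), 0); expect_lte(rand_index(x, y), 1)
  # brute-force pair enumeration oracle
  pairs <- combn(30, 2)
  agree <- mean((x[pairs[1, ]] == x[pairs[2, ]]) ==
                  (y[pairs[1, ]] == y[pairs[2, ]]))
  expect_equal(rand_index(x, y), agree, tolerance = 1e-12)
  expect_error(rand_index(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("fold-change survival curves are exact and non-increasing", {
  de <- structure(data.frame(gene = paste0("g", 1:6),
                             log2fc = c(0.1, 0.2, 0.4, 0.8, 0.05, 3),
                             fdr = c(rep(0.001, 4), 0.9, 0.9)),
                  class = c("nb_de", "data.frame"))
  sc <- fc_survival_curve(de, fdr_threshold = 0.01, grid = c(0, 0.3, 1))
  expect_equal(sc$pct_remaining, c(100, 50, 0))
  expect_true(all(diff(sc$pct_remaining) <= 0))
  expect_equal(attr(sc, "cross50"), 1)  # first grid point strictly below 50%
  de$fdr <- rep(0.9, 6)
  expect_error(fc_survival_curve(de), "no DEGs")
})

test_that("down-sampling at full size reproduces the reference exactly", {
  sim <- generate_counts(n_genes = 600, n_per_group = 5, de_fraction = 0.1,
                         seed = 19)
  pc <- downsampling_experiment(sim$counts, sample_sizes = 5, n_reps = 1,
                                seed = 31)
  expect_equal(pc$rand_index, 1)
  ref <- attr(pc, "reference")
  expect_equal(pc$deg_fc1.0, sum(ref$fdr <= 0.01, na.rm = TRUE))
  # stricter cutoffs never increase a row's DEG count
  expect_true(all(pc$deg_fc1.1 <= pc$deg_fc1.0))
  expect_true(all(pc$deg_fc1.2 <= pc$deg_fc1.1))
})

test_that("down-sampling is reproducible and stable under added replicates", {
  sim <- generate_counts(n_genes = 500, n_per_group = 6, de_fraction = 0.1,
                         seed = 23)
  a <- downsampling_experiment(sim$counts, sample_sizes = c(4, 3), n_reps = 3,
                               seed = 99)
  b <- downsampling_experiment(sim$counts, sample_sizes = c(4, 3), n_reps = 3,
                               seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # adding replicates never perturbs earlier drawings (per-(n, rep) substreams)
  c5 <- downsampling_experiment(sim$counts, sample_sizes = c(4, 3), n_reps = 5,
                                seed = 99)
  expect_equal(as.data.frame(c5[c5$rep <= 3, ]), as.data.frame(a),
               ignore_attr = TRUE)
  # requesting more samples than a group has is an error
  expect_error(downsampling_experiment(sim$counts, sample_sizes = 7,
                                       n_reps = 1, seed = 1), "exceeds")
  # summary exposes box-plot statistics per size and cutoff
  s <- summary(a)
  expect_true(all(c("min", "q1", "median", "q3", "max") %in% names(s)))
  expect_equal(nrow(s), 2 * 3)
})
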
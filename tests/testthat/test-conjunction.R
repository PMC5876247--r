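rand_ismap <- function(n = 500, p_active = 0.1, seed = 1) {
  set.seed(seed)
  lab <- rbinom(n, 1, p_active)
  m <- exp(rnorm(n, 0, 0.5) + 3 * 0.5 * lab)
  m[sample(n, n %/% 5)] <- 0          # exact zeros outside the model support
  list(m = m, lab = lab)
}

test_that("binarization is exactly invariant to positive rescaling", {
  for (seed in 1:6) {
    m <- rand_ismap(seed = seed)$m
    b0 <- suppressWarnings(binarize_lfdr(m, 0.2)$active)
    for (c in c(0.1, 3, 100)) {
      bc <- suppressWarnings(binarize_lfdr(c * m, 0.2)$active)
      expect_identical(bc, b0)
    }
  }
})

test_that("the mixture fit separates a labelled null/alternative mixture", {
  # oracle bound: with null N(0, 0.5) on the log scale, pi0 = 0.9 and the
  # alternative shifted by +3 null-sd, the exact-lfdr rule at threshold 0.2
  # activates z > 2.69 sd, i.e. at most 62% of the alternative; the EM fit
  # must recover most of that and keep false positives low
  sens <- c(); fpr <- c()
  for (r in 1:50) {
    set.seed(100 + r)
    lab <- rbinom(500, 1, 0.1)
    m <- exp(rnorm(500, 0, 0.5) + 3 * 0.5 * lab)
    bm <- suppressWarnings(binarize_lfdr(m, 0.2))
    sens <- c(sens, mean(bm$active[lab == 1]))
    fpr <- c(fpr, mean(bm$active[lab == 0]))
  }
  expect_gte(mean(sens), 0.45)
  expect_lte(mean(fpr), 0.05)
})

test_that("degenerate maps binarize to all-inactive", {
  expect_warning(b <- binarize_lfdr(rep(2, 100)), "degenerate")
  expect_false(any(b$active))
  expect_warning(b2 <- binarize_lfdr(c(rep(0, 90), rep(1.5, 10))),
                 "positive magnitudes")
  expect_false(any(b2$active))
  expect_error(binarize_lfdr(rep(1, 10)), "at least 50")
  expect_error(binarize_lfdr(c(-1, rep(1, 99))), "non-negative")
})

test_that("conjunction is the per-voxel proportion of active subjects", {
  one <- c(TRUE, FALSE, TRUE)
  maps <- rep(list(one), 4)
  cj <- conjunction(maps)
  expect_equal(cj$values, c(1, 0, 1))
  # 14 of 28 active at a voxel: exactly 0.5
  B <- matrix(0, 28, 3)
  B[1:14, 2] <- 1
  expect_equal(conjunction(B)$values[2], 0.5)
  expect_equal(conjunction(B)$n_subjects, 28L)
  # values live on the 1/n grid
  set.seed(8)
  Br <- matrix(rbinom(28 * 50, 1, 0.3), 28, 50)
  expect_true(all(conjunction(Br)$values * 28 ==
                    round(conjunction(Br)$values * 28)))
  # Bernoulli(p) maps: grand mean near p
  p <- 0.3
  expect_lt(abs(mean(conjunction(Br)$values) - p),
            3 * sqrt(p * (1 - p) / (28 * 50)))
  expect_error(conjunction(list(c(TRUE, FALSE), c(TRUE, FALSE, TRUE))),
               "length")
})

test_that("signed difference conjunctions subtract pairwise and antisymmetrically", {
  set.seed(9)
  A <- matrix(rbinom(28 * 40, 1, 0.4), 28, 40)
  B <- matrix(rbinom(28 * 40, 1, 0.4), 28, 40)
  expect_equal(diff_conjunction(A, A)$values, rep(0, 40))
  d1 <- diff_conjunction(A, B)
  d2 <- diff_conjunction(B, A)
  expect_identical(d1$values, -d2$values)
  expect_true(all(abs(d1$values) <= 1))
  # a single subject active in a / inactive in b gives value 1
  expect_equal(diff_conjunction(matrix(1, 1, 1), matrix(0, 1, 1))$values, 1)
  expect_error(diff_conjunction(A, B[1:10, ]), "unpaired")
})

test_that("permutation p-values are reproducible, valid and conservative-only", {
  set.seed(10)
  ps <- runif(28, 0.2, 0.6)
  A <- matrix(rbinom(28 * 300, 1, rep(ps, 300)), 28, 300)
  B <- matrix(rbinom(28 * 300, 1, rep(ps, 300)), 28, 300)
  pt1 <- permutation_threshold(A, B, n_iter = 500, q = 0.05, seed = 99)
  pt2 <- permutation_threshold(A, B, n_iter = 500, q = 0.05, seed = 99)
  expect_identical(pt1$p_values, pt2$p_values)
  expect_identical(pt1$mask, pt2$mask)
  # identical conditions: no signal anywhere
  pt0 <- permutation_threshold(A, A, n_iter = 500, q = 0.05, seed = 1)
  expect_equal(sum(pt0$mask), 0L)
  expect_true(all(pt0$p_values == 1))
  # super-uniformity (validity): P(p <= t) <= t + slack at the usual levels
  for (t in c(0.01, 0.05, 0.1, 0.2))
    expect_lte(mean(pt1$p_values <= t), t + 2.5 * sqrt(t * (1 - t) / 300))
  expect_error(permutation_threshold(A, B, n_iter = 50), "at least 100")
})

test_that("null difference maps stay empty under FDR across replicates", {
  empty <- 0L
  for (r in 1:10) {
    set.seed(400 + r)
    ps <- runif(28, 0.2, 0.6)
    A <- matrix(rbinom(28 * 300, 1, rep(ps, 300)), 28, 300)
    B <- matrix(rbinom(28 * 300, 1, rep(ps, 300)), 28, 300)
    pt <- permutation_threshold(A, B, n_iter = 500, q = 0.05, seed = r)
    empty <- empty + (sum(pt$mask) == 0L)
  }
  expect_gte(empty, 9L)
})

test_that("end-to-end conjunctions ignore any single subject's map scale", {
  ss <- fx_space()
  lf <- fx_lf()
  set.seed(16)
  g <- which(ss$compartment_labels == 2)[3]
  models <- enumerate_models(ss, 1)
  feats <- lapply(1:6, function(s) {
    pcd <- numeric(3 * ss$n_generators)
    pcd[3 * (g - 1) + (1:3)] <- rnorm(3, 2, 0.3)
    predict(lf, pcd) + rnorm(60, 0, 0.3)
  })
  fits <- lapply(feats, function(v) bma_solve(v, lf, ss, models = models))
  bins <- lapply(fits, function(f) suppressWarnings(binarize_lfdr(f, 0.2)))
  cj <- conjunction(bins)
  # rescale one subject's inverse map by a large positive constant
  bins2 <- bins
  bins2[[3]] <- suppressWarnings(binarize_lfdr(50 * coef(fits[[3]]), 0.2))
  cj2 <- conjunction(bins2)
  expect_identical(cj$values, cj2$values)
})

test_that("cluster tables summarise suprathreshold voxels per compartment", {
  ss <- fx_space()
  nv <- ss$n_generators
  vals <- numeric(nv)
  idx <- which(ss$compartment_labels == 2)[1:20]
  vals[idx] <- 0.58
  cm <- structure(list(values = vals, n_subjects = 28), class = "conjunction_map")
  tab <- cluster_table(cm, ss, min_value = 0.5)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$cluster_size, 20)
  expect_equal(tab$mean_value, 0.58)
  expect_equal(tab$sd_value, 0)
  # ordering by decreasing cluster size
  vals[which(ss$compartment_labels == 3)[1:5]] <- 0.7
  cm2 <- structure(list(values = vals, n_subjects = 28), class = "conjunction_map")
  tab2 <- cluster_table(cm2, ss, min_value = 0.5)
  expect_equal(tab2$cluster_size, c(20, 5))
  # empty set: empty table
  cm0 <- structure(list(values = numeric(nv), n_subjects = 28),
                   class = "conjunction_map")
  expect_equal(nrow(cluster_table(cm0, ss, 0.5)), 0L)
  # signed maps: two tables split by sign
  dm <- structure(list(values = vals * rep(c(1, -1), length.out = nv),
                       n_subjects = 28, d = NULL),
                  class = "diff_conjunction_map")
  tabs <- cluster_table(dm, ss, 0.5)
  expect_named(tabs, c("A > B", "B > A"))
})
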
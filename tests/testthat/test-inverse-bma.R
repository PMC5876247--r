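test_that("graph Laplacian is SPSD with zero row sums and constant null space", {
  ss <- fx_space()
  L <- graph_laplacian(ss, 1)
  expect_lt(max(abs(rowSums(L))), 1e-12)
  expect_true(isSymmetric(L, check.attributes = FALSE))
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_lt(max(abs(L %*% rep(1, nrow(L)))), 1e-12)
  # a single isolated generator: 1 x 1 zero operator
  ss1 <- source_space(1, 1, seed = 1)
  L1 <- graph_laplacian(ss1, 1)
  expect_equal(dim(L1), c(1L, 1L))
  expect_equal(L1[1, 1], 0)
  expect_error(graph_laplacian(ss, 99), "unknown compartment")
})

test_that("model enumeration counts follow the binomial sums", {
  ss4 <- source_space(60, 4, seed = 1)
  expect_length(enumerate_models(ss4, 1), 4L)
  expect_length(enumerate_models(ss4, 2), 10L)      # C(4,1)+C(4,2)
  ss12 <- source_space(120, 12, seed = 1)
  expect_length(enumerate_models(ss12, 3), 298L)    # 12+66+220
  expect_error(enumerate_models(ss12, 6, cap = 500), "cap")
  # deterministic order: singletons first, lexicographic pairs after
  mods <- enumerate_models(ss4, 2)
  expect_equal(mods[[1]]$compartments, 1L)
  expect_equal(mods[[5]]$compartments, c(1L, 2L))
})

test_that("LORETA solves the regularised normal equations", {
  ss <- fx_space()
  lf <- fx_lf()
  mdl <- compartment_model(ss, c(1, 2))
  set.seed(6)
  v <- rnorm(60)
  alpha <- 0.7; beta <- 12
  sol <- loreta_solve(v, lf, ss, mdl, alpha, beta)
  # v = 0 gives j = 0
  z <- loreta_solve(numeric(60), lf, ss, mdl, alpha, beta)
  expect_equal(max(abs(z$pcd)), 0)
  # algebraic oracle: residual of the normal equations built explicitly
  gi <- mdl$generator_index
  cols <- rep(3 * (gi - 1), each = 3) + 1:3
  K <- lf$matrix[, cols]
  L <- graph_laplacian(ss, c(1, 2))
  LL <- crossprod(L)
  eps <- 1e-8 * max(mean(diag(LL)), 1)
  M <- kronecker(LL + diag(eps, nrow(LL)), diag(3))
  j <- sol$pcd[cols]
  lhs <- beta * crossprod(K, K %*% j) + alpha * M %*% j
  rhs <- beta * crossprod(K, v)
  expect_lt(sqrt(sum((lhs - rhs)^2)), 1e-8 * sqrt(sum(rhs^2)))
  # zero outside the model's support
  expect_equal(max(abs(sol$pcd[-cols])), 0)
})

test_that("a noiseless single-generator source is localised to its neighbourhood", {
  ss <- fx_space()
  lf <- fx_lf()
  gA <- which(ss$compartment_labels == 1)
  mdl <- compartment_model(ss, 1)
  set.seed(12)
  for (r in 1:5) {
    g <- sample(gA, 1)
    pcd <- numeric(3 * ss$n_generators)
    pcd[3 * (g - 1) + (1:3)] <- c(2, 1, -1)
    v <- predict(lf, pcd)
    sol <- loreta_solve(v, lf, ss, mdl, alpha = 1e-4, beta = 1e4)
    top <- which.max(sol$magnitudes)
    A <- ss$neighbor_graph
    nb1 <- which(A[g, ])
    nb2 <- unique(c(g, nb1, which(colSums(A[nb1, , drop = FALSE] * 1) > 0)))
    expect_true(top %in% nb2)   # within graph distance 2 of the truth
  }
})

test_that("log evidence prefers the generating compartment and penalises complexity", {
  ss <- fx_space()
  lf <- fx_lf()
  mA <- compartment_model(ss, 1)
  mB <- compartment_model(ss, 4)
  mAB <- compartment_model(ss, c(1, 4))
  gA <- which(ss$compartment_labels == 1)
  set.seed(11)
  winA <- 0L; occam <- 0L
  n_rep <- 15L
  for (r in seq_len(n_rep)) {
    g <- sample(gA, 1)
    pcd <- numeric(3 * ss$n_generators)
    pcd[3 * (g - 1) + (1:3)] <- rnorm(3, 0, 3)
    v <- predict(lf, pcd) + rnorm(60, 0, 0.05)     # high SNR
    leA <- as.numeric(log_evidence(v, lf, ss, mA))
    leB <- as.numeric(log_evidence(v, lf, ss, mB))
    leAB <- as.numeric(log_evidence(v, lf, ss, mAB))
    winA <- winA + (leA > leB)
    occam <- occam + (leA > leAB)                  # Occam penalty
  }
  expect_gte(winA, n_rep - 1L)
  expect_gt(occam, n_rep / 2)
  # duplicated model: identical evidence, exactly
  le1 <- log_evidence(predict(lf, numeric(3 * ss$n_generators)) + 1, lf, ss, mA)
  le2 <- log_evidence(predict(lf, numeric(3 * ss$n_generators)) + 1, lf, ss, mA)
  expect_identical(as.numeric(le1), as.numeric(le2))
  expect_gt(attr(le1, "alpha"), 0)
  expect_gt(attr(le1, "beta"), 0)
})

test_that("BMA equals the brute-force evidence-weighted average", {
  ss <- fx_space()
  lf <- fx_lf()
  set.seed(13)
  g <- which(ss$compartment_labels == 2)[1]
  pcd <- numeric(3 * ss$n_generators)
  pcd[3 * (g - 1) + (1:3)] <- c(4, -1, 2)
  v <- predict(lf, pcd) + rnorm(60, 0, 0.3)
  fit <- bma_solve(v, lf, ss, max_size = 2, occam_window = 0)  # 21 models, none pruned
  expect_equal(sum(fit$posterior$weight), 1, tolerance = 1e-12)
  oracle <- oracle_bma_average(fit, lf, ss)
  expect_lt(max(abs(fit$magnitudes - oracle)), 1e-10)
})

test_that("Occam pruning brackets the solutions and keeps the best model", {
  ss <- fx_space()
  lf <- fx_lf()
  set.seed(14)
  g <- which(ss$compartment_labels == 3)[2]
  pcd <- numeric(3 * ss$n_generators)
  pcd[3 * (g - 1) + (1:3)] <- c(3, 3, 0)
  v <- predict(lf, pcd) + rnorm(60, 0, 0.3)
  f_all <- bma_solve(v, lf, ss, max_size = 1, occam_window = 0)
  f_mid <- bma_solve(v, lf, ss, max_size = 1, occam_window = 1 / 20)
  f_best <- bma_solve(v, lf, ss, max_size = 1, occam_window = Inf)
  expect_equal(sum(f_all$posterior$retained), 6L)
  expect_equal(sum(f_best$posterior$retained), 1L)
  expect_true(sum(f_mid$posterior$retained) >= 1 &&
                sum(f_mid$posterior$retained) <= 6)
  # best-model-only equals the single-model LORETA solution
  ib <- which.max(f_best$posterior$log_evidence)
  mdl <- f_best$models[[ib]]
  sol <- loreta_solve(v, lf, ss, mdl, mdl$alpha, mdl$beta)
  expect_equal(f_best$magnitudes, sol$magnitudes, tolerance = 1e-10)
  # single-model space: BMA is that model's solution
  f1 <- bma_solve(v, lf, ss, models = list(compartment_model(ss, 3)))
  sol1 <- loreta_solve(v, lf, ss, f1$models[[1]],
                       f1$models[[1]]$alpha, f1$models[[1]]$beta)
  expect_equal(f1$magnitudes, sol1$magnitudes, tolerance = 1e-12)
})

test_that("rescaling the feature rescales the solution (scale covariance)", {
  ss <- fx_space()
  lf <- fx_lf()
  set.seed(3)
  pcd <- numeric(3 * ss$n_generators)
  pcd[31:33] <- c(5, -2, 1)
  v <- predict(lf, pcd) + rnorm(60, 0, 0.5)
  f1 <- bma_solve(v, lf, ss, max_size = 1)
  f3 <- bma_solve(3 * v, lf, ss, max_size = 1)
  expect_lt(max(abs(f3$magnitudes - 3 * f1$magnitudes)) / max(3 * f1$magnitudes),
            1e-6)
  expect_equal(f3$posterior$weight, f1$posterior$weight, tolerance = 1e-8)
  # hyperparameters rescale as precisions of a c-times larger signal
  expect_equal(f3$posterior$beta, f1$posterior$beta / 9, tolerance = 1e-3)
})

test_that("bma_loreta behaves like a fitted model object", {
  ss <- fx_space()
  lf <- fx_lf()
  set.seed(15)
  pcd <- numeric(3 * ss$n_generators)
  pcd[61:63] <- c(2, 2, -1)
  v <- predict(lf, pcd) + rnorm(60, 0, 0.2)
  fit <- bma_solve(v, lf, ss, max_size = 1)
  expect_s3_class(fit, "bma_loreta")
  expect_length(coef(fit), ss$n_generators)
  expect_true(all(coef(fit) >= 0))
  expect_equal(fitted(fit) + residuals(fit), v, tolerance = 1e-12)
  expect_output(print(fit), "BMA-LORETA")
  s <- summary(fit)
  expect_s3_class(s, "summary.bma_loreta")
  expect_output(print(s), "compartment")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  # exports
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_ismap(fit, ss, p1)
  expect_equal(nrow(read.csv(p1)), ss$n_generators)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_model_posterior(fit, p2)
  expect_equal(nrow(read.csv(p2)), nrow(fit$posterior))
})
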
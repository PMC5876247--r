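des_small <- function(...) study_design(n_subjects = 2L, n_trials = 6L,
                                        n_samples = 128L, seed = 9L, ...)

test_that("zero components and zero noise give all-zero epochs", {
  des <- des_small(noise_sd = 0, artifact_prob = 0)
  ep <- simulate_epochs(des, list(), head_model(n_terms = 40), montage(),
                        fx_space(), lf = fx_lf())
  expect_equal(max(abs(ep$data)), 0)
})

test_that("epoch simulation is deterministic for a fixed seed", {
  des <- des_small()
  comps <- default_components(rep(1, 6))
  args <- list(des, comps, head_model(n_terms = 40), montage(), fx_space(),
               lf = fx_lf())
  ep1 <- do.call(simulate_epochs, args)
  ep2 <- do.call(simulate_epochs, args)
  expect_identical(ep1$data, ep2$data)
})

test_that("a mismatch-only component matches its lead-field projection", {
  ss <- fx_space()
  lf <- fx_lf()
  # plant in the best-coupled compartment (the one under the vertex)
  comp <- ss$compartment_labels[which.max(ss$positions[, 3])]
  cs <- component_spec("N400", 385, 45, c(0, 5, 0, 0), compartment = comp,
                       polarity = -1)
  des <- study_design(n_subjects = 2L, n_trials = 6L, n_samples = 256L,
                      seed = 9L, noise_sd = 0, artifact_prob = 0)
  ep <- simulate_epochs(des, list(cs), head_model(n_terms = 40), montage(),
                        ss, lf = lf)
  dd <- apply(ep$data[1, 2, , , ], c(2, 3), mean) -
        apply(ep$data[1, 1, , , ], c(2, 3), mean)
  # nothing before the component's support, a clear deflection after 300 ms
  expect_lt(max(abs(dd[, ep$times < 100])), 1e-6)
  expect_gt(max(abs(dd[, ep$times >= 300])), 10 * max(abs(dd[, ep$times < 100])))
  # oracle: direct projection of the planted Gaussian through the lead field
  cent <- compartment_centroids(ss, comp)[1, ]
  g <- which.min(rowSums((ss$positions - matrix(cent, ss$n_generators, 3,
                                                byrow = TRUE))^2))
  pat <- unname(drop(lf$matrix[, 3 * (g - 1) + (1:3)] %*%
                       (cent / sqrt(sum(cent^2)))))
  tc <- -exp(-0.5 * ((ep$times - 385) / 45)^2)
  expected <- 5 * outer(pat, tc)
  i <- which.max(abs(pat)); j <- which.min(abs(ep$times - 385))
  ratio <- dd[i, j] / expected[i, j]      # the subject's amplitude gain
  expect_equal(dd, ratio * expected, tolerance = 1e-8)
  expect_gt(ratio, 0.1)                    # gain = 1 + N(0, 0.2), floored
})

test_that("trials exceeding the voltage threshold are rejected", {
  des <- des_small(noise_sd = 1, artifact_prob = 0)
  ep <- simulate_epochs(des, list(), head_model(n_terms = 40), montage(),
                        fx_space(), lf = fx_lf())
  ep$data[1, 1, 3, 5, 10] <- 150  # one +150 uV spike
  av <- reject_and_average(ep, threshold = 100, min_kept = 1L,
                           equalize = FALSE)
  expect_equal(av$kept[1, 1], 5L)
  expect_equal(av$kept[1, 2], 6L)
  # equalisation matches the minimum surviving count, per subject
  av2 <- reject_and_average(ep, threshold = 100, min_kept = 1L,
                            equalize = TRUE)
  expect_true(all(av2$kept[1, ] == 5L))
  expect_true(all(av2$kept[2, ] == 6L))
})

test_that("averaging equals the detrended, baseline-corrected trial mean", {
  des <- des_small(noise_sd = 2, artifact_prob = 0)
  ep <- simulate_epochs(des, list(), head_model(n_terms = 40), montage(),
                        fx_space(), lf = fx_lf())
  av <- reject_and_average(ep, threshold = 1e6, min_kept = 1L)
  expect_true(all(av$kept == 6L))
  # independent reimplementation: lm() detrend per channel + baseline mean
  raw <- apply(ep$data[2, 3, , , ], c(2, 3), mean)
  x <- seq_along(ep$times)
  manual <- t(apply(raw, 1, function(y) stats::lm(y ~ x)$residuals))
  manual <- manual - rowMeans(manual[, ep$times < 0])
  expect_equal(av$data[2, 3, , ], manual, tolerance = 1e-10,
               ignore_attr = TRUE)
  bl <- av$times < 0
  expect_lt(max(abs(rowMeans(av$data[2, 3, , bl]))), 1e-9)
})

test_that("average noise variance shrinks as sigma^2/n", {
  # Monte-Carlo oracle: with white sensor noise of sd 5 uV and 10 kept
  # trials, the averaged sample variance is close to 25/10
  des <- study_design(n_subjects = 1L, n_trials = 10L, n_samples = 64L,
                      noise_sd = 5, noise_spatial_corr = 1e-6,
                      artifact_prob = 0, seed = 1L)
  set.seed(77)
  vals <- replicate(200, {
    des$seed <- sample.int(1e6, 1)
    ep <- simulate_epochs(des, list(), head_model(n_terms = 30), montage(),
                          fx_space(), lf = fx_lf())
    av <- reject_and_average(ep, threshold = 1e6, min_kept = 1L)
    av$data[1, 1, 7, 60]        # a post-stimulus sample
  })
  expect_equal(var(vals), 25 / 10, tolerance = 0.2)
})

test_that("unknown compartment labels are rejected", {
  cs <- component_spec("X", 200, 20, 1, compartment = 99)
  expect_error(simulate_epochs(des_small(), list(cs), head_model(n_terms = 40),
                               montage(), fx_space(), lf = fx_lf()),
               "unknown compartment")
})

test_that("reject_and_average errors when too few trials survive", {
  des <- des_small(noise_sd = 0, artifact_prob = 0)
  ep <- simulate_epochs(des, list(), head_model(n_terms = 40), montage(),
                        fx_space(), lf = fx_lf())
  ep$data[1, 4, , 1, 1] <- 500
  expect_error(reject_and_average(ep, threshold = 100, min_kept = 2L),
               "subject 1, condition cross.mismatch")
})

test_that("the paper_like preset has the full study geometry", {
  st <- fx_study()
  expect_equal(dim(st$erps$data), c(28L, 4L, 60L, 256L))
  expect_equal(st$erps$times[1], -200)
  expect_equal(st$erps$times[2] - st$erps$times[1], 4)
  expect_true(all(st$epochs_kept >= 24))
  expect_equal(nrow(st$ground_truth$planted), 6L)
  # distinct task-specific N400 compartments
  n400 <- st$ground_truth$planted$compartment[st$ground_truth$planted$name == "N400"]
  expect_length(unique(n400), 2L)
  # baseline property on every channel
  bl <- st$erps$times < 0
  expect_lt(max(abs(apply(st$erps$data[, , , bl], 1:3, mean))), 1e-9)
})

test_that("study generation is reproducible and the null preset is flat", {
  a <- generate_study("small", seed = 11)
  b <- generate_study("small", seed = 11)
  expect_identical(a$erps$data, b$erps$data)
  expect_identical(a$ground_truth$planted, b$ground_truth$planted)
  nul <- fx_null_study(21)
  expect_null(nul$ground_truth$planted)
  # condition means are equal in expectation: grand condition differences
  # are pure averaged noise, far below the planted-effect scale
  gm <- apply(nul$erps$data, 2, mean)
  expect_lt(max(abs(gm - mean(gm))), 0.2)
})

test_that("planted mismatch sign is recovered at the best-coupled channel", {
  # sensor-level recovery: grand-average mismatch-match difference in the
  # 330-440 ms window has the planted (negative) sign at the channel most
  # strongly coupled to the planted source, across seeds
  hits <- 0L
  n_seeds <- 8L
  for (s in seq_len(n_seeds)) {
    st <- generate_study("paper_like", seed = 100 + s, n_subjects = 8L,
                         n_trials = 12L, artifact_prob = 0)
    gt <- st$ground_truth
    comp <- gt$planted$compartment[5]         # intra-task N400
    cent <- compartment_centroids(gt$space, comp)[1, ]
    g <- which.min(rowSums((gt$space$positions -
                              matrix(cent, gt$space$n_generators, 3, byrow = TRUE))^2))
    pat <- drop(gt$lead_field$matrix[, 3 * (g - 1) + (1:3)] %*%
                  (cent / sqrt(sum(cent^2))))
    ch <- which.max(abs(pat))
    w <- st$erps$times >= 330 & st$erps$times <= 440
    d <- mean(st$erps$data[, 2, ch, w]) - mean(st$erps$data[, 1, ch, w])
    planted_sign <- -sign(pat[ch])  # negative-polarity component
    hits <- hits + (sign(d) == planted_sign)
  }
  expect_gte(hits, n_seeds)
})
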
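# Records with targets that are explicit functions of the inputs, for
# oracle-style surrogate checks.
linear_records <- function(n, seed = 1) {
  occ <- sample_population(n, seed = seed)
  u <- with_seed(seed + 1, lhs::randomLHS(n, 7))
  d <- unit_to_design(u)
  st <- standardize_covariates(occ, covariate_box())
  data.frame(occ, d,
             hic15 = 600 + 80 * st[, "bmi"] + 50 * st[, "stature"] +
               120 * u[, 5] - 60 * u[, 6],
             chest_d_mm = 30 + 5 * st[, "bmi"] + 8 * u[, 1] - 4 * u[, 5],
             femur_f_kn = 4 + 0.8 * st[, "bmi"] + 1.5 * u[, 7])
}

test_that("the GP reproduces a noiseless linear response out of sample", {
  rec <- linear_records(50, seed = 2)
  fit <- fit_gp(rec, seed = 1, restarts = 2, log_hic = FALSE)
  test <- linear_records(40, seed = 77)
  pred <- predict_ucb(fit, test, as_design_matrix(test), level = 0.5)
  for (m in measure_names()) {
    rel <- abs(pred[[m]] - test[[m]]) / abs(test[[m]])
    expect_lt(max(rel), 0.01)
  }
})

test_that("a constant target is fitted as a constant with a noise floor", {
  rec <- linear_records(30, seed = 3)
  rec$chest_d_mm <- 42
  fit <- fit_gp(rec, seed = 1, restarts = 1)
  expect_true(fit$models$chest_d_mm$constant)
  test <- linear_records(10, seed = 4)
  pred <- predict_ucb(fit, test, as_design_matrix(test), level = 0.5)
  expect_equal(pred$chest_d_mm, rep(42, 10), tolerance = 1e-8)
})

test_that("duplicating the training set leaves predictions unchanged", {
  rec <- linear_records(40, seed = 5)
  fit1 <- fit_gp(rec, seed = 1, restarts = 1, log_hic = FALSE)
  fit2 <- fit_gp(rbind(rec, rec), seed = 1, restarts = 1, log_hic = FALSE)
  test <- linear_records(15, seed = 6)
  p1 <- predict_ucb(fit1, test, as_design_matrix(test), level = 0.5)
  p2 <- predict_ucb(fit2, test, as_design_matrix(test), level = 0.5)
  for (m in measure_names())
    expect_equal(p2[[m]], p1[[m]], tolerance = 0.02)
})

test_that("posterior algebra matches an independent dense-solve oracle", {
  fit <- small_surrogate()
  g <- fit$models$femur_f_kn
  Xn <- fit$Xs[1:5, , drop = FALSE] + 0.3
  post <- .gp_posterior(g, fit$Xs, Xn)
  # reconstruct the standardized training target from alpha: y = K alpha
  K <- .se_kernel(fit$Xs, fit$Xs, g$ell, g$sf2) +
    diag(g$sn2 + 1e-6, nrow(fit$Xs))
  ystd <- as.vector(K %*% g$alpha)
  oracle <- naive_gp_posterior(fit$Xs, ystd, Xn, g$ell, g$sf2, g$sn2)
  expect_equal(post$mean, oracle$mean, tolerance = 1e-6)
  expect_equal(post$sd, oracle$sd, tolerance = 1e-4)
})

test_that("posterior mean agrees with an independent GP implementation", {
  skip_if_not_installed("kernlab")
  set.seed(10)
  n <- 40
  X <- matrix(runif(n * 3), n, 3)
  y <- sin(3 * X[, 1]) + X[, 2]^2 - X[, 3]
  Xte <- matrix(runif(8 * 3), 8, 3)
  sg <- 0.8; vr <- 0.01
  ref <- as.vector(kernlab::predict(
    kernlab::gausspr(X, y, kernel = "rbfdot", kpar = list(sigma = sg),
                     var = vr, scaled = FALSE), Xte))
  ell <- rep(1 / sqrt(2 * sg), 3)
  L <- chol(.se_kernel(X, X, ell, 1) + diag(vr + 1e-6, n))
  g <- list(constant = FALSE, ell = ell, sf2 = 1, sn2 = vr, L = L,
            alpha = backsolve(L, forwardsolve(t(L), y)))
  ours <- .gp_posterior(g, X, Xte)
  expect_equal(ours$mean, ref, tolerance = 1e-4)
})

test_that("UCB semantics: median equals mean, bound exceeds mean, prior far out", {
  fit <- small_surrogate()
  test <- sample_population(20, seed = 41)
  d <- unit_to_design(with_seed(42, matrix(runif(20 * 7), 20, 7)))
  mu <- predict_ucb(fit, test, d, level = 0.5)
  med <- predict_ucb(fit, test, d, level = 0.5, what = "mean")
  expect_equal(mu, med)
  ucb <- predict_ucb(fit, test, d, level = 0.95)
  expect_true(all(ucb >= med))
  expect_error(predict_ucb(fit, test, d, level = 1), "level")
  # far from all data the posterior reverts to the prior spread
  g <- fit$models$chest_d_mm
  far <- matrix(500, 2, 10)
  post <- .gp_posterior(g, fit$Xs, far)
  expect_equal(post$sd, rep(sqrt(g$sf2), 2), tolerance = 1e-3)
})

test_that("posterior sd at a training input is below the noise level", {
  fit <- small_surrogate()
  g <- fit$models$femur_f_kn
  post <- .gp_posterior(g, fit$Xs, fit$Xs[1:20, , drop = FALSE])
  expect_true(all(post$sd <= sqrt(g$sn2 + 1e-6) + 1e-9))
})

test_that("predictions are invariant to record ordering", {
  rec <- small_dataset()
  perm <- with_seed(50, sample(nrow(rec)))
  fit1 <- small_surrogate()
  fit2 <- fit_gp(rec[perm, ], seed = 1, restarts = 2)
  test <- sample_population(15, seed = 51)
  d <- unit_to_design(with_seed(52, matrix(runif(15 * 7), 15, 7)))
  p1 <- predict_ucb(fit1, test, d)
  p2 <- predict_ucb(fit2, test, d)
  for (m in measure_names())
    expect_equal(p2[[m]], p1[[m]], tolerance = 1e-3)
})

test_that("cross-validation partitions the data and scores accurately", {
  rec <- small_dataset()[1:80, ]
  cv <- cross_validate(rec, k = 5, seed = 2, restarts = 1)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_length(cv$folds, 80)
  expect_true(all(cv$r2 <= 1))
  expect_true(all(cv$r2 > 0.9))
  # R^2 definition: perfect predictions give 1, mean predictions give 0
  truth <- rec$femur_f_kn
  expect_equal(1 - sum((truth - truth)^2) / sum((truth - mean(truth))^2), 1)
  expect_equal(1 - sum((truth - mean(truth))^2) /
                 sum((truth - mean(truth))^2), 0)
  expect_error(cross_validate(rec, k = 81), "folds")
})

test_that("95% UCB covers most held-out noiseless responses under noise", {
  cfg <- simulator_config(noise_sd = 0.05)
  doe <- scale_design(generate_maxpro_design(150, 10, seed = 61,
                                             iterations = 3000))
  rec <- generate_dataset(doe, cfg, noisy = TRUE, seed = 62)
  fit <- fit_gp(rec, seed = 1, restarts = 2)
  test_doe <- scale_design(with_seed(63, lhs::randomLHS(200, 10)))
  truth <- simulate_measures(test_doe, as_design_matrix(test_doe), cfg,
                             noisy = FALSE)
  ucb <- predict_ucb(fit, test_doe, as_design_matrix(test_doe), level = 0.95)
  for (m in measure_names()) {
    coverage <- mean(ucb[[m]] >= truth[[m]])
    expect_gte(coverage, 0.80)
  }
})

test_that("surrogates persist to JSON and reload with identical predictions", {
  fit <- small_surrogate()
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(fit, path)
  back <- read_surrogate(path)
  test <- sample_population(10, seed = 71)
  d <- unit_to_design(with_seed(72, matrix(runif(10 * 7), 10, 7)))
  expect_equal(predict_ucb(back, test, d), predict_ucb(fit, test, d),
               tolerance = 1e-5)
})

test_that("fitting requires enough records", {
  expect_error(fit_gp(small_dataset()[1:5, ]), "at least 10")
})
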
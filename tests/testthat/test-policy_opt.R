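test_that("policy features de-duplicate sex powers and order by degree", {
  expect_equal(policy_feature_names(1), "(Intercept)")
  expect_equal(policy_feature_names(2),
               c("(Intercept)", "sex", "stature", "bmi"))
  fn3 <- policy_feature_names(3)
  expect_equal(sum(fn3 == "sex"), 1)      # sex^2 = 1 collapses
  expect_true(all(c("stature^2", "bmi^2") %in% fn3))
  st <- standardize_covariates(sample_population(10, seed = 1),
                               covariate_box())
  phi <- policy_features(st, 3)
  expect_equal(qr(phi)$rank, ncol(phi))   # identifiable feature matrix
})

test_that("policy evaluation is the documented affine-composed raw map", {
  box <- covariate_box()
  # raw output on one variable: 0.2 + 0.5 * standardized bmi, identity squash
  coef <- matrix(0, 7, 4)
  coef[5, 1] <- 0.2; coef[5, 4] <- 0.5
  pol <- design_policy(coef, m = 2, box = box, squash = "identity")
  bmi <- box$male$bmi[1] + 0.8 * diff(box$male$bmi)   # standardized 0.6
  occ <- data.frame(sex = "male", stature_cm = 170, bmi = bmi)
  u <- evaluate_policy(pol, occ, unit = TRUE)
  expect_equal(u[1, "f_ll"], 0.2 + 0.5 * 0.6)
  expect_equal(u[1, "d0_ll"], 0)
  # full-path consistency against a manual forward computation
  coef2 <- matrix(with_seed(2, rnorm(28, 0, 0.5)), 7, 4)
  pol2 <- design_policy(coef2, m = 2, box = box)
  pop <- sample_population(25, seed = 3)
  st <- standardize_covariates(pop, box)
  manual <- 1 / (1 + exp(-(cbind(1, st[, "sex"], st[, "stature"], st[, "bmi"]) %*%
                             t(coef2))))
  expect_equal(evaluate_policy(pol2, pop, unit = TRUE), manual,
               ignore_attr = TRUE)
})

test_that("an order-1 policy is constant and squashing keeps designs feasible", {
  pol <- design_policy(matrix(with_seed(4, rnorm(7, 0, 3)), 7, 1), m = 1)
  pop <- sample_population(50, seed = 5)
  d <- evaluate_policy(pol, pop)
  expect_equal(apply(d, 2, stats::sd), rep(0, 7), ignore_attr = TRUE)
  # raw outputs far outside the box still land strictly inside it
  big <- design_policy(matrix(3, 7, 4), m = 2)
  u <- evaluate_policy(big, pop, unit = TRUE)
  expect_true(all(u > 0 & u < 1))
  b <- design_box()
  dphys <- evaluate_policy(big, pop)
  expect_true(all(sweep(dphys, 2, b[, 1], ">") &
                    sweep(dphys, 2, b[, 2], "<")))
})

test_that("constant_policy reproduces its wrapped design", {
  d <- unit_to_design(matrix(c(0.1, 0.33, 0.5, 0.66, 0.9, 0.25, 0.75), 1, 7))
  pol <- constant_policy(d)
  got <- evaluate_policy(pol, sample_population(5, seed = 6))
  for (i in 1:5) expect_equal(got[i, ], d[1, ], tolerance = 1e-6)
})

test_that("policies persist to JSON and reload exactly", {
  coef <- matrix(with_seed(7, rnorm(7 * 6, 0, 1)), 7, 6)
  pol <- design_policy(coef, m = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_policy(pol, path)
  back <- read_policy(path)
  pop <- sample_population(10, seed = 8)
  expect_equal(evaluate_policy(back, pop), evaluate_policy(pol, pop),
               tolerance = 1e-12)
})

test_that("population objective equals an independent per-occupant summation", {
  cfg <- default_config()
  spec <- objective_spec(truth_predictor(cfg),
                         sample = sample_population(40, seed = 9))
  pol <- design_policy(matrix(with_seed(10, rnorm(28, 0, 0.4)), 7, 4), m = 2)
  got <- population_objective(pol, spec)
  # brute force: loop occupants, simulate, map to risks, average
  acc <- 0
  for (i in seq_len(40)) {
    occ_i <- spec$sample[i, , drop = FALSE]
    d_i <- evaluate_policy(pol, occ_i)
    y_i <- simulate_measures(occ_i, d_i, cfg, noisy = FALSE)
    acc <- acc + risk_from_measures(occ_i, y_i)$p_joint
  }
  expect_equal(got, acc / 40, tolerance = 1e-12)
  # constant design: same integrand at a fixed design
  d0 <- unit_to_design(matrix(0.4, 1, 7))
  y0 <- simulate_measures(spec$sample, d0, cfg, noisy = FALSE)
  expect_equal(population_objective(d0[1, ], spec),
               mean(risk_from_measures(spec$sample, y0)$p_joint),
               tolerance = 1e-12)
})

test_that("a flat response surface gives the same objective for any policy", {
  cfg <- simulator_config(bmi_slope = rep(0, 3), stature_slope = rep(0, 3),
                          female_offset = rep(0, 3),
                          bowl_weights = matrix(0, 3, 7))
  spec <- objective_spec(truth_predictor(cfg),
                         sample = sample_population(30, seed = 11),
                         scaling = scaling_model(
                           chest_coef = c(intercept = 230, bmi = 0, stature = 0, female = 0),
                           femur_coef = c(intercept = 600, bmi = 0, stature = 0, female = 0)))
  c0 <- population_objective(unit_to_design(matrix(0.5, 1, 7))[1, ], spec)
  for (s in 1:3) {
    pol <- design_policy(matrix(with_seed(s, rnorm(28)), 7, 4), m = 2)
    expect_equal(population_objective(pol, spec), c0, tolerance = 1e-12)
  }
})

test_that("analytic policy gradients match numerical differentiation", {
  sample <- sample_population(15, seed = 12)
  # nb: the GP forward pass carries ~1e-9 float noise through its triangular
  # solves, so its finite-difference step must be large enough to beat
  # cancellation, with a correspondingly looser comparison
  check_grad <- function(predictor, eps, tol) {
    spec <- objective_spec(predictor, sample = sample)
    st <- standardize_covariates(spec$sample, spec$box)
    phi <- policy_features(st, 2)
    template <- matrix(0, 7, 4, dimnames = list(design_names(),
                                                policy_feature_names(2)))
    mask <- matrix(TRUE, 7, 4)
    theta <- with_seed(13, rnorm(28, 0, 0.3))
    fg <- .policy_fg(theta, template, mask, spec, phi, "logistic")
    idx <- c(1, 5, 12, 19, 26)
    for (j in idx) {
      up <- theta; up[j] <- up[j] + eps
      dn <- theta; dn[j] <- dn[j] - eps
      num <- (.policy_fg(up, template, mask, spec, phi, "logistic")$value -
                .policy_fg(dn, template, mask, spec, phi, "logistic")$value) /
        (2 * eps)
      expect_equal(fg$gradient[j], num, tolerance = tol)
    }
  }
  check_grad(truth_predictor(default_config()), eps = 1e-5, tol = 1e-6)
  check_grad(small_surrogate(), eps = 2e-2, tol = 1e-2)
})

test_that("midsize-mode optimisation recovers the reference occupant optimum", {
  cfg <- default_config()
  spec <- objective_spec(truth_predictor(cfg),
                         sample = sample_population(8, seed = 14))
  d <- optimize_constant(spec, "midsize_male", seed = 1, steps = 2500,
                         restarts = 2)
  u <- design_to_unit(as_design_matrix(d))[1, ]
  u_star <- true_optimal_design(midsize_male_reference(), cfg, unit = TRUE)[1, ]
  expect_true(all(abs(u - u_star) < 0.05))
})

test_that("population optimum of a symmetric pair is the per-variable midpoint", {
  a <- matrix(0, 7, 3)
  a[, 1] <- c(0.1, -0.08, 0.12, 0, 0.15, -0.12, 0.05)  # sex-only optima
  cfg <- simulator_config(bmi_slope = rep(0, 3), stature_slope = rep(0, 3),
                          female_offset = rep(0, 3), opt_slopes = a)
  box <- covariate_box()
  pair <- data.frame(sex = c("male", "female"),
                     stature_cm = c(mean(box$male$stature), mean(box$female$stature)),
                     bmi = c(mean(box$male$bmi), mean(box$female$bmi)))
  neutral <- scaling_model(
    chest_coef = c(intercept = 230, bmi = 0, stature = 0, female = 0),
    femur_coef = c(intercept = 600, bmi = 0, stature = 0, female = 0))
  spec <- objective_spec(truth_predictor(cfg), sample = pair,
                         scaling = neutral)
  d <- optimize_constant(spec, "population", seed = 1, steps = 2500,
                         restarts = 2)
  u <- design_to_unit(as_design_matrix(d))[1, ]
  expect_true(all(abs(u - 0.5) < 0.02))
})

test_that("optimizer honours nesting, warm starts and a monotone trace", {
  cfg <- default_config()
  spec <- objective_spec(truth_predictor(cfg),
                         sample = sample_population(64, seed = 15,
                                                    scheme = "space-filling"))
  d_pop <- optimize_constant(spec, "population", seed = 1, steps = 1200,
                             restarts = 1)
  obj1 <- attr(d_pop, "objective")
  pol2 <- optimize_policy(spec, m = 2, seed = 1, steps = 800, restarts = 1,
                          init_design = d_pop)
  obj2 <- attr(pol2, "objective")
  expect_lte(obj2, obj1 + 1e-6)                     # nested model classes
  expect_lte(obj2, population_objective(d_pop, spec) + 1e-6)
  tr <- attr(pol2, "trace")
  expect_true(all(diff(tr) <= 0))                   # accepted trace monotone
  expect_equal(obj2, population_objective(pol2, spec), tolerance = 1e-12)
})

test_that("constant-mode and order-1 policy optimisation agree", {
  cfg <- default_config()
  spec <- objective_spec(truth_predictor(cfg),
                         sample = sample_population(32, seed = 16))
  d <- optimize_constant(spec, "population", seed = 3, steps = 600,
                         restarts = 1)
  pol1 <- optimize_policy(spec, m = 1, seed = 3, steps = 600, restarts = 1)
  expect_equal(attr(d, "objective"), attr(pol1, "objective"),
               tolerance = 1e-10)
})

test_that("sensitivity masking freezes the non-adaptive variables", {
  cfg <- default_config()
  spec <- objective_spec(truth_predictor(cfg),
                         sample = sample_population(32, seed = 17))
  d0 <- unit_to_design(matrix(0.5, 1, 7))[1, ]
  pol <- optimize_policy(spec, m = 2, seed = 1, steps = 300, restarts = 1,
                         init_design = d0, free_vars = "f_ll")
  u <- evaluate_policy(pol, sample_population(20, seed = 18), unit = TRUE)
  fixed <- setdiff(design_names(), "f_ll")
  expect_equal(apply(u[, fixed], 2, stats::sd), rep(0, 6), ignore_attr = TRUE)
  expect_equal(u[1, fixed], rep(0.5, 6), tolerance = 1e-9, ignore_attr = TRUE)
  expect_gt(stats::sd(u[, "f_ll"]), 0)
  expect_error(optimize_policy(spec, free_vars = "f_ll"), "init_design")
})
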
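# Population objective and gradient-based policy optimization.

#' Ground-truth measure predictor
#'
#' Wraps a [simulator_config()] as a measure predictor for
#' [objective_spec()], serving the noiseless synthetic response itself
#' instead of a surrogate. Used for oracle checks of policy recovery where
#' the true response surface is known.
#'
#' @param config a [simulator_config()].
#' @return object of class `truth_predictor`.
#' @export
truth_predictor <- function(config = simulator_config()) {
  structure(list(config = config), class = "truth_predictor")
}

# Unified predictor interface: natural-scale measures (n x 3) at occupants x
# unit designs, optionally with gradients wrt the unit design (n x 7 x 3).
#' @keywords internal
predict_measures_grad <- function(predictor, occupants, d_unit, level,
                                  need_grad = FALSE) {
  if (inherits(predictor, "injury_surrogate")) {
    pr <- .surrogate_predict(predictor, occupants, d_unit, level, need_grad)
    list(measures = pr$ucb, grad = pr$grad)
  } else if (inherits(predictor, "truth_predictor")) {
    cfg <- predictor$config
    list(measures = .noiseless_measures(occupants, d_unit, cfg),
         grad = if (need_grad) .noiseless_measures_grad(occupants, d_unit, cfg))
  } else stop("unsupported predictor", call. = FALSE)
}

#' Population objective specification
#'
#' Bundles everything needed to evaluate the Monte-Carlo population risk of a
#' design or policy: the measure predictor (a fitted [fit_gp()] surrogate
#' queried at its upper confidence bound, or a [truth_predictor()]), the
#' Monte-Carlo occupant sample standing in for the population integral
#' (occupants carry equal weight, i.e. a constant population density), and
#' the injury-risk model.
#'
#' @param predictor `injury_surrogate` or `truth_predictor`.
#' @param sample occupant data.frame (the Monte-Carlo sample); by default a
#'   512-point space-filling sample over `box`.
#' @param box occupant [covariate_box()].
#' @param scaling a [scaling_model()].
#' @param level one-sided UCB level for surrogate predictions.
#' @param params risk-curve coefficients, see [risk_params()].
#' @param seed seed for the default sample.
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(predictor, sample = NULL, box = covariate_box(),
                           scaling = scaling_model(), level = 0.95,
                           params = risk_params(), seed = 99L) {
  if (is.null(sample))
    sample <- sample_population(512, box, seed = seed, scheme = "space-filling")
  if (nrow(sample) < 1L) stop("empty Monte-Carlo sample", call. = FALSE)
  structure(list(predictor = predictor, sample = as_occupants(sample),
                 box = box, scaling = scaling, level = level, params = params),
            class = "objective_spec")
}

# Forward risk evaluation for a sample/unit-design pairing; optionally the
# gradient of mean p_joint wrt the unit designs (n x 7).
#' @keywords internal
.population_forward <- function(spec, occupants, d_unit, need_grad = FALSE) {
  pm <- predict_measures_grad(spec$predictor, occupants, d_unit, spec$level,
                              need_grad)
  scales <- anthropometric_scale(occupants, spec$scaling)
  rk <- .risk_with_grad(pm$measures, scales, spec$params)
  out <- list(p_joint = rk$p_joint, p = rk$p, measures = pm$measures)
  if (need_grad) {
    n <- nrow(d_unit)
    g <- matrix(0, n, 7)
    for (m in 1:3) g <- g + rk$djoint_dm[, m] * pm$grad[, , m]
    out$grad_d <- g
  }
  out
}

#' Population injury risk of a design or policy
#'
#' The Monte-Carlo population objective: the mean joint injury probability
#' over the specification's occupant sample, with injury measures predicted
#' at each occupant's assigned design (the policy output, or a fixed design
#' for every occupant).
#'
#' @param x a [design_policy()], or a length-7 design vector / 1-row design
#'   data.frame in physical units.
#' @param spec an [objective_spec()].
#' @return scalar mean joint injury risk.
#' @export
population_objective <- function(x, spec) {
  mean(population_risks(x, spec)$p_joint)
}

#' @rdname population_objective
#' @return `population_risks` returns the per-occupant risk data.frame
#'   (`p_head`, `p_chest`, `p_lower_ext`, `p_joint`).
#' @export
population_risks <- function(x, spec) {
  stopifnot(inherits(spec, "objective_spec"))
  occ <- spec$sample
  if (inherits(x, "design_policy")) {
    d_unit <- evaluate_policy(x, occ, unit = TRUE)
  } else {
    d <- as_design_matrix(x)
    d_unit <- design_to_unit(d)[rep(1L, nrow(occ)), , drop = FALSE]
  }
  fw <- .population_forward(spec, occ, d_unit)
  data.frame(p_head = fw$p[, 1], p_chest = fw$p[, 2], p_lower_ext = fw$p[, 3],
             p_joint = fw$p_joint)
}

# Adam optimizer on a flat parameter vector. fg(par) must return
# list(value, gradient). Tracks and returns the best parameters visited; the
# trace records the best objective after each step (non-increasing).
#' @keywords internal
.adam <- function(par, fg, lr = 0.001, steps = 2000L,
                  beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- v <- numeric(length(par))
  best_par <- par
  ev <- fg(par)
  if (!is.finite(ev$value)) stop("non-finite objective at start", call. = FALSE)
  best_val <- ev$value
  trace <- numeric(steps)
  for (t in seq_len(steps)) {
    g <- ev$gradient
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    par <- par - lr * mh / (sqrt(vh) + eps)
    ev <- fg(par)
    if (!is.finite(ev$value)) stop("non-finite objective", call. = FALSE)
    if (ev$value < best_val) { best_val <- ev$value; best_par <- par }
    trace[t] <- best_val
  }
  list(par = best_par, value = best_val, trace = trace)
}

# Objective/gradient over policy coefficients (7 x F, masked), with
# precomputed features and scales.
#' @keywords internal
.policy_fg <- function(theta_free, template, mask, spec, phi, squash) {
  coef <- template
  coef[mask] <- theta_free
  raw <- phi %*% t(coef)
  u <- apply_squash(raw, squash)
  fw <- .population_forward(spec, spec$sample, u, need_grad = TRUE)
  dR <- fw$grad_d * squash_deriv(raw, squash)      # n x 7
  gcoef <- (t(dR) %*% phi) / nrow(phi)             # 7 x F
  list(value = mean(fw$p_joint), gradient = gcoef[mask])
}

#' Optimize an adaptive design policy
#'
#' Searches for the polynomial design policy minimising the population
#' objective by a first-order adaptive-moment (Adam) gradient method with
#' analytic gradients, full-batch over the Monte-Carlo sample, from several
#' seeded starts; the best solution over all starts is returned and the
#' returned objective never exceeds any start's initial objective.
#'
#' The default learning rate of 0.001 follows standard practice for
#' adaptive-moment optimizers on smooth objectives of this scale.
#'
#' @param spec an [objective_spec()].
#' @param m polynomial order (1 = constant, 2 = linear, ...).
#' @param seed integer seed for the start points.
#' @param lr learning rate.
#' @param steps Adam steps per start.
#' @param restarts number of starts.
#' @param init_design optional length-7 design (physical units) used to warm
#'   start the intercept of the first start.
#' @param free_vars optional character vector of design variables allowed to
#'   vary; the others are held constant at `init_design` (which is then
#'   required). Used for per-variable sensitivity analysis.
#' @param squash squashing function, see [design_policy()].
#' @return a [design_policy()] with attributes `objective` (best value) and
#'   `trace` (best-so-far objective after each accepted step).
#' @export
optimize_policy <- function(spec, m = 2L, seed = 1L, lr = 0.001,
                            steps = 2000L, restarts = 3L, init_design = NULL,
                            free_vars = NULL, squash = "logistic") {
  stopifnot(inherits(spec, "objective_spec"), m >= 1)
  fn <- policy_feature_names(m)
  nf <- length(fn)
  dn <- design_names()
  st <- standardize_covariates(spec$sample, spec$box)
  phi <- policy_features(st, m)

  template <- matrix(0, 7, nf, dimnames = list(dn, fn))
  if (!is.null(init_design) || !is.null(free_vars)) {
    if (is.null(init_design) && !is.null(free_vars))
      stop("free_vars requires init_design for the held-fixed variables",
           call. = FALSE)
    u0 <- pmin(pmax(design_to_unit(as_design_matrix(init_design))[1, ],
                    1e-4), 1 - 1e-4)
    template[, 1] <- if (squash == "logistic") logit(u0) else u0
  }
  mask <- matrix(TRUE, 7, nf, dimnames = list(dn, fn))
  if (!is.null(free_vars)) {
    if (!all(free_vars %in% dn)) stop("unknown design variable", call. = FALSE)
    mask[!(dn %in% free_vars), ] <- FALSE
  }

  seeds <- child_seeds(seed, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    start <- template
    if (r > 1L || is.null(init_design))
      start <- start + with_seed(seeds[r], matrix(stats::rnorm(7 * nf, 0, 0.3), 7, nf))
    res <- .adam(start[mask],
                 function(th) .policy_fg(th, template, mask, spec, phi, squash),
                 lr = lr, steps = steps)
    if (is.null(best) || res$value < best$value) best <- res
  }
  coef <- template
  coef[mask] <- best$par
  out <- design_policy(coef, m = m, box = spec$box, squash = squash)
  attr(out, "objective") <- best$value
  attr(out, "trace") <- best$trace
  out
}

#' Optimize a constant (non-adaptive) design
#'
#' The two non-adaptive baselines: `mode = "midsize_male"` minimises the
#' joint injury risk of the reference occupant alone (the traditional single
#' design target); `mode = "population"` minimises the mean joint risk over
#' the Monte-Carlo sample. Same optimizer contract as [optimize_policy()]
#' over the 7-dimensional design box.
#'
#' @inheritParams optimize_policy
#' @param mode which baseline to optimise.
#' @param reference reference occupant for `mode = "midsize_male"`.
#' @return named length-7 design vector in physical units, with attributes
#'   `objective` and `trace`.
#' @export
optimize_constant <- function(spec, mode = c("population", "midsize_male"),
                              seed = 1L, lr = 0.001, steps = 2000L,
                              restarts = 3L, init_design = NULL,
                              reference = midsize_male_reference()) {
  mode <- match.arg(mode)
  if (mode == "midsize_male")
    spec <- objective_spec(spec$predictor, sample = reference, box = spec$box,
                           scaling = spec$scaling, level = spec$level,
                           params = spec$params)
  pol <- optimize_policy(spec, m = 1L, seed = seed, lr = lr, steps = steps,
                         restarts = restarts, init_design = init_design)
  d <- evaluate_policy(pol, spec$sample[1, , drop = FALSE])[1, ]
  attr(d, "objective") <- attr(pol, "objective")
  attr(d, "trace") <- attr(pol, "trace")
  d
}
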
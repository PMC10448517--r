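#' Restraint design-variable box
#'
#' The seven tunable restraint settings and their feasible ranges: load
#' limiter belt payouts D0 and D1 (m), airbag cushion diameter (m), airbag
#' tether length (m), retractor belt force (N), adjustment fraction of the
#' default airbag mass flow rate, and adjustment fraction of the default knee
#' bolster stiffness.
#'
#' @return 7 x 2 numeric matrix (rownames are the design variables, columns
#'   `min`, `max`).
#' @export
design_box <- function() {
  m <- rbind(
    d0_ll    = c(0.03,   0.05),
    d1_ll    = c(0.01,   0.11),
    dab      = c(0.96,   1.12),
    dabstrap = c(0.2032, 0.3048),
    f_ll     = c(1000,   4000),
    mf       = c(-0.15,  0.15),
    stiff    = c(-0.40,  0.40)
  )
  colnames(m) <- c("min", "max")
  m
}

#' @keywords internal
design_names <- function() rownames(design_box())

# Map unit-cube designs (n x 7, in [0,1]) to physical units and back.
#' @keywords internal
unit_to_design <- function(u) {
  b <- design_box()
  u <- as_design_matrix(u, unit = TRUE)
  out <- sweep(sweep(u, 2, b[, 2] - b[, 1], "*"), 2, b[, 1], "+")
  colnames(out) <- design_names()
  out
}

#' @keywords internal
design_to_unit <- function(d) {
  b <- design_box()
  d <- as_design_matrix(d, unit = FALSE)
  out <- sweep(sweep(d, 2, b[, 1], "-"), 2, b[, 2] - b[, 1], "/")
  colnames(out) <- design_names()
  out
}

# Coerce a design (named vector, data.frame or matrix) to an n x 7 matrix in
# canonical column order; checks box containment unless check = FALSE.
#' @keywords internal
as_design_matrix <- function(d, unit = FALSE, check = FALSE, tol = 1e-9) {
  nm <- design_names()
  if (is.data.frame(d)) d <- as.matrix(d[, intersect(nm, names(d)), drop = FALSE])
  if (is.null(dim(d))) {
    if (length(d) != 7L) stop("a design vector must have 7 components", call. = FALSE)
    d <- matrix(d, 1, 7, dimnames = list(NULL, if (is.null(names(d))) nm else names(d)))
  }
  if (!is.null(colnames(d))) {
    if (!all(nm %in% colnames(d)))
      stop("design matrix missing columns: ",
           paste(setdiff(nm, colnames(d)), collapse = ", "), call. = FALSE)
    d <- d[, nm, drop = FALSE]
  } else colnames(d) <- nm
  storage.mode(d) <- "double"
  if (check) {
    b <- if (unit) cbind(min = rep(0, 7), max = rep(1, 7)) else design_box()
    bad <- sweep(d, 2, b[, 1] - tol, "<") | sweep(d, 2, b[, 2] + tol, ">")
    if (any(bad))
      stop("design outside the feasible box: ",
           paste(unique(nm[col(bad)[bad]]), collapse = ", "), call. = FALSE)
  }
  d
}

#' Synthetic crash-simulator configuration
#'
#' Configures the seedable synthetic stand-in for full multibody crash
#' simulations. Each injury measure responds as a quadratic "bowl" around an
#' occupant-dependent optimal restraint setting:
#' \deqn{y_m(s, d) = b_m(s)\,\big(1 + \sum_l w_{ml} (\tilde d_l - \tilde
#' d^*_l(s))^2\big)\,\varepsilon,}
#' where \eqn{\tilde d} is the design on the unit scale of [design_box()],
#' \eqn{\tilde d^*(s)} is a ground-truth optimal setting linear in the
#' standardised covariates (clipped to the box), \eqn{b_m(s)} is a baseline
#' strictly increasing in BMI and stature, and \eqn{\varepsilon} is
#' multiplicative lognormal noise. The linear-in-covariates optimum makes the
#' globally optimal adaptive policy linear, so policy recovery can be checked
#' against a closed-form oracle. Baseline magnitudes are documented stand-ins,
#' not biofidelic predictions.
#'
#' Defaults encode the physical intuition that heavier and taller occupants
#' see higher injury measures, and that the optimal retractor belt force
#' increases while the optimal airbag mass flow rate decreases with BMI
#' (tighter belt, softer airbag for obese occupants).
#'
#' @param preset `"sedan"` or `"suv"`; two structurally identical
#'   configurations differing in baselines and bowl weights.
#' @param baselines named numeric: `hic15`, `chest_d_mm`, `femur_f_kn` at the
#'   midsize-male reference.
#' @param bmi_slope,stature_slope per-measure log-baseline slopes (per BMI
#'   unit, per cm).
#' @param female_offset per-measure additive log-baseline offset for females.
#' @param bowl_weights 3 x 7 non-negative matrix (measures x design
#'   variables) of bowl curvatures on the unit design scale.
#' @param opt_intercept length-7 unit-scale intercepts of the ground-truth
#'   optimal design map.
#' @param opt_slopes 7 x 3 matrix of optimal-map slopes over standardised
#'   covariates (sex, stature, bmi).
#' @param noise_sd relative (log-scale) noise standard deviation.
#' @param box occupant [covariate_box()].
#' @return An object of class `simulator_config`.
#' @export
simulator_config <- function(preset = c("sedan", "suv"),
                             baselines = NULL,
                             bmi_slope = NULL, stature_slope = NULL,
                             female_offset = NULL,
                             bowl_weights = NULL,
                             opt_intercept = NULL, opt_slopes = NULL,
                             noise_sd = 0.02,
                             box = covariate_box()) {
  preset <- match.arg(preset)
  meas <- c("hic15", "chest_d_mm", "femur_f_kn")
  dn <- design_names()
  def_base <- if (preset == "sedan") c(600, 30, 4) else c(450, 27, 3.5)
  names(def_base) <- meas
  if (is.null(baselines)) baselines <- def_base
  if (is.null(bmi_slope)) bmi_slope <- c(hic15 = 0.025, chest_d_mm = 0.025, femur_f_kn = 0.025)
  if (is.null(stature_slope)) stature_slope <- c(hic15 = 0.016, chest_d_mm = 0.016, femur_f_kn = 0.016)
  if (is.null(female_offset)) female_offset <- c(hic15 = 0, chest_d_mm = 0.08, femur_f_kn = 0)
  if (is.null(bowl_weights)) {
    w <- matrix(0, 3, 7, dimnames = list(meas, dn))
    w["hic15", c("dab", "dabstrap", "mf", "f_ll")] <- c(0.5, 0.3, 0.5, 0.1)
    w["chest_d_mm", c("d0_ll", "d1_ll", "f_ll", "mf")] <- c(0.4, 0.3, 0.6, 0.4)
    w["femur_f_kn", c("stiff", "f_ll")] <- c(0.8, 0.2)
    if (preset == "suv") w <- w * matrix(c(0.8, 1.2, 1.0), 3, 7)
    bowl_weights <- w
  }
  if (is.null(opt_intercept)) opt_intercept <- stats::setNames(rep(0.5, 7), dn)
  if (is.null(opt_slopes)) {
    a <- matrix(0, 7, 3, dimnames = list(dn, c("sex", "stature", "bmi")))
    a["d0_ll", "bmi"] <- 0.06
    a["d1_ll", "bmi"] <- -0.05
    a["dab", "stature"] <- 0.10
    a["dabstrap", c("sex", "stature")] <- c(0.04, 0.06)
    a["f_ll", c("stature", "bmi")] <- c(0.05, 0.18)
    a["mf", c("stature", "bmi")] <- c(-0.04, -0.18)
    a["stiff", "bmi"] <- 0.08
    opt_slopes <- a
  }
  bowl_weights <- matrix(as.numeric(bowl_weights), 3, 7, dimnames = list(meas, dn))
  if (any(bowl_weights < 0)) stop("bowl weights must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  named <- function(x, nm) {
    if (length(x) != length(nm))
      stop("expected ", length(nm), " values", call. = FALSE)
    if (!is.null(names(x))) x <- x[nm]
    if (anyNA(x)) stop("missing or misnamed components", call. = FALSE)
    stats::setNames(as.numeric(x), nm)
  }
  structure(list(
    preset = preset,
    baselines = named(baselines, meas),
    bmi_slope = named(bmi_slope, meas),
    stature_slope = named(stature_slope, meas),
    female_offset = named(female_offset, meas),
    bowl_weights = bowl_weights,
    opt_intercept = named(opt_intercept, dn),
    opt_slopes = matrix(as.numeric(opt_slopes), 7, 3,
                        dimnames = list(dn, c("sex", "stature", "bmi"))),
    noise_sd = as.numeric(noise_sd),
    reference = midsize_male_reference(),
    box = box
  ), class = "simulator_config")
}

#' @keywords internal
measure_names <- function() c("hic15", "chest_d_mm", "femur_f_kn")

# Baseline measures b_m(s): n x 3 matrix, strictly increasing in BMI and
# stature by construction (exponential link keeps them positive).
#' @keywords internal
simulator_baseline <- function(occupants, config) {
  occupants <- as_occupants(occupants)
  ref <- config$reference
  female <- as.numeric(occupants$sex == "female")
  dbmi <- occupants$bmi - ref$bmi
  dst <- occupants$stature_cm - ref$stature_cm
  out <- sapply(measure_names(), function(m) {
    config$baselines[m] *
      exp(config$bmi_slope[m] * dbmi + config$stature_slope[m] * dst +
            config$female_offset[m] * female)
  })
  matrix(out, nrow = nrow(occupants), dimnames = list(NULL, measure_names()))
}

#' Ground-truth optimal restraint design
#'
#' Returns the synthetic simulator's true optimal design \eqn{d^*(s)} for
#' each occupant: the configured linear map over standardised covariates,
#' clipped into the feasible design box. Under the default configuration the
#' optimal retractor force `f_ll` increases and the optimal mass flow `mf`
#' decreases with BMI.
#'
#' @param occupants occupant data.frame.
#' @param config a [simulator_config()].
#' @param unit if `TRUE`, return designs on the unit [0,1] scale instead of
#'   physical units.
#' @return n x 7 matrix of designs.
#' @export
true_optimal_design <- function(occupants, config = simulator_config(),
                                unit = FALSE) {
  st <- standardize_covariates(occupants, config$box)
  u <- matrix(config$opt_intercept, nrow(st), 7, byrow = TRUE) +
    st %*% t(config$opt_slopes)
  u <- pmin(pmax(u, 0), 1)
  colnames(u) <- design_names()
  if (unit) u else unit_to_design(u)
}

#' Simulate injury measures
#'
#' Evaluates the synthetic crash simulator for occupant/design pairs. See
#' [simulator_config()] for the response model. With `noisy = FALSE` the
#' deterministic noiseless response is returned; with `noisy = TRUE`
#' multiplicative lognormal noise with relative sd `config$noise_sd` is
#' applied, reproducibly under `seed`.
#'
#' @param occupants occupant data.frame (n rows).
#' @param designs design matrix/data.frame in physical units (n x 7, or one
#'   row recycled).
#' @param config a [simulator_config()].
#' @param noisy logical.
#' @param seed integer seed for the noise draw.
#' @return data.frame with columns `hic15`, `chest_d_mm`, `femur_f_kn`.
#' @export
simulate_measures <- function(occupants, designs, config = simulator_config(),
                              noisy = FALSE, seed = 1L) {
  occupants <- as_occupants(occupants)
  if (!all(occupants_in_box(occupants, config$box)))
    stop("occupant outside the covariate box", call. = FALSE)
  d <- as_design_matrix(designs, unit = FALSE, check = TRUE)
  n <- nrow(occupants)
  if (nrow(d) == 1L && n > 1L) d <- d[rep(1L, n), , drop = FALSE]
  if (nrow(d) != n) stop("designs must have 1 or nrow(occupants) rows", call. = FALSE)
  y <- .noiseless_measures(occupants, design_to_unit(d), config)
  if (noisy && config$noise_sd > 0) {
    z <- with_seed(seed, matrix(stats::rnorm(n * 3), n, 3))
    y <- y * exp(config$noise_sd * z)
  }
  as.data.frame(y)
}

# Core noiseless response on the unit design scale: n x 3 matrix.
#' @keywords internal
.noiseless_measures <- function(occupants, d_unit, config) {
  base <- simulator_baseline(occupants, config)
  dstar <- true_optimal_design(occupants, config, unit = TRUE)
  delta2 <- (d_unit - dstar)^2
  bowl <- 1 + delta2 %*% t(config$bowl_weights)  # n x 3
  y <- base * bowl
  colnames(y) <- measure_names()
  y
}

# Gradient of the noiseless response wrt the unit design: n x 7 x 3 array.
#' @keywords internal
.noiseless_measures_grad <- function(occupants, d_unit, config) {
  base <- simulator_baseline(occupants, config)
  dstar <- true_optimal_design(occupants, config, unit = TRUE)
  n <- nrow(d_unit)
  g <- array(0, c(n, 7, 3), dimnames = list(NULL, design_names(), measure_names()))
  for (m in 1:3)
    g[, , m] <- 2 * base[, m] * (d_unit - dstar) *
      matrix(config$bowl_weights[m, ], n, 7, byrow = TRUE)
  g
}

#' Generate a simulation dataset
#'
#' Runs the synthetic simulator at every row of a design-of-experiments
#' matrix of occupant covariates and restraint settings, producing the
#' triplets (covariates, design, injury measures) used to train surrogate
#' models.
#'
#' @param doe data.frame with occupant columns (`sex`, `stature_cm`, `bmi`)
#'   and design columns in physical units (see [design_box()]), e.g. from
#'   [scale_design()].
#' @param config a [simulator_config()].
#' @param noisy logical; add lognormal observation noise.
#' @param seed integer seed.
#' @return data.frame with the input columns plus `hic15`, `chest_d_mm`,
#'   `femur_f_kn`; one record per row of `doe`.
#' @export
generate_dataset <- function(doe, config = simulator_config(), noisy = TRUE,
                             seed = 1L) {
  if (nrow(doe) < 1L) stop("empty design matrix", call. = FALSE)
  occ <- as_occupants(doe)
  d <- as_design_matrix(doe, check = TRUE)
  y <- simulate_measures(occ, d, config, noisy = noisy, seed = seed)
  cbind(occ[, c("sex", "stature_cm", "bmi")], as.data.frame(d), y)
}

#' Save and load a simulator configuration
#'
#' Serialises a [simulator_config()] (baselines, slopes, bowl weights,
#' optimal-map coefficients, noise level, covariate box) to JSON.
#'
#' @param config a [simulator_config()].
#' @param path file path.
#' @export
write_simulator_config <- function(config, path) {
  stopifnot(inherits(config, "simulator_config"))
  b <- config$box
  jsonlite::write_json(list(
    preset = config$preset, baselines = as.list(config$baselines),
    bmi_slope = as.list(config$bmi_slope),
    stature_slope = as.list(config$stature_slope),
    female_offset = as.list(config$female_offset),
    bowl_weights = config$bowl_weights,
    opt_intercept = as.list(config$opt_intercept),
    opt_slopes = config$opt_slopes, noise_sd = config$noise_sd,
    box = list(male = b$male, female = b$female)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_simulator_config
#' @export
read_simulator_config <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  simulator_config(
    preset = s$preset, baselines = unlist(s$baselines),
    bmi_slope = unlist(s$bmi_slope), stature_slope = unlist(s$stature_slope),
    female_offset = unlist(s$female_offset),
    bowl_weights = as.matrix(s$bowl_weights),
    opt_intercept = unlist(s$opt_intercept),
    opt_slopes = as.matrix(s$opt_slopes), noise_sd = s$noise_sd,
    box = covariate_box(male_stature = s$box$male$stature,
                        male_bmi = s$box$male$bmi,
                        female_stature = s$box$female$stature,
                        female_bmi = s$box$female$bmi))
}

#' Read and write simulation datasets
#'
#' Datasets use the CSV schema
#' `sex,stature_cm,bmi,d0_ll,d1_ll,dab,dabstrap,f_ll,mf,stiff,hic15,chest_d_mm,femur_f_kn`.
#'
#' @param records dataset data.frame from [generate_dataset()].
#' @param path file path.
#' @export
write_dataset <- function(records, path) {
  cols <- c("sex", "stature_cm", "bmi", design_names(), measure_names())
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
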
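#' Injury risk curve parameters
#'
#' Frontal-impact AIS3+ risk curves for the three body regions: a lognormal
#' curve in HIC15 for the head, and logistic curves in (effective) chest
#' deflection and femur axial force for the chest and lower extremities.
#' Head risk: \eqn{\Phi((\ln \mathrm{HIC} - 7.45231)/0.73998)}. Chest risk:
#' \eqn{1/(1+\exp(10.5456 - 1.568\,D^{0.4612}))} with \eqn{D} in mm. Lower
#' extremity risk: \eqn{1/(1+\exp(5.795 - 0.5196\,F))} with \eqn{F} in kN.
#'
#' @return named list of curve coefficients.
#' @export
risk_params <- function() {
  list(
    head = c(mu = 7.45231, sigma = 0.73998),
    chest = c(b0 = 10.5456, b1 = 1.568, pow = 0.4612),
    lower_ext = c(b0 = 5.795, b1 = 0.5196)
  )
}

#' Anthropometric scaling model
#'
#' Linear predictors of chest depth (mm) and femur cross-sectional area
#' (mm^2) from occupant covariates, used to scale the midsize-male injury
#' risk curves to other body sizes. The default coefficients are documented
#' stand-ins calibrated to give scale factors near 1 in the centre of the
#' covariate box and chest depth increasing with BMI.
#'
#' @param chest_coef named numeric: `intercept` (value at the midsize-male
#'   reference), `bmi`, `stature`, `female` (per-unit linear effects).
#' @param femur_coef same layout for femur cross-sectional area.
#' @param reference reference occupant, see [midsize_male_reference()].
#' @return object of class `scaling_model`.
#' @export
scaling_model <- function(chest_coef = c(intercept = 230, bmi = 2.2,
                                         stature = 0.3, female = -10),
                          femur_coef = c(intercept = 600, bmi = 6,
                                         stature = 3, female = -60),
                          reference = midsize_male_reference()) {
  structure(list(chest_coef = chest_coef, femur_coef = femur_coef,
                 reference = reference), class = "scaling_model")
}

#' @keywords internal
predict_anthropometry <- function(occupants, model, coef_name) {
  occupants <- as_occupants(occupants)
  co <- model[[coef_name]]
  ref <- model$reference
  co[["intercept"]] +
    co[["bmi"]] * (occupants$bmi - ref$bmi) +
    co[["stature"]] * (occupants$stature_cm - ref$stature_cm) +
    co[["female"]] * as.numeric(occupants$sex == "female")
}

#' Anthropometric scale factors
#'
#' Ratios of each occupant's predicted chest depth and femur cross-sectional
#' area to the midsize-male reference values. Both factors equal 1 at the
#' reference occupant and are applied as abscissa stretches of the chest and
#' lower-extremity risk curves (head risk is not scaled).
#'
#' @param occupants occupant data.frame.
#' @param model a [scaling_model()].
#' @return data.frame with columns `chest_scale`, `femur_scale` (both > 0).
#' @export
anthropometric_scale <- function(occupants, model = scaling_model()) {
  ref <- model$reference
  chest <- predict_anthropometry(occupants, model, "chest_coef")
  femur <- predict_anthropometry(occupants, model, "femur_coef")
  ref_chest <- predict_anthropometry(ref, model, "chest_coef")
  ref_femur <- predict_anthropometry(ref, model, "femur_coef")
  if (any(chest <= 0) || any(femur <= 0) || ref_chest <= 0 || ref_femur <= 0)
    stop("scaling model predicts a non-positive body dimension", call. = FALSE)
  data.frame(chest_scale = chest / ref_chest, femur_scale = femur / ref_femur)
}

#' Map an injury measure to an injury risk
#'
#' Evaluates the region risk curve at an injury measure, with anthropometric
#' scaling applied to the measure (`measure / scale`), equivalent to
#' stretching the risk-curve abscissa by `scale`. The head curve is defined
#' on HIC15 and takes no anthropometric scaling (pass `scale = 1`). Risks are
#' monotone increasing in the measure and decreasing in the scale.
#'
#' @param region `"head"`, `"chest"` or `"lower_ext"`.
#' @param measure non-negative measure value(s): HIC15, chest deflection in
#'   mm, or femur force in kN.
#' @param scale positive scale factor(s); ignored (forced to 1) for the head.
#' @param params curve coefficients, see [risk_params()].
#' @return injury probability in [0, 1], vectorised over `measure`.
#' @examples
#' measure_to_risk("head", 1000)         # ~0.231
#' measure_to_risk("lower_ext", 11.1528) # 0.5
#' @export
measure_to_risk <- function(region = c("head", "chest", "lower_ext"),
                            measure, scale = 1, params = risk_params()) {
  region <- match.arg(region)
  if (any(measure < 0)) stop("injury measures must be non-negative", call. = FALSE)
  if (any(scale <= 0)) stop("scale factors must be positive", call. = FALSE)
  switch(region,
    head = {
      p <- params$head
      ifelse(measure <= 0, 0, stats::pnorm((log(measure) - p[["mu"]]) / p[["sigma"]]))
    },
    chest = {
      p <- params$chest
      1 / (1 + exp(p[["b0"]] - p[["b1"]] * (measure / scale)^p[["pow"]]))
    },
    lower_ext = {
      p <- params$lower_ext
      1 / (1 + exp(p[["b0"]] - p[["b1"]] * (measure / scale)))
    })
}

#' Joint injury risk across body regions
#'
#' Combines head, chest and lower-extremity risks into the probability of
#' sustaining an injury in at least one region, assuming independence:
#' \eqn{P_\mathrm{joint} = 1 - (1-p_h)(1-p_c)(1-p_l)}.
#'
#' @param p_head,p_chest,p_lower_ext probabilities in [0, 1] (vectorised).
#' @return probability in [0, 1], never less than any input.
#' @export
joint_risk <- function(p_head, p_chest, p_lower_ext) {
  ps <- cbind(p_head, p_chest, p_lower_ext)
  if (any(ps < 0 | ps > 1)) stop("region risks must lie in [0, 1]", call. = FALSE)
  1 - (1 - p_head) * (1 - p_chest) * (1 - p_lower_ext)
}

#' Injury risks from measures
#'
#' Full risk mapping for occupant/measure pairs: anthropometric scale
#' factors, the three region risk curves, and the joint combination.
#'
#' @param occupants occupant data.frame (n rows).
#' @param measures data.frame/matrix with columns `hic15`, `chest_d_mm`,
#'   `femur_f_kn` (n rows).
#' @param model a [scaling_model()].
#' @param params curve coefficients, see [risk_params()].
#' @return data.frame with columns `p_head`, `p_chest`, `p_lower_ext`,
#'   `p_joint`.
#' @export
risk_from_measures <- function(occupants, measures, model = scaling_model(),
                               params = risk_params()) {
  measures <- as.data.frame(measures)
  sc <- anthropometric_scale(occupants, model)
  p_head <- measure_to_risk("head", measures$hic15, 1, params)
  p_chest <- measure_to_risk("chest", measures$chest_d_mm, sc$chest_scale, params)
  p_low <- measure_to_risk("lower_ext", measures$femur_f_kn, sc$femur_scale, params)
  data.frame(p_head = p_head, p_chest = p_chest, p_lower_ext = p_low,
             p_joint = joint_risk(p_head, p_chest, p_low))
}

# Region risks and their derivatives wrt the raw measures, for gradient-based
# policy optimization. measures: n x 3 matrix; scales: data.frame from
# anthropometric_scale(). Returns list(p = n x 3, dp_dm = n x 3,
# p_joint = n, djoint_dm = n x 3).
#' @keywords internal
.risk_with_grad <- function(measures, scales, params = risk_params()) {
  m <- measures
  n <- nrow(m)
  p <- matrix(0, n, 3); dp <- matrix(0, n, 3)
  # head (lognormal in HIC)
  ph <- params$head
  h <- pmax(m[, 1], 1e-12)
  z <- (log(h) - ph[["mu"]]) / ph[["sigma"]]
  p[, 1] <- stats::pnorm(z)
  dp[, 1] <- stats::dnorm(z) / (ph[["sigma"]] * h)
  # chest (logistic in scaled deflection^pow)
  pc <- params$chest
  dce <- pmax(m[, 2], 1e-12) / scales$chest_scale
  eta <- pc[["b0"]] - pc[["b1"]] * dce^pc[["pow"]]
  p[, 2] <- 1 / (1 + exp(eta))
  dp[, 2] <- p[, 2] * (1 - p[, 2]) * pc[["b1"]] * pc[["pow"]] *
    dce^(pc[["pow"]] - 1) / scales$chest_scale
  # lower extremity (logistic in scaled force)
  pl <- params$lower_ext
  fe <- m[, 3] / scales$femur_scale
  eta <- pl[["b0"]] - pl[["b1"]] * fe
  p[, 3] <- 1 / (1 + exp(eta))
  dp[, 3] <- p[, 3] * (1 - p[, 3]) * pl[["b1"]] / scales$femur_scale
  q <- 1 - p
  pj <- 1 - q[, 1] * q[, 2] * q[, 3]
  djoint <- cbind(q[, 2] * q[, 3] * dp[, 1],
                  q[, 1] * q[, 3] * dp[, 2],
                  q[, 1] * q[, 2] * dp[, 3])
  list(p = p, dp_dm = dp, p_joint = pj, djoint_dm = djoint)
}
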
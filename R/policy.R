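# Polynomial adaptive design policies.
#
# A policy maps occupant covariates s to restraint settings d. Covariates are
# standardized to [-1, 1] per the covariate box (sex to {-1, +1}); the raw
# policy output is a linear combination of per-order power features
# phi_j(s) = [s_1^(j-1), ..., s_K^(j-1)], j = 1..m, and is squashed into the
# feasible design box so the returned settings are always feasible.

# Feature matrix for standardized covariates st (n x 3: sex, stature, bmi).
# Powers of sex collapse (sex^2 = 1, sex^3 = sex), so duplicated columns are
# dropped to keep the coefficient problem identifiable: the features are the
# intercept, sex (order >= 2 policies), and stature^p, bmi^p for p < m.
#' @keywords internal
policy_features <- function(st, m) {
  stopifnot(m >= 1)
  cols <- list("(Intercept)" = rep(1, nrow(st)))
  if (m >= 2) cols[["sex"]] <- st[, "sex"]
  for (p in seq_len(m - 1)) {
    suffix <- if (p == 1) "" else paste0("^", p)
    cols[[paste0("stature", suffix)]] <- st[, "stature"]^p
    cols[[paste0("bmi", suffix)]] <- st[, "bmi"]^p
  }
  do.call(cbind, cols)
}

#' @keywords internal
policy_feature_names <- function(m) {
  colnames(policy_features(matrix(0, 1, 3,
    dimnames = list(NULL, c("sex", "stature", "bmi"))), m))
}

#' Construct a design policy
#'
#' A polynomial adaptive design policy of order `m`: raw outputs are linear
#' in the power features of the standardized covariates and are mapped into
#' the feasible design box by a squashing function. `m = 1` gives a constant
#' (non-adaptive) policy; `m = 2` a linear policy.
#'
#' @param coef 7 x F coefficient matrix (rows = design variables, columns =
#'   features of [policy_feature_names()] for order `m`).
#' @param m polynomial order (>= 1).
#' @param box occupant [covariate_box()] used to standardize covariates.
#' @param squash `"logistic"` (smooth scaled-logistic squash, outputs strictly
#'   inside the box), `"clip"` (hard clipping) or `"identity"` (raw unit
#'   outputs; no feasibility guarantee, intended for analysis).
#' @return object of class `design_policy`.
#' @export
design_policy <- function(coef, m, box = covariate_box(),
                          squash = c("logistic", "clip", "identity")) {
  squash <- match.arg(squash)
  fn <- policy_feature_names(m)
  coef <- matrix(as.numeric(coef), 7, length(fn),
                 dimnames = list(design_names(), fn))
  structure(list(coef = coef, m = m, box = box, squash = squash),
            class = "design_policy")
}

#' @keywords internal
apply_squash <- function(raw, squash) {
  switch(squash,
         logistic = sigmoid(raw),
         clip = pmin(pmax(raw, 0), 1),
         identity = raw)
}

#' @keywords internal
squash_deriv <- function(raw, squash) {
  switch(squash,
         logistic = { u <- sigmoid(raw); u * (1 - u) },
         clip = (raw > 0 & raw < 1) * 1,
         identity = raw * 0 + 1)
}

#' Evaluate a design policy
#'
#' Returns the restraint settings the policy assigns to each occupant.
#'
#' @param policy a [design_policy()].
#' @param occupants occupant data.frame.
#' @param unit if `TRUE`, return unit-scale designs.
#' @return n x 7 matrix of designs (physical units unless `unit = TRUE`).
#' @export
evaluate_policy <- function(policy, occupants, unit = FALSE) {
  stopifnot(inherits(policy, "design_policy"))
  st <- standardize_covariates(occupants, policy$box)
  phi <- policy_features(st, policy$m)
  raw <- phi %*% t(policy$coef)         # n x 7
  u <- apply_squash(raw, policy$squash)
  colnames(u) <- design_names()
  if (unit) u else unit_to_design(u)
}

#' Constant policy wrapping a fixed design
#'
#' Builds the order-1 policy that returns `design` for every occupant
#' (up to the squash: unit coordinates are clipped away from 0/1 so the
#' logistic squash can represent them exactly).
#'
#' @param design length-7 design in physical units.
#' @inheritParams design_policy
#' @export
constant_policy <- function(design, box = covariate_box(),
                            squash = "logistic") {
  u <- design_to_unit(as_design_matrix(design))[1, ]
  u <- pmin(pmax(u, 1e-4), 1 - 1e-4)
  coef <- matrix(if (squash == "logistic") logit(u) else u, 7, 1)
  design_policy(coef, m = 1, box = box, squash = squash)
}

#' @export
print.design_policy <- function(x, ...) {
  cat(sprintf("design policy: order m = %d, squash = %s\n", x$m, x$squash))
  print(round(x$coef, 4))
  invisible(x)
}

#' Save and load design policies
#'
#' Policies are persisted as JSON: order, coefficient matrix, squash and the
#' covariate box used for standardization.
#'
#' @param policy a [design_policy()].
#' @param path file path.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "design_policy"))
  b <- policy$box
  jsonlite::write_json(list(
    m = policy$m, squash = policy$squash, coef = policy$coef,
    feature_names = colnames(policy$coef),
    box = list(male = b$male, female = b$female)
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  box <- covariate_box(
    male_stature = ser$box$male$stature, male_bmi = ser$box$male$bmi,
    female_stature = ser$box$female$stature, female_bmi = ser$box$female$bmi)
  coef <- if (is.matrix(ser$coef)) ser$coef else
    matrix(unlist(ser$coef), nrow = 7, byrow = TRUE)
  design_policy(coef, m = ser$m, box = box, squash = ser$squash)
}
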
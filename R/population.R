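#' Occupant covariate box
#'
#' The occupant population is characterised by three covariates: sex, stature
#' and body-mass index (BMI). Continuous covariates are restricted to a
#' per-sex box nominally spanning the 5th--95th percentile of the adult
#' population. The default ranges are documented stand-ins for survey-based
#' percentiles and can be overridden.
#'
#' @param male_stature,female_stature numeric length-2, stature range in cm.
#' @param male_bmi,female_bmi numeric length-2, BMI range in kg/m^2.
#' @return An object of class `covariate_box`: a list with elements `male`
#'   and `female`, each holding `stature` and `bmi` ranges.
#' @examples
#' box <- covariate_box()
#' box$male$stature
#' @export
covariate_box <- function(male_stature = c(163, 186),
                          male_bmi = c(20.5, 39.5),
                          female_stature = c(150, 172),
                          female_bmi = c(19.5, 42.5)) {
  chk_range <- function(r, what) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop("invalid ", what, " range: need finite min < max", call. = FALSE)
    as.numeric(r)
  }
  structure(list(
    male = list(stature = chk_range(male_stature, "male stature"),
                bmi = chk_range(male_bmi, "male bmi")),
    female = list(stature = chk_range(female_stature, "female stature"),
                  bmi = chk_range(female_bmi, "female bmi"))
  ), class = "covariate_box")
}

#' Sample an occupant population
#'
#' Draws `n` occupants with a balanced sex split (ties go to male) and
#' continuous covariates either uniform over the per-sex box or from a
#' Latin-hypercube space-filling design over (stature, BMI) within each sex.
#' Uniform sampling with equal sex weights implements a constant population
#' density over the covariate box.
#'
#' @param n number of occupants (>= 1).
#' @param box a [covariate_box()].
#' @param seed integer seed; identical seeds reproduce the sample exactly.
#' @param scheme `"uniform"` for independent uniform draws, `"space-filling"`
#'   for a per-sex Latin hypercube.
#' @return data.frame with columns `sex` ("male"/"female"), `stature_cm`,
#'   `bmi`.
#' @examples
#' pop <- sample_population(10, seed = 1)
#' table(pop$sex)
#' @export
sample_population <- function(n, box = covariate_box(), seed = 1L,
                              scheme = c("uniform", "space-filling")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single count >= 1", call. = FALSE)
  n <- as.integer(n)
  stopifnot(inherits(box, "covariate_box"))
  n_male <- as.integer(ceiling(n / 2))   # ties to male
  n_female <- n - n_male

  draw <- function(n_sex, ranges, rng_seed) {
    if (n_sex == 0L)
      return(matrix(numeric(0), 0, 2))
    u <- with_seed(rng_seed, {
      if (scheme == "uniform") {
        matrix(stats::runif(2 * n_sex), n_sex, 2)
      } else if (n_sex == 1L) {
        matrix(stats::runif(2), 1, 2)
      } else {
        lhs::randomLHS(n_sex, 2)
      }
    })
    cbind(ranges$stature[1] + u[, 1] * diff(ranges$stature),
          ranges$bmi[1] + u[, 2] * diff(ranges$bmi))
  }
  m <- draw(n_male, box$male, seed)
  f <- draw(n_female, box$female, seed + 1L)
  out <- data.frame(
    sex = rep(c("male", "female"), c(n_male, n_female)),
    stature_cm = c(m[, 1], f[, 1]),
    bmi = c(m[, 2], f[, 2]),
    stringsAsFactors = FALSE
  )
  out
}

#' Midsize-male reference occupant
#'
#' The single occupant that traditional restraint systems are optimised for:
#' by default a 50th-percentile male of 175.0 cm stature and BMI 25.6.
#'
#' @param stature_cm,bmi reference anthropometry.
#' @return One-row occupant data.frame.
#' @export
midsize_male_reference <- function(stature_cm = 175.0, bmi = 25.6) {
  data.frame(sex = "male", stature_cm = as.numeric(stature_cm),
             bmi = as.numeric(bmi), stringsAsFactors = FALSE)
}

#' Vulnerable-subgroup rules
#'
#' Builds the default subgroup definitions used for subgroup risk reporting:
#' tall obese males (BMI > 30.5 and stature > 181.7 cm) and short obese
#' females (BMI > 37.3 and stature < 157.0 cm). Thresholds are strict
#' inequalities; directions are `"above"` or `"below"` per threshold.
#'
#' @return A list of rules, each a list with `name`, `sex`, `bmi_threshold`,
#'   `bmi_direction`, `stature_threshold`, `stature_direction`.
#' @export
default_subgroup_rules <- function() {
  list(
    list(name = "tall_obese_male", sex = "male",
         bmi_threshold = 30.5, bmi_direction = "above",
         stature_threshold = 181.7, stature_direction = "above"),
    list(name = "short_obese_female", sex = "female",
         bmi_threshold = 37.3, bmi_direction = "above",
         stature_threshold = 157.0, stature_direction = "below")
  )
}

#' Subgroup membership
#'
#' Classifies occupants against subgroup rules. An occupant matches a rule
#' when sex agrees and both covariates fall strictly on the required side of
#' their thresholds; an occupant may match zero rules. Membership does not
#' depend on the ordering of the rules.
#'
#' @param occupants occupant data.frame (`sex`, `stature_cm`, `bmi`).
#' @param rules list of rules as produced by [default_subgroup_rules()].
#' @return A list (one element per occupant) of matched rule names; use
#'   [subgroup_indicator()] for a logical matrix instead.
#' @export
subgroup_membership <- function(occupants, rules = default_subgroup_rules()) {
  ind <- subgroup_indicator(occupants, rules)
  apply(ind, 1L, function(r) colnames(ind)[r], simplify = FALSE)
}

#' @rdname subgroup_membership
#' @export
subgroup_indicator <- function(occupants, rules = default_subgroup_rules()) {
  occupants <- as_occupants(occupants)
  side <- function(x, thr, dir) {
    switch(dir, above = x > thr, below = x < thr,
           stop("direction must be 'above' or 'below'", call. = FALSE))
  }
  cols <- vapply(rules, function(rule) {
    occupants$sex == rule$sex &
      side(occupants$bmi, rule$bmi_threshold, rule$bmi_direction) &
      side(occupants$stature_cm, rule$stature_threshold, rule$stature_direction)
  }, logical(nrow(occupants)))
  cols <- matrix(cols, nrow = nrow(occupants))
  colnames(cols) <- vapply(rules, `[[`, character(1), "name")
  cols
}

#' @keywords internal
as_occupants <- function(x) {
  if (is.data.frame(x)) {
    need <- c("sex", "stature_cm", "bmi")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("occupant data missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (!all(x$sex %in% c("male", "female")))
      stop("sex must be 'male' or 'female'", call. = FALSE)
    return(x)
  }
  stop("occupants must be a data.frame", call. = FALSE)
}

# Check containment of occupants in a covariate box.
#' @keywords internal
occupants_in_box <- function(occupants, box) {
  occupants <- as_occupants(occupants)
  ok <- logical(nrow(occupants))
  for (sx in c("male", "female")) {
    i <- occupants$sex == sx
    r <- box[[sx]]
    ok[i] <- occupants$stature_cm[i] >= r$stature[1] &
      occupants$stature_cm[i] <= r$stature[2] &
      occupants$bmi[i] >= r$bmi[1] & occupants$bmi[i] <= r$bmi[2]
  }
  ok
}

# Numeric covariate encoding: sex in {0 male, 1 female}, raw stature/bmi.
#' @keywords internal
occupants_matrix <- function(occupants) {
  occupants <- as_occupants(occupants)
  cbind(sex = as.numeric(occupants$sex == "female"),
        stature_cm = occupants$stature_cm, bmi = occupants$bmi)
}

# Covariates standardised to [-1, 1] per the box; sex -> {-1 male, +1 female}.
#' @keywords internal
standardize_covariates <- function(occupants, box) {
  occupants <- as_occupants(occupants)
  n <- nrow(occupants)
  out <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("sex", "stature", "bmi")))
  out[, "sex"] <- ifelse(occupants$sex == "female", 1, -1)
  for (sx in c("male", "female")) {
    i <- occupants$sex == sx
    r <- box[[sx]]
    out[i, "stature"] <- 2 * (occupants$stature_cm[i] - r$stature[1]) /
      diff(r$stature) - 1
    out[i, "bmi"] <- 2 * (occupants$bmi[i] - r$bmi[1]) / diff(r$bmi) - 1
  }
  out
}

#' Read and write occupant populations
#'
#' Populations are exchanged as CSV with columns `sex,stature_cm,bmi`.
#'
#' @param occupants occupant data.frame.
#' @param path file path.
#' @return `read_population` returns the occupant data.frame;
#'   `write_population` returns `path` invisibly.
#' @export
write_population <- function(occupants, path) {
  utils::write.csv(as_occupants(occupants)[, c("sex", "stature_cm", "bmi")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  as_occupants(utils::read.csv(path, stringsAsFactors = FALSE))
}
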
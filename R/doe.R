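#' Maximum-projection (MaxPro) criterion
#'
#' Space-filling quality score for a design on the unit hypercube:
#' \deqn{\psi(D) = \Big[\frac{1}{\binom{n}{2}} \sum_{i<j} \prod_{l=1}^{p}
#' (x_{il} - x_{jl})^{-2}\Big]^{1/p}.}
#' Lower is better. The criterion rewards designs whose projections onto
#' every subset of factors remain space-filling, which is what matters when a
#' surrogate model turns out to depend on only a few inputs. If any two rows
#' share a coordinate in any column the criterion is infinite (the design has
#' a degenerate projection), reported as `Inf` rather than an error.
#'
#' @param design n x p numeric matrix with entries in [0, 1], n >= 2.
#' @return scalar \eqn{\psi \ge 0} (possibly `Inf`).
#' @export
maxpro_criterion <- function(design) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (n < 2L) stop("need at least 2 design rows", call. = FALSE)
  P <- matrix(1, n, n)
  for (l in seq_len(p)) {
    d2 <- outer(design[, l], design[, l], "-")^2
    P <- P / d2                       # Inf on coincident coordinates
  }
  s <- P[upper.tri(P)]
  if (any(is.nan(s)) || any(is.infinite(s))) return(Inf)
  (mean(s))^(1 / p)
}

#' Generate a maximum-projection Latin hypercube design
#'
#' Starts from a random Latin hypercube and improves the MaxPro criterion by
#' simulated-annealing coordinate exchange: each proposal swaps two entries
#' within one column (preserving the Latin-hypercube structure), accepted
#' always when it improves \eqn{\psi} and with Boltzmann probability
#' otherwise, under geometric cooling. The best design visited is returned,
#' so the final criterion never exceeds the initial one.
#'
#' @param n number of runs (>= 2).
#' @param p number of factors (>= 1).
#' @param seed integer seed.
#' @param iterations number of exchange proposals.
#' @param t0,t_final initial and final annealing temperatures, as fractions
#'   of the initial mean pair score.
#' @return n x p matrix of unit-scale coordinates with attributes `psi`
#'   (final criterion) and `psi_initial`.
#' @examples
#' d <- generate_maxpro_design(12, 3, seed = 1, iterations = 2000)
#' attr(d, "psi") <= attr(d, "psi_initial")
#' @export
generate_maxpro_design <- function(n, p, seed = 1L, iterations = 10000L,
                                   t0 = 0.05, t_final = 1e-6) {
  if (!is.numeric(n) || n < 2L) stop("n must be >= 2", call. = FALSE)
  if (!is.numeric(p) || p < 1L) stop("p must be >= 1", call. = FALSE)
  n <- as.integer(n); p <- as.integer(p)
  X <- with_seed(seed, lhs::randomLHS(n, p))
  # pair score matrix P[i,j] = prod_l (x_il - x_jl)^(-2), diag unused
  pairP <- function(X) {
    P <- matrix(1, n, n)
    for (l in seq_len(p)) P <- P / outer(X[, l], X[, l], "-")^2
    diag(P) <- 0
    P
  }
  P <- pairP(X)
  npairs <- n * (n - 1) / 2
  S <- sum(P) / 2
  psi0 <- (S / npairs)^(1 / p)
  best_X <- X; best_S <- S
  if (n > 2L || p > 1L) {
    moves <- with_seed(seed + 1L, list(
      col = sample.int(p, iterations, replace = TRUE),
      i = sample.int(n, iterations, replace = TRUE),
      jraw = sample.int(n - 1L, iterations, replace = TRUE),
      u = stats::runif(iterations)
    ))
    temp <- (S / npairs) * t0 * (t_final / t0)^(seq_len(iterations) / iterations)
    for (it in seq_len(iterations)) {
      cl <- moves$col[it]; i <- moves$i[it]
      j <- moves$jraw[it]; if (j >= i) j <- j + 1L
      xi <- X[i, cl]; xj <- X[j, cl]
      others <- setdiff(seq_len(n), c(i, j))
      # swapping entries i,j in column cl rescales pairs (i,k) and (j,k)
      ri <- (xi - X[others, cl])^2 / (xj - X[others, cl])^2
      newPi <- P[i, others] * ri
      newPj <- P[j, others] / ri
      dS <- sum(newPi - P[i, others]) + sum(newPj - P[j, others])
      if (dS < 0 || moves$u[it] < exp(-dS / temp[it])) {
        X[i, cl] <- xj; X[j, cl] <- xi
        P[i, others] <- newPi; P[others, i] <- newPi
        P[j, others] <- newPj; P[others, j] <- newPj
        S <- S + dS
        if (S < best_S) { best_S <- S; best_X <- X }
      }
    }
  }
  structure(best_X, psi = (best_S / npairs)^(1 / p), psi_initial = psi0)
}

#' DOE column layout for the joint covariate/design space
#'
#' The simulation campaign explores a 10-dimensional input space: three
#' occupant covariates (sex treated as a continuous column thresholded at 0.5
#' when scaled, stature, BMI) followed by the seven restraint design
#' variables of [design_box()].
#'
#' @return character vector of the 10 column names in canonical order.
#' @export
doe_columns <- function() c("sex", "stature_cm", "bmi", design_names())

#' Scale a unit-cube design to physical units
#'
#' Maps a unit-scale DOE matrix onto occupant covariates and restraint
#' settings: the sex column is binarised at 0.5 (below 0.5 is male), stature
#' and BMI are affinely mapped into the per-sex covariate box, and the seven
#' design columns into their physical ranges. [unscale_design()] inverts the
#' mapping for the continuous columns.
#'
#' @param design n x 10 unit-scale matrix with columns ordered as
#'   [doe_columns()].
#' @param box occupant [covariate_box()].
#' @return data.frame with columns `sex`, `stature_cm`, `bmi` and the seven
#'   design variables in physical units.
#' @export
scale_design <- function(design, box = covariate_box()) {
  design <- as.matrix(design)
  if (ncol(design) != 10L)
    stop("expected 10 columns (", paste(doe_columns(), collapse = ", "), ")",
         call. = FALSE)
  if (any(design < 0 | design > 1))
    stop("unit-scale design entries must lie in [0, 1]", call. = FALSE)
  colnames(design) <- doe_columns()
  sex <- ifelse(design[, "sex"] < 0.5, "male", "female")
  stature <- bmi <- numeric(nrow(design))
  for (sx in c("male", "female")) {
    i <- sex == sx
    r <- box[[sx]]
    stature[i] <- r$stature[1] + design[i, "stature_cm"] * diff(r$stature)
    bmi[i] <- r$bmi[1] + design[i, "bmi"] * diff(r$bmi)
  }
  d <- unit_to_design(design[, design_names(), drop = FALSE])
  cbind(data.frame(sex = sex, stature_cm = stature, bmi = bmi,
                   stringsAsFactors = FALSE),
        as.data.frame(d))
}

#' @rdname scale_design
#' @param scaled data.frame as returned by `scale_design`.
#' @export
unscale_design <- function(scaled, box = covariate_box()) {
  occ <- as_occupants(scaled)
  u <- matrix(NA_real_, nrow(occ), 10, dimnames = list(NULL, doe_columns()))
  u[, "sex"] <- ifelse(occ$sex == "male", 0.25, 0.75)
  for (sx in c("male", "female")) {
    i <- occ$sex == sx
    r <- box[[sx]]
    u[i, "stature_cm"] <- (occ$stature_cm[i] - r$stature[1]) / diff(r$stature)
    u[i, "bmi"] <- (occ$bmi[i] - r$bmi[1]) / diff(r$bmi)
  }
  u[, design_names()] <- design_to_unit(as_design_matrix(scaled))
  u
}

#' Write a unit-scale design with column metadata
#'
#' Saves the design as CSV (unit scale) plus a JSON sidecar recording the
#' column names and physical ranges used by [scale_design()].
#'
#' @param design unit-scale design matrix (10 columns).
#' @param path CSV path; metadata is written to `<path>.json`.
#' @param box occupant [covariate_box()].
#' @export
write_design <- function(design, path, box = covariate_box()) {
  design <- as.matrix(design)
  colnames(design) <- doe_columns()
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  db <- design_box()
  meta <- list(
    columns = doe_columns(),
    covariate_box = list(
      male = list(stature = box$male$stature, bmi = box$male$bmi),
      female = list(stature = box$female$stature, bmi = box$female$bmi)
    ),
    design_box = lapply(seq_len(nrow(db)), function(i) unname(db[i, ])),
    sex_threshold = 0.5
  )
  names(meta$design_box) <- rownames(db)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
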
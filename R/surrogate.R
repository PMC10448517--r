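# Gaussian-process surrogate of the injury-measure response surfaces.
#
# One independent GP per injury measure over the 10-dimensional standardized
# input (sex, stature, bmi, 7 unit-scale design variables), with a constant
# mean (absorbed into target standardization), a squared-exponential kernel
# with per-dimension lengthscales (ARD), and Gaussian observation noise.
# Hyperparameters are estimated by maximising the marginal likelihood with
# analytic gradients from a fixed-seed multi-start.

GP_JITTER <- 1e-6

# Squared-exponential cross-kernel between scaled inputs. X1, X2 are
# standardized matrices; ell a lengthscale vector.
#' @keywords internal
.se_kernel <- function(X1, X2, ell, sf2) {
  A <- sweep(X1, 2, ell, "/")
  B <- sweep(X2, 2, ell, "/")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sf2 * exp(-0.5 * pmax(d2, 0))
}

# Negative log marginal likelihood and gradient wrt
# theta = c(log ell (p), log sf, log sn). y is the standardized target.
#' @keywords internal
.gp_nll <- function(theta, X, y) {
  p <- ncol(X); n <- nrow(X)
  ell <- exp(theta[1:p]); sf2 <- exp(2 * theta[p + 1]); sn2 <- exp(2 * theta[p + 2])
  R <- .se_kernel(X, X, ell, 1)
  K <- sf2 * R + diag(sn2 + GP_JITTER, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, gradient = rep(0, p + 2)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  A <- Kinv - tcrossprod(alpha)          # 0.5 * sum(A * dK) is dNLL/dtheta
  g <- numeric(p + 2)
  KR <- sf2 * R
  for (l in seq_len(p)) {
    D2 <- outer(X[, l], X[, l], "-")^2
    g[l] <- 0.5 * sum(A * (KR * D2 / ell[l]^2))
  }
  g[p + 1] <- 0.5 * sum(A * (2 * KR))
  g[p + 2] <- 0.5 * sum(diag(A)) * 2 * sn2
  list(value = nll, gradient = g)
}

#' Fit Gaussian-process surrogates of the injury measures
#'
#' Trains one GP per injury measure on simulation records. Inputs are the
#' concatenated occupant covariates (sex coded 0/1) and design variables on
#' the unit scale, standardized to zero mean and unit variance; targets are
#' standardized, with HIC15 modelled on the log scale. Hyperparameters
#' (per-dimension lengthscales, signal and noise standard deviations)
#' maximise the marginal likelihood via L-BFGS-B from `restarts` fixed-seed
#' starting points. A zero-variance target is fitted as a constant with a
#' noise floor.
#'
#' @param records dataset from [generate_dataset()] (or the same CSV schema);
#'   at least 10 rows.
#' @param seed integer seed controlling the multi-start.
#' @param restarts number of MLE starts.
#' @param log_hic model `hic15` on the log scale.
#' @return object of class `injury_surrogate`.
#' @export
fit_gp <- function(records, seed = 1L, restarts = 3L, log_hic = TRUE) {
  if (nrow(records) < 10L) stop("need at least 10 records", call. = FALSE)
  occ <- as_occupants(records)
  Dunit <- design_to_unit(as_design_matrix(records))
  Xraw <- cbind(occupants_matrix(occ), Dunit)
  x_mean <- colMeans(Xraw)
  x_sd <- apply(Xraw, 2, stats::sd)
  x_sd[x_sd < 1e-12] <- 1
  Xs <- sweep(sweep(Xraw, 2, x_mean, "-"), 2, x_sd, "/")
  p <- ncol(Xs)

  fit_one <- function(yraw, log_scale) {
    y0 <- if (log_scale) log(pmax(yraw, 1e-12)) else yraw
    y_mean <- mean(y0); y_sd <- stats::sd(y0)
    if (!is.finite(y_sd) || y_sd < 1e-10) {
      return(list(constant = TRUE, y_mean = y_mean, y_sd = 1,
                  log = log_scale))
    }
    y <- (y0 - y_mean) / y_sd
    starts <- lapply(seq_len(restarts), function(r) {
      with_seed(child_seeds(seed, restarts)[r], {
        c(log(stats::runif(p, 0.5, 3)), log(stats::runif(1, 0.5, 1.5)),
          log(stats::runif(1, 0.01, 0.3)))
      })
    })
    starts[[1]] <- c(rep(log(1.5), p), log(1), log(0.1))
    best <- NULL
    for (th0 in starts) {
      fit <- tryCatch(
        stats::optim(th0, fn = function(th) .gp_nll(th, Xs, y)$value,
                     gr = function(th) .gp_nll(th, Xs, y)$gradient,
                     method = "L-BFGS-B",
                     lower = c(rep(log(0.05), p), log(1e-3), log(1e-4)),
                     upper = c(rep(log(50), p), log(10), log(2)),
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    th <- best$par
    ell <- exp(th[1:p]); sf2 <- exp(2 * th[p + 1]); sn2 <- exp(2 * th[p + 2])
    K <- .se_kernel(Xs, Xs, ell, sf2) + diag(sn2 + GP_JITTER, nrow(Xs))
    L <- chol(K)
    alpha <- backsolve(L, forwardsolve(t(L), y))
    list(constant = FALSE, y_mean = y_mean, y_sd = y_sd, log = log_scale,
         ell = ell, sf2 = sf2, sn2 = sn2, L = L, alpha = alpha, nll = best$value)
  }

  models <- list(
    hic15 = fit_one(records$hic15, log_hic),
    chest_d_mm = fit_one(records$chest_d_mm, FALSE),
    femur_f_kn = fit_one(records$femur_f_kn, FALSE)
  )
  structure(list(models = models, x_mean = x_mean, x_sd = x_sd, Xs = Xs,
                 n = nrow(Xs), seed = seed),
            class = "injury_surrogate")
}

# Posterior mean/sd (standardized-target scale) for one measure's GP at
# standardized inputs Xn; optionally gradients wrt the standardized inputs
# restricted to columns `grad_cols`.
#' @keywords internal
.gp_posterior <- function(fit, Xs_train, Xn, grad_cols = NULL) {
  if (fit$constant) {
    out <- list(mean = rep(0, nrow(Xn)), sd = rep(1e-6, nrow(Xn)))
    if (!is.null(grad_cols)) {
      z <- matrix(0, nrow(Xn), length(grad_cols))
      out$dmean <- z; out$dsd <- z
    }
    return(out)
  }
  Ks <- .se_kernel(Xn, Xs_train, fit$ell, fit$sf2)     # n* x n
  mu <- as.vector(Ks %*% fit$alpha)
  W <- Ks %*% chol2inv(fit$L)                          # n* x n
  varf <- pmax(fit$sf2 - rowSums(W * Ks), 1e-12)
  sdf <- sqrt(varf)
  out <- list(mean = mu, sd = sdf)
  if (!is.null(grad_cols)) {
    nd <- length(grad_cols)
    dmean <- matrix(0, nrow(Xn), nd)
    dsd <- matrix(0, nrow(Xn), nd)
    for (j in seq_len(nd)) {
      l <- grad_cols[j]
      # d k(x, x_i)/d x_l = k * (x_il - x_l) / ell_l^2
      Dl <- outer(-Xn[, l], -Xs_train[, l], "-") / fit$ell[l]^2  # (x_il - x_l)
      dKs <- Ks * Dl
      dmean[, j] <- dKs %*% fit$alpha
      dsd[, j] <- -rowSums(W * dKs) / sdf
    }
    out$dmean <- dmean; out$dsd <- dsd
  }
  out
}

# Full-surrogate prediction at occupants/unit-designs. Returns per-measure
# natural-scale UCB (level) plus mean/sd, and optionally gradients of the UCB
# wrt the 7 unit design coordinates (n x 7 x 3 array).
#' @keywords internal
.surrogate_predict <- function(object, occupants, d_unit, level = 0.95,
                               need_grad = FALSE) {
  z <- stats::qnorm(level)
  Xraw <- cbind(occupants_matrix(occupants), d_unit)
  Xn <- sweep(sweep(Xraw, 2, object$x_mean, "-"), 2, object$x_sd, "/")
  dcols <- 4:10
  n <- nrow(Xn)
  ucb <- mean_nat <- matrix(0, n, 3, dimnames = list(NULL, measure_names()))
  sd_model <- matrix(0, n, 3)
  grad <- if (need_grad) array(0, c(n, 7, 3)) else NULL
  for (m in seq_along(measure_names())) {
    fit <- object$models[[measure_names()[m]]]
    post <- .gp_posterior(fit, object$Xs, Xn, if (need_grad) dcols else NULL)
    u_std <- post$mean + z * post$sd
    u_nat <- fit$y_mean + fit$y_sd * u_std
    mu_nat <- fit$y_mean + fit$y_sd * post$mean
    if (fit$log) {
      ucb[, m] <- exp(u_nat); mean_nat[, m] <- exp(mu_nat)
    } else {
      ucb[, m] <- u_nat; mean_nat[, m] <- mu_nat
    }
    sd_model[, m] <- fit$y_sd * post$sd
    if (need_grad) {
      du_std <- post$dmean + z * post$dsd                 # wrt standardized x
      du <- fit$y_sd * sweep(du_std, 2, object$x_sd[dcols], "/")
      if (fit$log) du <- du * ucb[, m]
      grad[, , m] <- du
    }
  }
  list(ucb = ucb, mean = mean_nat, sd = sd_model, grad = grad)
}

#' Predict injury measures with an upper confidence bound
#'
#' Serves robust predictions from a fitted surrogate: the one-sided
#' upper confidence bound \eqn{\mu(x) + z_\mathrm{level}\,\sigma(x)} of each
#' measure's GP posterior, back-transformed from the log scale for HIC15
#' (the bound commutes with the monotone transform). `level = 0.5` returns
#' the posterior mean/median.
#'
#' @param object fitted `injury_surrogate`.
#' @param occupants occupant data.frame (n rows).
#' @param designs designs in physical units (n x 7 or one row recycled).
#' @param level one-sided confidence level in (0, 1); 0.95 gives z = 1.645.
#' @param what `"ucb"`, `"mean"` or `"sd"`.
#' @return data.frame of the three measures.
#' @export
predict_ucb <- function(object, occupants, designs, level = 0.95,
                        what = c("ucb", "mean", "sd")) {
  stopifnot(inherits(object, "injury_surrogate"))
  what <- match.arg(what)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  occupants <- as_occupants(occupants)
  d <- as_design_matrix(designs)
  n <- nrow(occupants)
  if (nrow(d) == 1L && n > 1L) d <- d[rep(1L, n), , drop = FALSE]
  pr <- .surrogate_predict(object, occupants, design_to_unit(d), level)
  as.data.frame(pr[[what]])
}

#' @export
predict.injury_surrogate <- function(object, occupants, designs,
                                     level = 0.95, ...) {
  predict_ucb(object, occupants, designs, level)
}

#' Cross-validate the surrogate
#'
#' k-fold cross-validation of the GP surrogate: records are partitioned into
#' folds under `seed`, the surrogate is refitted on each set of k-1 folds and
#' its posterior-mean predictions assembled on the held-out fold. R^2 is
#' computed per measure on the natural measure scale as
#' \eqn{1 - SS_{res}/SS_{tot}}.
#'
#' @param records dataset from [generate_dataset()].
#' @param k number of folds (>= 2, <= n).
#' @param seed integer seed for the fold assignment and refits.
#' @param restarts MLE restarts per refit.
#' @return object of class `cv_report`: list with `predictions` (data.frame
#'   of out-of-fold predictions and truths), `r2` (named per-measure), `folds`
#'   and `seed`.
#' @export
cross_validate <- function(records, k = 10L, seed = 1L, restarts = 2L) {
  n <- nrow(records)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("more folds than records", call. = FALSE)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- matrix(NA_real_, n, 3, dimnames = list(NULL, measure_names()))
  for (f in seq_len(k)) {
    hold <- folds == f
    fit <- fit_gp(records[!hold, , drop = FALSE], seed = seed,
                  restarts = restarts)
    pred[hold, ] <- as.matrix(predict_ucb(
      fit, as_occupants(records[hold, , drop = FALSE]),
      as_design_matrix(records[hold, , drop = FALSE]), level = 0.5))
  }
  truth <- as.matrix(records[, measure_names()])
  r2 <- vapply(seq_len(3), function(m) {
    1 - sum((truth[, m] - pred[, m])^2) / sum((truth[, m] - mean(truth[, m]))^2)
  }, numeric(1))
  names(r2) <- measure_names()
  structure(list(
    predictions = data.frame(fold = folds, truth, check.names = FALSE,
                             predicted = pred),
    r2 = r2, folds = folds, seed = seed
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n",
              max(x$folds), x$seed))
  for (m in names(x$r2)) cat(sprintf("  R^2 %-12s %.4f\n", m, x$r2[m]))
  invisible(x)
}

#' Save and load a fitted surrogate
#'
#' Persists the hyperparameters, standardization and training inputs as JSON
#' so a surrogate can be reconstructed without refitting.
#'
#' @param object fitted `injury_surrogate`.
#' @param path file path.
#' @export
write_surrogate <- function(object, path) {
  stopifnot(inherits(object, "injury_surrogate"))
  ser <- list(x_mean = object$x_mean, x_sd = object$x_sd,
              Xs = object$Xs, n = object$n, seed = object$seed,
              models = lapply(object$models, function(f) {
                f[c("constant", "y_mean", "y_sd", "log",
                    if (!f$constant) c("ell", "sf2", "sn2", "alpha"))]
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  Xs <- as.matrix(ser$Xs)
  models <- lapply(ser$models, function(f) {
    f$constant <- isTRUE(f$constant)
    if (!f$constant) {
      K <- .se_kernel(Xs, Xs, f$ell, f$sf2) + diag(f$sn2 + GP_JITTER, nrow(Xs))
      f$L <- chol(K)
      f$alpha <- as.numeric(f$alpha)
    }
    f
  })
  structure(list(models = models, x_mean = ser$x_mean, x_sd = ser$x_sd,
                 Xs = Xs, n = ser$n, seed = ser$seed),
            class = "injury_surrogate")
}
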
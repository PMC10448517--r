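# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small noiseless dataset + fitted surrogate used across surrogate tests.
small_dataset <- function() {
  fixture("small_dataset", function() {
    cfg <- simulator_config()
    doe <- scale_design(generate_maxpro_design(120, 10, seed = 11,
                                               iterations = 3000))
    generate_dataset(doe, cfg, noisy = FALSE)
  })
}

small_surrogate <- function() {
  fixture("small_surrogate", function() fit_gp(small_dataset(), seed = 1,
                                               restarts = 2))
}

default_config <- function() fixture("default_config", simulator_config)

# Explicit GP posterior mean/sd computed independently of the package's
# kernel/posterior code (plain loops + dense solve), for algebra checks.
naive_gp_posterior <- function(Xtr, y, Xte, ell, sf2, sn2, jitter = 1e-6) {
  kfun <- function(a, b) {
    s <- 0
    for (l in seq_along(a)) s <- s + (a[l] - b[l])^2 / ell[l]^2
    sf2 * exp(-0.5 * s)
  }
  n <- nrow(Xtr); m <- nrow(Xte)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- kfun(Xtr[i, ], Xtr[j, ])
  K <- K + diag(sn2 + jitter, n)
  Ks <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) Ks[i, j] <- kfun(Xte[i, ], Xtr[j, ])
  Kinv <- solve(K)
  list(mean = as.vector(Ks %*% Kinv %*% y),
       sd = sqrt(pmax(sf2 - rowSums((Ks %*% Kinv) * Ks), 0)))
}
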
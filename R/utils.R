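# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so package functions never perturb the
# user's random stream.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
logit <- function(p) log(p / (1 - p))

# Derive a stream of child seeds from one seed (kept within 32-bit range).
#' @keywords internal
child_seeds <- function(seed, n) {
  (as.integer(seed) + 7919L * seq_len(n)) %% 2147483629L
}
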
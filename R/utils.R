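# RNG helpers: every stochastic step draws its own child seed from a master
# seed so results do not depend on evaluation order or parallel chunking.

MAX_SEED <- 2147483646L

#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @noRd
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(MAX_SEED, n, replace = FALSE))
}

# Deterministic seed for (scenario, replication) pairs; keeps replications
# reproducible and independent of execution order. Arithmetic kept in doubles
# (exact below 2^53) and reduced into 32-bit integer range.
#' @noRd
hash_seed <- function(master, scenario, replication) {
  h <- (as.numeric(master) + 1000003 * as.numeric(scenario) +
          7919 * as.numeric(replication)) %% 2147483629
  as.integer(h) + 1L
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
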
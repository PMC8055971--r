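# Internal RNG helpers. All stochastic operations in the package draw from an
# isolated stream keyed by an explicit integer seed, so results are
# reproducible and the caller's .Random.seed is left untouched.

local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  swap_in <- function() {
    env$outer <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    if (is.null(env$state)) {
      set.seed(as.integer(seed))
    } else {
      assign(".Random.seed", env$state, globalenv())
    }
  }
  swap_out <- function() {
    env$state <- get(".Random.seed", globalenv(), inherits = FALSE)
    if (is.null(env$outer)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", env$outer, globalenv())
    }
  }
  wrap <- function(f) {
    function(...) {
      swap_in()
      on.exit(swap_out())
      f(...)
    }
  }
  list(
    runif = wrap(stats::runif),
    rnorm = wrap(stats::rnorm),
    sample = wrap(base::sample),
    sample_int = wrap(base::sample.int)
  )
}

#' Derive a component seed from a master seed
#'
#' Deterministic Lehmer-style seed splitting: one master seed controls the
#' full campaign, and every stochastic component (initialization, surrogate
#' restarts, oracle noise, GA) draws from its own derived stream. Derived
#' seeds stay in `[1, 2^31 - 2]`, valid 32-bit R seeds.
#'
#' @param seed Integer master seed.
#' @param k Integer or string tag naming the component.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  m <- 2147483647
  if (is.character(k)) {
    k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) %% m
  }
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + as.numeric(k) %% m + 1) %% m
  as.integer(s + (s == 0))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Euclidean distance matrix between rows of a and rows of b.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
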
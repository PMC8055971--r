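# Shared fixtures: everything is generated in code at test time.

# A quick campaign configuration for small problems.
quick_config <- function(m, epsilon = 0.05, ...) {
  epal_config(epsilon = rep_len(epsilon, m), init_size = 6L,
              max_iterations = 60L, n_restarts = 2L, refit_every = 10L, ...)
}

# Random objective matrices with positive entries (safe for nadir/HV tests).
random_front <- function(n, d, seed) {
  rng_mat <- local({
    set.seed(seed)
    matrix(runif(n * d, 0.2, 1), n, d)
  })
  rng_mat
}

# Direct O(n^2) Pareto check written independently of the package internals.
brute_pareto <- function(pts) {
  n <- nrow(pts)
  sapply(seq_len(n), function(i) {
    !any(sapply(seq_len(n), function(j) {
      j != i && all(pts[j, ] >= pts[i, ]) && any(pts[j, ] > pts[i, ])
    }))
  })
}
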
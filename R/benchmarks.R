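#' Configuration of the polymer pseudo-simulator
#'
#' An analytic, noisy stand-in for the molecular-simulation oracle. Its
#' functional forms are invented emulations of the qualitative
#' structure-property trends of coarse-grained dispersants — they are NOT
#' calibrated to any force field:
#' * radius of gyration follows the Flory scaling `Rg = a * N^nu_eff`, with
#'   `nu_eff` a composition-weighted blend of textbook Flory exponents
#'   (0.588 good solvent for `W`, 1/3 collapsed for `R`, 0.5 theta for
#'   `Ta`/`Tr`), so more good-solvent beads swell the chain;
#' * adsorption strength sums per-bead surface affinities (low for `W`)
#'   plus an end-anchoring bonus, so it falls with the good-solvent
#'   fraction and rises with the affinities;
#' * the dimer repulsion barrier grows with the good-solvent bead count,
#'   with the relative sequence entropy, and weakly with the number of
#'   monomer runs (blockiness).
#'
#' @param prefactor Flory prefactor `a` (bead-length units).
#' @param nu Named Flory exponents per solvent regime
#'   (`good`, `theta`, `collapsed`), each in (0, 1).
#' @param surface_affinity Named per-bead surface affinities (kT per bead).
#' @param end_bonus Multiplier on head/tail affinities added to the
#'   adsorption strength (end-anchoring).
#' @param rep_w,rep_entropy,rep_runs Repulsion couplings: per-`W`-bead term,
#'   entropy coupling (times chain length), per-run term.
#' @param noise_sd Additive Gaussian noise SD per objective
#'   `(Rg, dG_ads, dG_rep)`. Defaults are about 1% of typical objective
#'   magnitudes — deliberately below the default mean-scaled tolerance
#'   `0.05 * |mu|` (after the `sqrt(beta_t)` inflation), following the
#'   practical rule that the tolerance should exceed the simulation error;
#'   otherwise measured points can remain unclassifiable at that tolerance.
#' @param seed Integer seed; noise is a deterministic function of
#'   (seed, sequence), so repeated calls agree.
#' @return List of class `pseudo_sim_config`.
#' @export
pseudo_sim_config <- function(prefactor = 1,
                              nu = c(good = 0.588, theta = 0.5, collapsed = 1 / 3),
                              surface_affinity = c(W = 0.1, R = 0.6,
                                                   Ta = 0.8, Tr = 1.4),
                              end_bonus = 0.5,
                              rep_w = 0.4, rep_entropy = 0.6, rep_runs = 0.1,
                              noise_sd = c(0.04, 0.2, 0.15),
                              seed = 1L) {
  stopifnot(all(nu > 0 & nu < 1), all(noise_sd >= 0))
  structure(list(prefactor = prefactor, nu = nu,
                 surface_affinity = surface_affinity, end_bonus = end_bonus,
                 rep_w = rep_w, rep_entropy = rep_entropy, rep_runs = rep_runs,
                 noise_sd = rep_len(noise_sd, 3L), seed = as.integer(seed)),
            class = "pseudo_sim_config")
}

#' Pseudo-simulate the three dispersant objectives of a sequence
#'
#' Returns `(Rg, dG_ads, dG_rep)` for a polymer sequence under
#' [pseudo_sim_config()], optionally with additive Gaussian noise that is a
#' deterministic function of the config seed and the sequence.
#'
#' @inheritParams relative_sequence_entropy
#' @param config A [pseudo_sim_config()].
#' @param noisy Add the configured measurement noise?
#' @return Named numeric vector `c(Rg, dG_ads, dG_rep)` (natural
#'   orientation: small `Rg` is good, large `dG_ads` and `dG_rep` are good).
#' @export
pseudo_simulate <- function(sequence, config = pseudo_sim_config(),
                            noisy = TRUE) {
  beads <- if (length(sequence) == 1L && grepl("\\[", sequence[1])) {
    parse_sequence(sequence)
  } else sequence
  counts <- sequence_composition(beads)
  n <- length(beads)
  nu_eff <- (counts["W"] * config$nu[["good"]] +
               counts["R"] * config$nu[["collapsed"]] +
               (counts["Ta"] + counts["Tr"]) * config$nu[["theta"]]) / n
  rg <- config$prefactor * n^nu_eff
  aff <- config$surface_affinity
  dg_ads <- sum(aff[beads]) +
    config$end_bonus * (aff[[beads[1]]] + aff[[beads[n]]])
  cl <- cluster_statistics(beads)
  dg_rep <- config$rep_w * counts[["W"]] +
    config$rep_entropy * relative_sequence_entropy(beads) * n +
    config$rep_runs * cl$n_runs
  out <- c(Rg = unname(rg), dG_ads = unname(dg_ads), dG_rep = unname(dg_rep))
  if (noisy && any(config$noise_sd > 0)) {
    rng <- local_rng(derive_seed(config$seed, format_sequence(beads)))
    out <- out + rng$rnorm(3L) * config$noise_sd
  }
  out
}

#' Construct a reproducible benchmark problem
#'
#' Desk-scale stand-ins for a simulation campaign, with precomputed ground
#' truth:
#' * `two_obj_convex` — two smooth conflicting objectives of two uniform
#'   features, maximization of both;
#' * `three_obj_polymer` — a small full-factorial polymer design space
#'   evaluated by the pseudo-simulator: minimize `Rg`, maximize `dG_ads`
#'   and `dG_rep`;
#' * `correlated_missing` — `three_obj_polymer` with a fraction of the
#'   third objective's (`dG_rep`) labels removed, emulating a property too
#'   expensive to measure everywhere.
#'
#' @param name One of `"two_obj_convex"`, `"three_obj_polymer"`,
#'   `"correlated_missing"`.
#' @param size Target number of candidates (>= 10; the polymer problems
#'   round to a multiple of their 81-composition factorial grid).
#' @param seed Integer seed; identical seeds give identical problems.
#' @param missing_fraction Fraction of objective-3 labels removed
#'   (`correlated_missing` only); exactly `floor(size * fraction)`
#'   candidates lose that label.
#' @param noise_sd Overrides the per-objective measurement noise.
#' @return List of class `epal_benchmark`: `features` (matrix), `truth`
#'   (noiseless objective matrix, natural orientation), `directions`,
#'   `oracle` (noisy, deterministic per candidate), `pareto_true` (logical
#'   mask on the oriented truth), `labels` (full label table; with missing
#'   rows dropped for `correlated_missing`), `missing` (candidate indices
#'   lacking objective 3), `design` (sequence tibble for polymer problems).
#' @export
make_benchmark <- function(name = c("two_obj_convex", "three_obj_polymer",
                                    "correlated_missing"),
                           size = 100L, seed = 1L,
                           missing_fraction = 1 / 3, noise_sd = NULL) {
  name <- match.arg(name)
  if (size < 10L) stop("size must be >= 10", call. = FALSE)
  if (name == "two_obj_convex") {
    rng <- local_rng(derive_seed(seed, "bench2"))
    x <- matrix(rng$runif(2L * size), ncol = 2L)
    colnames(x) <- c("x1", "x2")
    truth <- cbind(f1 = x[, 1L],
                   f2 = 1 - x[, 1L]^2 - 0.5 * x[, 2L])
    directions <- c("maximize", "maximize")
    ns <- rep_len(noise_sd %||% 0.01, 2L)
    prob <- list(features = x, truth = truth, directions = directions,
                 noise_sd = ns, design = NULL)
  } else {
    spp <- max(1L, as.integer(round(size / 81)))
    design <- full_factorial_design(c(4, 6, 8), n_factors = 4L,
                                    sequences_per_point = spp,
                                    seed = derive_seed(seed, "doe"))
    cfg <- pseudo_sim_config(seed = derive_seed(seed, "sim"))
    if (!is.null(noise_sd)) cfg$noise_sd <- rep_len(noise_sd, 3L)
    truth <- t(vapply(design$sequence, pseudo_simulate, numeric(3L),
                      config = cfg, noisy = FALSE, USE.NAMES = FALSE))
    colnames(truth) <- c("Rg", "dG_ads", "dG_rep")
    directions <- c("minimize", "maximize", "maximize")
    prob <- list(features = as.matrix(design[, feature_names()]),
                 truth = truth, directions = directions,
                 noise_sd = cfg$noise_sd, design = design, sim_config = cfg)
  }
  n <- nrow(prob$truth)
  m <- ncol(prob$truth)
  sgn <- ifelse(prob$directions == "minimize", -1, 1)
  prob$pareto_true <- pareto_mask(sweep(prob$truth, 2L, sgn, "*"))
  # deterministic per-candidate noisy measurements
  noisy <- prob$truth
  for (i in seq_len(n)) {
    rng <- local_rng(derive_seed(seed, i * 37 + 11))
    noisy[i, ] <- noisy[i, ] + rng$rnorm(m) * prob$noise_sd
  }
  labels <- tibble::tibble(
    candidate = rep(seq_len(n), each = m),
    objective = rep(seq_len(m), times = n),
    value = as.numeric(t(noisy)),
    noise_sd = rep(prob$noise_sd, times = n))
  prob$missing <- integer(0)
  if (name == "correlated_missing") {
    n_missing <- floor(size * missing_fraction)
    rng <- local_rng(derive_seed(seed, "missing"))
    prob$missing <- sort(rng$sample_int(n, min(n_missing, n)))
    labels <- labels[!(labels$candidate %in% prob$missing &
                         labels$objective == 3L), ]
  }
  prob$labels <- label_table(labels, m)
  prob$oracle <- oracle_from_table(prob$labels)
  prob$name <- name
  prob$n <- n
  prob$seed <- as.integer(seed)
  structure(prob, class = "epal_benchmark")
}

#' @export
print.epal_benchmark <- function(x, ...) {
  cat("benchmark '", x$name, "': ", x$n, " candidates, ",
      ncol(x$truth), " objectives, ", sum(x$pareto_true),
      " true Pareto points\n", sep = "")
  invisible(x)
}

#' Bootstrapped random-search baseline
#'
#' Uniform sampling without replacement over the design space, replicated
#' `n_bootstrap` times with derived seeds. The hypervolume error after `k`
#' samples is computed from the true-Pareto subset of the sampled points, so
#' each replicate's trajectory is non-increasing. Replicates can share a
#' matched set of initial points with an active-learning run.
#'
#' @param problem An [make_benchmark()] problem.
#' @param n_iterations Samples per replicate (truncated to the design size
#'   with a warning).
#' @param n_bootstrap Number of replicates (default 100).
#' @param seed Integer master seed.
#' @param init Optional integer indices sampled first in every replicate.
#' @return List with `trajectories` (tibble: `replicate`, `iteration`,
#'   `hv_error`) and `summary` (tibble: `iteration`, `mean`, `sd`).
#' @export
random_search_baseline <- function(problem, n_iterations, n_bootstrap = 100L,
                                   seed = 1L, init = NULL) {
  stopifnot(n_bootstrap >= 1L)
  n <- problem$n
  if (n_iterations > n) {
    warning("n_iterations exceeds the design size; truncating to ", n)
    n_iterations <- n
  }
  sgn <- ifelse(problem$directions == "minimize", -1, 1)
  truth_or <- sweep(problem$truth, 2L, sgn, "*")
  ref <- nadir_point(truth_or)
  front_idx <- which(problem$pareto_true)
  hv_max <- hypervolume(truth_or[front_idx, , drop = FALSE], ref)
  trajs <- vector("list", n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    rng <- local_rng(derive_seed(seed, b))
    rest <- setdiff(seq_len(n), init)
    ordering <- c(init, rest[rng$sample_int(length(rest))])[seq_len(n_iterations)]
    err <- numeric(n_iterations)
    cur_front <- integer(0)
    cur_err <- 1
    for (k in seq_len(n_iterations)) {
      if (ordering[k] %in% front_idx) {
        cur_front <- c(cur_front, ordering[k])
        cur_err <- (hv_max -
                      hypervolume(truth_or[cur_front, , drop = FALSE], ref)) /
          hv_max
      }
      err[k] <- cur_err
    }
    trajs[[b]] <- tibble::tibble(replicate = b,
                                 iteration = seq_len(n_iterations),
                                 hv_error = err)
  }
  trajectories <- dplyr::bind_rows(trajs)
  summary <- dplyr::summarise(
    dplyr::group_by(trajectories, .data$iteration),
    mean = mean(.data$hv_error),
    sd = if (dplyr::n() > 1L) stats::sd(.data$hv_error) else 0,
    .groups = "drop")
  list(trajectories = trajectories, summary = summary)
}
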
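#' Configuration of an epsilon-PAL campaign
#'
#' @param epsilon Per-objective tolerance fractions `eps_i >= 0`
#'   (dimensionless; the working tolerance on objective i is
#'   `eps_i * |mu_i|`, i.e. mean-scaled). Length defines the number of
#'   objectives; a scalar is recycled to `n_objectives`.
#' @param delta Confidence parameter in (0, 1): the classification is
#'   epsilon-accurate with probability at least `1 - delta` under the model.
#' @param beta_scale Multiplier on the theoretical hyperrectangle scaling
#'   `beta_t` (default 1/9, a common practical deflation of the
#'   union-bound-derived width).
#' @param init_size Number of initial design points chosen by greedy
#'   farthest-point sampling.
#' @param max_iterations Cap on learning iterations (each samples
#'   `batch_size` candidates).
#' @param objective_directions Character vector `"maximize"` / `"minimize"`
#'   per objective; minimized objectives are negated at ingestion and
#'   re-negated on output.
#' @param batch_size Candidates sampled per iteration.
#' @param exclude_high_variance If `TRUE`, candidates whose dimensionless
#'   rectangle size exceeds the `high_variance_quantile` are skipped during
#'   the classification stage (they stay unclassified this iteration).
#' @param high_variance_quantile Quantile threshold for the above.
#' @param n_objectives Number of objectives (defaults to `length(epsilon)`).
#' @param rank,n_restarts,refit_every Surrogate settings, see
#'   [fit_surrogate()].
#' @param surrogate_theta Optional fixed surrogate hyperparameters (see the
#'   `theta` argument of [fit_surrogate()]).
#' @param hv_stop Optional hypervolume-error target: when ground truth is
#'   supplied to [run_campaign()] and the error of the classified front
#'   drops to this value or below, the campaign stops early.
#' @param cv_tol Lower clamp on `|mu|` in coefficient-of-variation
#'   denominators (mean-scaled widths presuppose sign-stable objectives;
#'   means near zero are clamped to this tolerance).
#' @return A list of class `epal_config`.
#' @export
epal_config <- function(epsilon, delta = 0.05, beta_scale = 1 / 9,
                        init_size = 10L, max_iterations = 500L,
                        objective_directions = NULL, batch_size = 1L,
                        exclude_high_variance = FALSE,
                        high_variance_quantile = 0.95,
                        n_objectives = NULL,
                        rank = 1L, n_restarts = 5L, refit_every = 10L,
                        surrogate_theta = NULL,
                        hv_stop = NULL, cv_tol = 1e-8) {
  m <- n_objectives %||% length(epsilon)
  epsilon <- rep_len(epsilon, m)
  if (any(epsilon < 0)) stop("epsilon must be >= 0", call. = FALSE)
  if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  dirs <- objective_directions %||% rep("maximize", m)
  dirs <- match.arg(dirs, c("maximize", "minimize"), several.ok = TRUE)
  dirs <- rep_len(dirs, m)
  structure(list(
    epsilon = epsilon, delta = delta, beta_scale = beta_scale,
    init_size = as.integer(init_size),
    max_iterations = as.integer(max_iterations),
    objective_directions = dirs, batch_size = as.integer(batch_size),
    exclude_high_variance = exclude_high_variance,
    high_variance_quantile = high_variance_quantile,
    n_objectives = as.integer(m), rank = as.integer(rank),
    n_restarts = as.integer(n_restarts), refit_every = as.integer(refit_every),
    surrogate_theta = surrogate_theta,
    hv_stop = hv_stop, cv_tol = cv_tol
  ), class = "epal_config")
}

#' Greedy farthest-point initial design
#'
#' Maximin initialization in feature space: the first point is drawn
#' uniformly (seeded), then each subsequent point maximizes its minimum
#' Euclidean distance to the already chosen set (ties broken by lowest
#' index).
#'
#' @param features Numeric feature matrix.
#' @param k Number of points to select (`k <= n`).
#' @param seed Integer seed for the starting point.
#' @param start Optional fixed index of the starting point (overrides the
#'   seeded random choice).
#' @return Integer vector of `k` distinct row indices, in selection order.
#' @export
select_initial_design <- function(features, k, seed = 1L, start = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > n) stop("k exceeds the number of candidates", call. = FALSE)
  chosen <- if (!is.null(start)) as.integer(start) else {
    local_rng(derive_seed(seed, "fps"))$sample_int(n, 1L)
  }
  if (k == 1L) return(chosen)
  mind <- cross_dist(features, features[chosen, , drop = FALSE])[, 1L]
  for (i in 2L:k) {
    mind[chosen] <- -Inf
    nxt <- which.max(mind) # which.max takes the first (lowest-index) maximum
    chosen <- c(chosen, nxt)
    d_new <- cross_dist(features, features[nxt, , drop = FALSE])[, 1L]
    mind <- pmin(mind, d_new)
  }
  chosen
}

#' Hyperrectangle scaling factor
#'
#' The iteration-dependent width multiplier
#' `beta_t = beta_scale * 2 * log(m * n * pi^2 * t^2 / (6 * delta))`,
#' monotonically non-decreasing in the iteration `t`, the design-space size
#' `n` and the number of objectives `m`.
#'
#' @param iteration Learning iteration `t >= 1`.
#' @param n_candidates Design-space size.
#' @param n_objectives Number of objectives.
#' @param config An [epal_config()] (uses `delta` and `beta_scale`).
#' @return The scalar `beta_t`.
#' @export
beta_t <- function(iteration, n_candidates, n_objectives, config) {
  stopifnot(iteration >= 1)
  config$beta_scale * 2 * log(
    n_objectives * n_candidates * pi^2 * iteration^2 / (6 * config$delta))
}

#' Build confidence hyperrectangles
#'
#' For each candidate and objective the plausible interval is
#' `mu +/- sqrt(beta_t) * sigma`, where `mu`/`sigma` come from the surrogate
#' posterior for unsampled pairs and from the measurement (value and its
#' `noise_sd`) for sampled pairs. Each interval is intersected with the
#' candidate's previous rectangle, so rectangles only ever shrink; an empty
#' intersection (model inconsistency) falls back to the new interval with a
#' warning.
#'
#' @param prediction List with `mean` and `sd` matrices
#'   (candidates x objectives, maximization orientation).
#' @param previous Previous rectangle set (as returned by this function), or
#'   `NULL` on the first iteration.
#' @param beta Scaling factor from [beta_t()].
#' @param sampled_labels Label table of measurements already taken
#'   (maximization orientation); `noise_sd` `NA` treated as 0.
#' @return List of matrices `lower`, `upper`, `center` (the per-pair `mu`
#'   actually used, measured value where sampled).
#' @export
build_rectangles <- function(prediction, previous, beta, sampled_labels = NULL) {
  center <- prediction$mean
  sd_m <- prediction$sd
  if (!is.null(sampled_labels) && nrow(sampled_labels) > 0L) {
    idx <- cbind(sampled_labels$candidate, sampled_labels$objective)
    center[idx] <- sampled_labels$value
    sd_m[idx] <- ifelse(is.na(sampled_labels$noise_sd), 0,
                        sampled_labels$noise_sd)
  }
  half <- sqrt(beta) * sd_m
  lower <- center - half
  upper <- center + half
  bad <- rep(FALSE, nrow(center))
  if (!is.null(previous)) {
    new_lower <- pmax(lower, previous$lower)
    new_upper <- pmin(upper, previous$upper)
    bad <- rowSums(new_lower > new_upper) > 0L
    if (any(bad)) {
      warning(sum(bad), " candidate(s) had empty rectangle intersections; ",
              "falling back to the new interval (model inconsistency)")
      new_lower[bad, ] <- lower[bad, ]
      new_upper[bad, ] <- upper[bad, ]
    }
    lower <- new_lower
    upper <- new_upper
  }
  list(lower = lower, upper = upper, center = center, fallback = bad)
}

#' Create an empty classification state
#'
#' All candidates start unclassified; the sampled set records which have
#' been queried.
#'
#' @param n Number of candidates.
#' @param sampled Integer indices already sampled.
#' @return List of class `epal_state` with integer index sets `pareto`,
#'   `discarded`, `unclassified`, `sampled`.
#' @export
epal_state <- function(n, sampled = integer(0)) {
  structure(list(pareto = integer(0), discarded = integer(0),
                 unclassified = seq_len(n), sampled = as.integer(sampled),
                 n = as.integer(n)),
            class = "epal_state")
}

# Dimensionless (coefficient-of-variation) rectangle size per candidate.
cv_width <- function(rectangles, means, cv_tol = 1e-8) {
  denom <- pmax(abs(means), cv_tol)
  apply((rectangles$upper - rectangles$lower) / denom, 1L, max)
}

# Candidates exempt from classification this iteration under the
# exclude-high-variance option.
classification_skip <- function(state, rectangles, config) {
  if (!isTRUE(config$exclude_high_variance)) return(integer(0))
  w <- cv_width(rectangles, rectangles$center, config$cv_tol)
  alive <- c(state$pareto, state$unclassified)
  thr <- stats::quantile(w[alive], config$high_variance_quantile, names = FALSE)
  intersect(state$unclassified, which(w > thr))
}

# x' epsilon-dominates x's optimistic corner, with mean-scaled tolerance on
# x''s side: pess(x') + eps*|mu(x')| >= opt(x) in all coordinates and > in
# at least one (the strict part keeps exactly tied candidates mutually
# unclassified rather than arbitrarily discarding one).
strictly_eps_above <- function(aug, target) {
  n <- nrow(aug)
  geq <- aug >= rep(target, each = n)
  gt <- aug > rep(target, each = n)
  rowSums(geq) == ncol(aug) & rowSums(gt) > 0L
}

#' Discard rule of epsilon-PAL
#'
#' Moves a candidate from unclassified to discarded when some other
#' still-alive candidate's pessimistic corner, inflated by the mean-scaled
#' tolerance `eps_i * |mu_i|`, dominates its optimistic corner: such a
#' candidate cannot be epsilon-Pareto-optimal with the required confidence.
#' Discarded candidates never return.
#'
#' @param state An `epal_state`.
#' @param rectangles Rectangle set from [build_rectangles()].
#' @param epsilon Per-objective tolerance fractions.
#' @param skip Candidate indices exempt from classification this iteration.
#' @return Updated `epal_state`.
#' @export
epsilon_discard <- function(state, rectangles, epsilon, skip = integer(0)) {
  aug <- rectangles$lower +
    rep(epsilon, each = nrow(rectangles$lower)) * abs(rectangles$center)
  todo <- setdiff(state$unclassified, skip)
  for (x in todo) {
    alive <- setdiff(c(state$pareto, state$unclassified), x)
    if (length(alive) == 0L) next
    if (any(strictly_eps_above(aug[alive, , drop = FALSE],
                               rectangles$upper[x, ]))) {
      state$unclassified <- setdiff(state$unclassified, x)
      state$discarded <- c(state$discarded, x)
    }
  }
  state
}

#' Pareto-promotion rule of epsilon-PAL
#'
#' Runs after [epsilon_discard()]. A candidate is classified
#' epsilon-accurate Pareto-optimal when no other alive candidate could
#' dominate it even under the most optimistic outcome: there is no `x'`
#' whose optimistic corner exceeds the candidate's pessimistic corner
#' inflated by `eps_i * |mu_i|` in every objective (strictly in one).
#' Promoted candidates never return to unclassified.
#'
#' @inheritParams epsilon_discard
#' @return Updated `epal_state`.
#' @export
epsilon_pareto_promote <- function(state, rectangles, epsilon, skip = integer(0)) {
  todo <- setdiff(state$unclassified, skip)
  for (x in todo) {
    others <- setdiff(c(state$pareto, state$unclassified), x)
    target <- rectangles$lower[x, ] + epsilon * abs(rectangles$center[x, ])
    blocked <- length(others) > 0L &&
      any(strictly_eps_above(rectangles$upper[others, , drop = FALSE],
                             target))
    if (!blocked) {
      state$unclassified <- setdiff(state$unclassified, x)
      state$pareto <- c(state$pareto, x)
    }
  }
  state
}

#' Coefficient-of-variation acquisition
#'
#' Ranks the unsampled candidates that are still presumed near or at the
#' Pareto front (the union of the Pareto-classified and unclassified sets)
#' by the dimensionless rectangle size
#' `w(x) = max_i (upper_i - lower_i) / |mu_i|` and returns the `batch_size`
#' largest (ties by lowest index). Discarded candidates are never selected.
#'
#' @inheritParams epsilon_discard
#' @param batch_size Number of candidates to return.
#' @param cv_tol Clamp on `|mu|` denominators.
#' @param exclude Additional indices to never select (e.g. unmeasurable
#'   candidates).
#' @return Integer vector of candidate indices (possibly shorter than
#'   `batch_size`); length 0 signals natural termination.
#' @export
acquisition <- function(state, rectangles, batch_size = 1L, cv_tol = 1e-8,
                        exclude = integer(0)) {
  pool <- setdiff(c(state$pareto, state$unclassified),
                  c(state$sampled, exclude))
  if (length(pool) == 0L) return(integer(0))
  w <- cv_width(rectangles, rectangles$center, cv_tol)[pool]
  ord <- order(-w, pool)
  pool[ord][seq_len(min(batch_size, length(pool)))]
}

#' Run an epsilon-PAL active-learning campaign
#'
#' The full loop: greedy farthest-point initialization, ICM Gaussian-process
#' surrogate fit, per-iteration hyperrectangle construction (intersected so
#' they only shrink), confident discarding and epsilon-accurate Pareto
#' promotion, coefficient-of-variation acquisition, oracle query, and model
#' update. Terminates naturally when every candidate is classified and all
#' Pareto-classified candidates have been sampled, or at `max_iterations`,
#' or (with ground truth supplied) when the hypervolume error of the
#' classified front reaches `config$hv_stop`. After the loop the surrogate
#' is retrained once on all sampled points, including discarded ones.
#'
#' @param design Feature source: a numeric matrix, or a tibble whose numeric
#'   columns (other than `id`) are the features (e.g. from
#'   [full_factorial_design()]).
#' @param oracle Either a function `function(indices)` returning a data
#'   frame with columns `candidate`, `objective`, `value` and optionally
#'   `noise_sd` (natural orientation; partial objectives allowed), or a
#'   label table covering the whole space (see [oracle_from_table()]).
#' @param config An [epal_config()].
#' @param seed Integer master seed; all internal randomness derives from it.
#' @param truth Optional matrix of true objective values
#'   (candidates x objectives, natural orientation) enabling per-iteration
#'   hypervolume-error tracking.
#' @param track Record a per-iteration trace (rectangle widths, fallback
#'   flags, discarded set) in the `trace` field, for property checking.
#' @param standardize Standardize features with the initial training
#'   sample's statistics before fitting (default). Disable when features
#'   are already on the scale the surrogate hyperparameters refer to, e.g.
#'   with fixed `surrogate_theta`.
#' @return An object of class `epal_campaign`: fields `state`, `history`
#'   (tibble), `model`, `rectangles`, `config`, plus [tidy()][generics::tidy],
#'   [glance()][generics::glance] and [autoplot()][ggplot2::autoplot] methods.
#' @export
run_campaign <- function(design, oracle, config, seed = 1L, truth = NULL,
                         track = FALSE, standardize = TRUE) {
  feats <- design_features(design)
  n <- nrow(feats)
  m <- config$n_objectives
  sgn <- ifelse(config$objective_directions == "minimize", -1, 1)
  oracle_fn <- if (is.function(oracle)) oracle else oracle_from_table(oracle)

  truth_or <- NULL
  ref <- NULL
  if (!is.null(truth)) {
    truth_or <- sweep(as.matrix(truth), 2L, sgn, "*")
    ref <- nadir_point(truth_or)
  }
  hv_err <- function(state) {
    if (is.null(truth_or)) return(NA_real_)
    hypervolume_error(truth_or[state$pareto, , drop = FALSE], truth_or, ref)
  }

  init <- select_initial_design(
    standardize_features(feats)$standardized,
    k = min(config$init_size, n), seed = derive_seed(seed, "init"))
  labels <- query_oracle(oracle_fn, init, m, sgn)
  failed <- attr(labels, "failed")
  state <- epal_state(n, sampled = setdiff(init, failed))

  # standardize features with the initial training sample, as during fitting
  std <- if (standardize) {
    standardize_features(feats, train_rows = state$sampled)$standardized
  } else feats

  history <- list(tibble::tibble(
    iteration = 0L, sampled_ids = paste(init, collapse = ";"),
    n_pareto = 0L, n_discarded = 0L, n_unclassified = n,
    hypervolume_error = hv_err(state), refit = TRUE))

  model <- NULL
  rects <- NULL
  pending <- labels
  stopped <- FALSE
  trace <- if (track) list()
  if (config$max_iterations >= 1L) {
    for (t in seq_len(config$max_iterations)) {
      if (is.null(model)) {
        model <- fit_surrogate(std, labels, m, rank = config$rank,
                               n_restarts = config$n_restarts,
                               refit_every = config$refit_every,
                               seed = derive_seed(seed, "surrogate"),
                               theta = config$surrogate_theta)
        refitted <- TRUE
      } else {
        before <- model$since_refit
        model <- update_surrogate(model, pending)
        refitted <- model$since_refit < before + nrow(pending)
      }
      pending <- labels[0, ]
      pred <- predict(model, std)
      rects <- build_rectangles(pred, rects,
                                beta_t(t, n, m, config), labels)
      skip <- classification_skip(state, rects, config)
      state <- epsilon_discard(state, rects, config$epsilon, skip)
      state <- epsilon_pareto_promote(state, rects, config$epsilon, skip)
      err <- hv_err(state)
      done <- length(state$unclassified) == 0L &&
        length(setdiff(state$pareto, state$sampled)) == 0L
      hv_hit <- !is.null(config$hv_stop) && is.finite(err) &&
        err <= config$hv_stop
      picks <- if (done || hv_hit) integer(0) else {
        acquisition(state, rects, config$batch_size, config$cv_tol,
                    exclude = failed)
      }
      new_labels <- NULL
      if (length(picks) > 0L) {
        new_labels <- query_oracle(oracle_fn, picks, m, sgn)
        newly_failed <- attr(new_labels, "failed")
        failed <- c(failed, newly_failed)
        state$sampled <- c(state$sampled, setdiff(picks, newly_failed))
        labels <- label_table(
          dplyr::bind_rows(as.data.frame(labels), as.data.frame(new_labels)), m)
        pending <- new_labels
      }
      if (track) {
        trace[[t]] <- list(
          iteration = t, widths = rects$upper - rects$lower,
          fallback = rects$fallback, pareto = state$pareto,
          discarded = state$discarded, sampled = picks)
      }
      history[[t + 1L]] <- tibble::tibble(
        iteration = t, sampled_ids = paste(picks, collapse = ";"),
        n_pareto = length(state$pareto),
        n_discarded = length(state$discarded),
        n_unclassified = length(state$unclassified),
        hypervolume_error = err, refit = refitted)
      if (done || hv_hit || length(picks) == 0L) {
        stopped <- TRUE
        break
      }
    }
  }
  # final retrain on all sampled points, including discarded ones
  if (!is.null(model)) {
    model <- update_surrogate(model, pending, force_refit = TRUE)
  }
  structure(list(
    state = state, history = dplyr::bind_rows(history), model = model,
    rectangles = rects, config = config, seed = seed,
    failed = failed, directions = sgn, trace = trace,
    natural_stop = stopped && length(state$unclassified) == 0L
  ), class = "epal_campaign")
}

design_features <- function(design) {
  if (is.matrix(design)) return(design)
  df <- as.data.frame(design)
  num <- vapply(df, is.numeric, logical(1))
  num[names(df) %in% c("id")] <- FALSE
  as.matrix(df[, num, drop = FALSE])
}

# Query the oracle for a set of candidates, orient values to maximization,
# and record candidates the oracle failed on (attribute "failed").
query_oracle <- function(oracle_fn, idx, m, sgn) {
  rows <- list()
  failed <- integer(0)
  for (i in idx) {
    res <- tryCatch(oracle_fn(i), error = function(e) NULL)
    if (is.null(res) || nrow(as.data.frame(res)) == 0L) {
      failed <- c(failed, i)
      next
    }
    res <- tibble::as_tibble(res)
    if (!"candidate" %in% names(res)) res$candidate <- i
    rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows) > 0L) dplyr::bind_rows(rows) else {
    tibble::tibble(candidate = integer(0), objective = integer(0),
                   value = numeric(0), noise_sd = numeric(0))
  }
  if (!"noise_sd" %in% names(out)) out$noise_sd <- NA_real_
  out$value <- out$value * sgn[out$objective]
  out <- label_table(out, m)
  attr(out, "failed") <- failed
  out
}

#' Wrap a complete label table as a campaign oracle
#'
#' @param labels Data frame with columns `candidate`, `objective`, `value`,
#'   optionally `noise_sd`; rows may be missing for unmeasurable
#'   (candidate, objective) pairs.
#' @return A function usable as the `oracle` argument of [run_campaign()].
#' @export
oracle_from_table <- function(labels) {
  labels <- tibble::as_tibble(labels)
  function(i) labels[labels$candidate == i, , drop = FALSE]
}

#' Wrap a vector-valued function as a campaign oracle
#'
#' @param f `function(i)` returning one numeric value per objective
#'   (natural orientation).
#' @param noise_sd Known measurement noise per objective reported alongside
#'   the values (0 = noiseless measurement).
#' @return A function usable as the `oracle` argument of [run_campaign()].
#' @export
oracle_from_function <- function(f, noise_sd = 0) {
  function(i) {
    v <- f(i)
    tibble::tibble(candidate = i, objective = seq_along(v), value = as.numeric(v),
                   noise_sd = rep_len(noise_sd, length(v)))
  }
}

#' @export
print.epal_campaign <- function(x, ...) {
  s <- x$state
  cat("epsilon-PAL campaign: ", max(x$history$iteration), " iterations\n",
      "  Pareto: ", length(s$pareto), "  discarded: ", length(s$discarded),
      "  unclassified: ", length(s$unclassified),
      "  sampled: ", length(s$sampled), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-candidate classification of a finished campaign
#'
#' @param x An `epal_campaign`.
#' @param ... Unused.
#' @return Tibble with one row per candidate: index, classification
#'   (`pareto` / `discarded` / `unclassified`), whether it was sampled, and
#'   the final rectangle bounds per objective (original orientation).
#' @export
tidy.epal_campaign <- function(x, ...) {
  n <- x$state$n
  cls <- rep("unclassified", n)
  cls[x$state$pareto] <- "pareto"
  cls[x$state$discarded] <- "discarded"
  out <- tibble::tibble(candidate = seq_len(n), classification = cls,
                        sampled = seq_len(n) %in% x$state$sampled)
  if (!is.null(x$rectangles)) {
    m <- ncol(x$rectangles$lower)
    for (o in seq_len(m)) {
      lo <- x$rectangles$lower[, o] * x$directions[o]
      hi <- x$rectangles$upper[, o] * x$directions[o]
      out[[paste0("lower_", o)]] <- pmin(lo, hi)
      out[[paste0("upper_", o)]] <- pmax(lo, hi)
    }
  }
  out
}

#' One-row summary of a finished campaign
#'
#' @inheritParams tidy.epal_campaign
#' @return Tibble with iteration count, set sizes, number of oracle
#'   evaluations, final hypervolume error (if tracked) and whether the
#'   campaign terminated naturally (all candidates classified).
#' @export
glance.epal_campaign <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    iterations = max(h$iteration),
    n_pareto = length(x$state$pareto),
    n_discarded = length(x$state$discarded),
    n_unclassified = length(x$state$unclassified),
    n_evaluations = length(x$state$sampled),
    hypervolume_error = h$hypervolume_error[nrow(h)],
    natural_stop = x$natural_stop
  )
}

#' Plot campaign progress
#'
#' Classified-set sizes per iteration and, when ground truth was supplied,
#' the hypervolume-error trajectory.
#'
#' @param object An `epal_campaign`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epal_campaign <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(
    h[, c("iteration", "n_pareto", "n_discarded", "n_unclassified")],
    -"iteration", names_to = "set", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$count,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "candidates",
                  title = "epsilon-PAL classification progress") +
    ggplot2::theme_minimal()
}

#' Plot a hypervolume-error trajectory
#'
#' @param object An `epal_campaign` run with ground truth.
#' @return A ggplot object.
#' @export
plot_hv_error <- function(object) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(.data$iteration, .data$hypervolume_error)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "hypervolume error") +
    ggplot2::theme_minimal()
}
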
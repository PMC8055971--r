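#' Assemble and validate a label table
#'
#' Long-format observation table for the surrogate: one row per measured
#' (candidate, objective) pair. A candidate may have any non-empty subset of
#' objectives labeled — this is how partially missing data enter the model.
#'
#' @param df Data frame with columns `candidate` (integer row index into the
#'   feature matrix), `objective` (integer in `1..n_objectives`), `value`
#'   (numeric), and optionally `noise_sd` (known measurement noise; `NA`
#'   means unknown, to be learned per objective).
#' @param n_objectives Total number of objectives.
#' @return A validated tibble with class `epal_label_table`.
#' @export
label_table <- function(df, n_objectives) {
  df <- tibble::as_tibble(df)
  req <- c("candidate", "objective", "value")
  if (!all(req %in% names(df))) {
    stop("label table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!"noise_sd" %in% names(df)) df$noise_sd <- NA_real_
  if (nrow(df) > 0L) {
    if (any(!is.finite(df$value))) stop("non-finite label values", call. = FALSE)
    if (any(df$objective < 1 | df$objective > n_objectives)) {
      stop("objective index out of range 1..", n_objectives, call. = FALSE)
    }
    if (anyDuplicated(df[, c("candidate", "objective")])) {
      stop("duplicate (candidate, objective) rows in label table", call. = FALSE)
    }
  }
  attr(df, "n_objectives") <- as.integer(n_objectives)
  class(df) <- c("epal_label_table", class(df))
  df
}

matern52 <- function(r) {
  s <- sqrt(5) * r
  (1 + s + s^2 / 3) * exp(-s)
}

# Coregionalization matrix B = W W' + diag(kappa) from the parameter vector.
icm_B <- function(theta, m, rank) {
  W <- matrix(theta$w, nrow = m, ncol = rank)
  tcrossprod(W) + diag(exp(theta$log_kappa), m)
}

unpack_theta <- function(par, m, rank) {
  i <- 0L
  take <- function(k) {
    out <- par[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  list(log_ell = take(1L), w = take(m * rank),
       log_kappa = take(m), log_noise = take(m))
}

# Negative log marginal likelihood of the stacked ICM model.
icm_nll <- function(par, D, obj_idx, y, fixed_nv, m, rank, jitter = 1e-6) {
  th <- unpack_theta(par, m, rank)
  B <- icm_B(th, m, rank)
  Kx <- matern52(D / exp(th$log_ell))
  K <- B[obj_idx, obj_idx] * Kx
  nv <- ifelse(is.na(fixed_nv), exp(2 * th$log_noise[obj_idx]), fixed_nv)
  diag(K) <- diag(K) + nv + jitter
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(L))) +
               0.5 * length(y) * log(2 * pi))
}

#' Fit a coregionalized Gaussian-process surrogate
#'
#' Intrinsic coregionalization model (ICM): all objectives are modeled as
#' scaled samples of shared latent Gaussian processes through the
#' coregionalization matrix `B = W W' + diag(kappa)` (rank = number of
#' latent functions, default 1), on a Matern-5/2 base kernel with a single
#' lengthscale. Observations are stacked `(feature vector, objective index)`
#' rows, so candidates with missing objectives simply contribute fewer rows,
#' and cross-objective correlations flow through `B`. Labels are z-scored
#' per objective internally and predictions are returned on the original
#' scale. Rows with a known `noise_sd` use it as fixed heteroscedastic
#' noise; other rows share a learned per-objective noise term.
#'
#' @param features Numeric matrix (candidates x feature dims), typically
#'   standardized (see [standardize_features()]).
#' @param labels An [label_table()] (or data frame coercible to one).
#' @param n_objectives Number of objectives.
#' @param rank Coregionalization rank (1 or 2; default 1).
#' @param n_restarts Random restarts for hyperparameter optimization; 0
#'   keeps the data-driven initial hyperparameters without optimization.
#' @param refit_every Full re-optimization fires after this many labels have
#'   been added through [update_surrogate()]; cheap conditioning otherwise.
#' @param seed Integer seed (restart initializations).
#' @param jitter Diagonal jitter for numerical stability.
#' @param theta Optional fixed hyperparameters on the original label scale
#'   (list with `log_ell`, `w`, `log_kappa`, `log_noise`): optimization is
#'   skipped, labels are centered per objective but not rescaled, and refits
#'   reduce to re-centering plus conditioning. Used when the generating
#'   kernel is known, e.g. when testing probabilistic guarantees on
#'   functions drawn from the model's own prior.
#' @return An object of class `epal_surrogate`.
#' @export
fit_surrogate <- function(features, labels, n_objectives,
                          rank = 1L, n_restarts = 5L, refit_every = 10L,
                          seed = 1L, jitter = 1e-6, theta = NULL) {
  features <- as.matrix(features)
  if (!inherits(labels, "epal_label_table")) {
    labels <- label_table(labels, n_objectives)
  }
  if (nrow(labels) == 0L) stop("no labels to fit on", call. = FALSE)
  model <- structure(list(
    features = features, labels = labels, m = as.integer(n_objectives),
    rank = as.integer(rank), n_restarts = as.integer(n_restarts),
    refit_every = as.integer(refit_every), seed = as.integer(seed),
    jitter = jitter, since_refit = 0L, fixed_theta = theta
  ), class = "epal_surrogate")
  refit(model)
}

# Full hyperparameter (re-)optimization + posterior cache.
refit <- function(model) {
  lab <- model$labels
  m <- model$m; rank <- model$rank
  if (!is.null(model$fixed_theta)) {
    centers <- vapply(seq_len(m), function(o) {
      v <- lab$value[lab$objective == o]
      if (length(v) > 0L) mean(v) else 0
    }, numeric(1))
    model$theta <- model$fixed_theta
    model$y_center <- centers
    model$y_scale <- rep(1, m)
    model$since_refit <- 0L
    return(condition_cache(model))
  }
  # per-objective z-scoring of labels
  centers <- scales <- rep(0, m); scales[] <- 1
  for (o in seq_len(m)) {
    v <- lab$value[lab$objective == o]
    if (length(v) > 0L) {
      centers[o] <- mean(v)
      s <- sqrt(mean((v - centers[o])^2))
      scales[o] <- if (is.finite(s) && s > 1e-12) s else 1
    }
  }
  obj_idx <- lab$objective
  y <- (lab$value - centers[obj_idx]) / scales[obj_idx]
  fixed_nv <- ifelse(is.na(lab$noise_sd), NA_real_,
                     (lab$noise_sd / scales[obj_idx])^2)
  X <- model$features[lab$candidate, , drop = FALSE]
  D <- cross_dist(X, X)
  med_d <- stats::median(D[upper.tri(D)])
  if (!is.finite(med_d) || med_d <= 0) med_d <- 1
  base <- c(log(med_d), rep(1, m * rank), rep(log(0.1), m), rep(log(0.1), m))
  lower <- c(log(1e-2), rep(-10, m * rank), rep(log(1e-6), m), rep(log(1e-4), m))
  upper <- c(log(1e3), rep(10, m * rank), rep(log(10), m), rep(log(10), m))
  nll <- function(par) icm_nll(par, D, obj_idx, y, fixed_nv, m, rank, model$jitter)
  best_par <- base
  best_val <- nll(base)
  if (model$n_restarts > 0L) {
    rng <- local_rng(derive_seed(model$seed, "hyperopt"))
    ok <- FALSE
    for (r in seq_len(model$n_restarts)) {
      init <- if (r == 1L) base else {
        pmin(pmax(base + rng$rnorm(length(base), sd = 0.7), lower), upper)
      }
      fit <- tryCatch(
        stats::optim(init, nll, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 60)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value)) {
        ok <- TRUE
        if (fit$value < best_val) {
          best_val <- fit$value
          best_par <- fit$par
        }
      }
    }
    if (!ok) {
      stop("hyperparameter optimization failed on all restarts (best nll ",
           signif(best_val, 6), ")", call. = FALSE)
    }
  }
  model$theta <- unpack_theta(best_par, m, rank)
  model$nll <- best_val
  model$y_center <- centers
  model$y_scale <- scales
  model$since_refit <- 0L
  condition_cache(model)
}

# Recompute the posterior cache (chol factor + weights) at the current
# hyperparameters; used after both refits and cheap updates.
condition_cache <- function(model) {
  lab <- model$labels
  th <- model$theta
  m <- model$m
  obj_idx <- lab$objective
  y <- (lab$value - model$y_center[obj_idx]) / model$y_scale[obj_idx]
  fixed_nv <- ifelse(is.na(lab$noise_sd), NA_real_,
                     (lab$noise_sd / model$y_scale[obj_idx])^2)
  X <- model$features[lab$candidate, , drop = FALSE]
  B <- icm_B(th, m, model$rank)
  K <- B[obj_idx, obj_idx] * matern52(cross_dist(X, X) / exp(th$log_ell))
  nv <- ifelse(is.na(fixed_nv), exp(2 * th$log_noise[obj_idx]), fixed_nv)
  diag(K) <- diag(K) + nv + model$jitter
  L <- chol(K) # upper triangular
  model$cache <- list(
    L = L,
    alpha = backsolve(L, forwardsolve(t(L), y)),
    X = X, obj_idx = obj_idx, B = B
  )
  model
}

#' Predict objective means and standard deviations
#'
#' Posterior mean and standard deviation of the latent objective functions
#' for every query candidate and every objective, de-standardized to the
#' original objective scale.
#'
#' @param object A fitted `epal_surrogate`.
#' @param features Query feature matrix (same columns as training).
#' @param ... Unused.
#' @return List with matrices `mean` and `sd` (`n_query x n_objectives`).
#' @export
predict.epal_surrogate <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != ncol(object$features)) {
    stop("feature dimension mismatch: model has ", ncol(object$features),
         ", query has ", ncol(features), call. = FALSE)
  }
  m <- object$m
  ca <- object$cache
  nq <- nrow(features)
  Kx <- matern52(cross_dist(features, ca$X) / exp(object$theta$log_ell))
  mean_m <- sd_m <- matrix(0, nq, m)
  for (o in seq_len(m)) {
    Ks <- Kx * rep(ca$B[o, ca$obj_idx], each = nq)
    mean_o <- as.numeric(Ks %*% ca$alpha)
    v <- forwardsolve(t(ca$L), t(Ks))
    var_o <- pmax(ca$B[o, o] - colSums(v^2), 1e-12)
    mean_m[, o] <- mean_o * object$y_scale[o] + object$y_center[o]
    sd_m[, o] <- sqrt(var_o) * object$y_scale[o]
  }
  list(mean = mean_m, sd = sd_m)
}

#' Add observations to a fitted surrogate
#'
#' Extends the training set with new (candidate, objective) rows. Full
#' hyperparameter re-optimization fires once at least `refit_every` labels
#' have accumulated since the last refit (or when `force_refit = TRUE`);
#' otherwise the posterior is re-conditioned at fixed hyperparameters, which
#' is cheap and can only shrink predictive variance.
#'
#' @param model A fitted `epal_surrogate`.
#' @param new_rows Label table (or data frame) of new observations, disjoint
#'   from the existing (candidate, objective) pairs.
#' @param force_refit Re-optimize hyperparameters regardless of the schedule.
#' @return The updated `epal_surrogate`.
#' @export
update_surrogate <- function(model, new_rows, force_refit = FALSE) {
  if (!inherits(new_rows, "epal_label_table")) {
    new_rows <- label_table(new_rows, model$m)
  }
  if (nrow(new_rows) == 0L && !force_refit) return(model)
  key_old <- paste(model$labels$candidate, model$labels$objective)
  key_new <- paste(new_rows$candidate, new_rows$objective)
  if (any(key_new %in% key_old)) {
    stop("duplicate (candidate, objective) pairs in update", call. = FALSE)
  }
  model$labels <- label_table(
    dplyr::bind_rows(as.data.frame(model$labels), as.data.frame(new_rows)),
    model$m)
  model$since_refit <- model$since_refit + nrow(new_rows)
  if (force_refit || model$since_refit >= model$refit_every) {
    refit(model)
  } else {
    condition_cache(model)
  }
}

#' @export
print.epal_surrogate <- function(x, ...) {
  cat("ICM Gaussian-process surrogate (Matern-5/2, rank ", x$rank, ")\n",
      "  objectives: ", x$m, ", labels: ", nrow(x$labels),
      ", lengthscale: ", signif(exp(x$theta$log_ell), 4), "\n", sep = "")
  invisible(x)
}
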
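# ---- hand-rolled least-squares gradient boosting --------------------------
# No tree package ships with this stack, so the distillation regressor is a
# small greedy CART-style booster: depth-limited regression trees fit to
# residuals with shrinkage.

# Best single split of (x, grad) by SSE reduction; returns NULL if no split
# with both sides >= min_node exists.
best_split <- function(X, r, rows, min_node) {
  n <- length(rows)
  if (n < 2L * min_node) return(NULL)
  best <- NULL
  base_sse <- sum((r[rows] - mean(r[rows]))^2)
  for (j in seq_len(ncol(X))) {
    x <- X[rows, j]
    ord <- order(x)
    xs <- x[ord]
    rs <- r[rows][ord]
    csum <- cumsum(rs)
    csq <- cumsum(rs^2)
    tot <- csum[n]
    totsq <- csq[n]
    k <- seq_len(n - 1L)
    valid <- k >= min_node & (n - k) >= min_node & xs[k] < xs[k + 1L]
    if (!any(valid)) next
    sse <- (csq[k] - csum[k]^2 / k) +
      ((totsq - csq[k]) - (tot - csum[k])^2 / (n - k))
    sse[!valid] <- Inf
    kb <- which.min(sse)
    if (sse[kb] < (best$sse %||% base_sse) - 1e-12) {
      best <- list(feature = j, threshold = (xs[kb] + xs[kb + 1L]) / 2,
                   sse = sse[kb])
    }
  }
  best
}

grow_tree <- function(X, r, rows, depth, min_node) {
  sp <- if (depth > 0L) best_split(X, r, rows, min_node) else NULL
  if (is.null(sp)) {
    return(list(leaf = TRUE, value = mean(r[rows])))
  }
  left <- rows[X[rows, sp$feature] <= sp$threshold]
  right <- setdiff(rows, left)
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree(X, r, left, depth - 1L, min_node),
       right = grow_tree(X, r, right, depth - 1L, min_node))
}

predict_tree <- function(tree, X, rows = seq_len(nrow(X))) {
  out <- numeric(nrow(X))
  rec <- function(node, rows) {
    if (length(rows) == 0L) return()
    if (node$leaf) {
      out[rows] <<- node$value
      return()
    }
    go_left <- X[rows, node$feature] <= node$threshold
    rec(node$left, rows[go_left])
    rec(node$right, rows[!go_left])
  }
  rec(tree, rows)
  out
}

gbt_fit <- function(X, y, n_trees = 150L, depth = 3L, shrinkage = 0.1,
                    min_node = 5L) {
  X <- as.matrix(X)
  f0 <- mean(y)
  pred <- rep(f0, length(y))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    tree <- grow_tree(X, y - pred, seq_len(nrow(X)), depth, min_node)
    trees[[t]] <- tree
    pred <- pred + shrinkage * predict_tree(tree, X)
  }
  structure(list(f0 = f0, trees = trees, shrinkage = shrinkage,
                 r_squared = 1 - sum((y - pred)^2) / sum((y - mean(y))^2)),
            class = "epal_gbt")
}

#' @export
predict.epal_gbt <- function(object, X, ...) {
  X <- as.matrix(X)
  pred <- rep(object$f0, nrow(X))
  for (tree in object$trees) {
    pred <- pred + object$shrinkage * predict_tree(tree, X)
  }
  pred
}

# ---- distillation ---------------------------------------------------------

#' Distill a GP surrogate into a fast tree regressor
#'
#' Fits a gradient-boosted regression tree on the GP's predicted means over
#' the design space, using only the reduced invertible feature schema (the
#' relative sequence entropy and the non-invertible run statistics are
#' dropped), so the genetic algorithm can both evaluate candidates cheaply
#' and decode its proposals back to sequences.
#'
#' @param model A fitted `epal_surrogate` trained during a campaign
#'   (its stored feature matrix is the full design space).
#' @param design Design tibble from [full_factorial_design()] providing the
#'   reduced feature columns.
#' @param objective_index Objective to distill (maximization orientation as
#'   used inside the campaign), or a numeric weight vector over all
#'   objectives for a scalarized target.
#' @param seed Unused randomness hook (the booster is deterministic); kept
#'   for interface stability.
#' @return List of class `epal_distilled`: the booster, the reduced feature
#'   names, and the training `r_squared` against the GP means.
#' @export
distill_surrogate <- function(model, design, objective_index = 1L, seed = 1L) {
  red <- feature_names(reduced = TRUE)
  X <- as.matrix(as.data.frame(design)[, red])
  pred <- predict(model, model$features)
  target <- if (length(objective_index) == 1L) {
    pred$mean[, objective_index]
  } else {
    as.numeric(pred$mean %*% objective_index)
  }
  if (stats::sd(target) < 1e-10) {
    stop("GP predicted means are constant; nothing to distill", call. = FALSE)
  }
  booster <- gbt_fit(X, target)
  structure(list(booster = booster, features = red,
                 r_squared = booster$r_squared,
                 objective_index = objective_index),
            class = "epal_distilled")
}

#' @export
predict.epal_distilled <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else {
    as.matrix(as.data.frame(newdata)[, object$features])
  }
  predict(object$booster, X)
}

# ---- GA -------------------------------------------------------------------

#' Configuration of the elitist genetic algorithm
#'
#' @param population_size,generations GA size parameters.
#' @param elitist_ratio Fraction of the population copied unchanged into the
#'   next generation (at least one individual).
#' @param novelty_weight Weight of the similarity-to-dataset penalty
#'   (0 = pure objective; the protocol sweep uses 0, 1, 10 and 50 times the
#'   objective scale).
#' @param invalid_penalty Penalty subtracted when a feature vector cannot be
#'   decoded to a valid sequence.
#' @param mutation_rate,crossover_rate Per-gene mutation probability and
#'   per-pair crossover probability.
#' @param novelty_lengthscale Lengthscale of the similarity kernel
#'   `exp(-d^2 / l^2)` on standardized reduced features.
#' @param n_decodes_per_vector Sequences decoded per final feature vector (a
#'   vector does not map to a unique arrangement).
#' @param seed Integer seed.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population_size = 60L, generations = 40L,
                      elitist_ratio = 0.1, novelty_weight = 0,
                      invalid_penalty = 10, mutation_rate = 0.15,
                      crossover_rate = 0.9, novelty_lengthscale = 1,
                      n_decodes_per_vector = 3L, seed = 1L) {
  stopifnot(elitist_ratio > 0, elitist_ratio < 1,
            ceiling(elitist_ratio * population_size) >= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 elitist_ratio = elitist_ratio,
                 novelty_weight = novelty_weight,
                 invalid_penalty = invalid_penalty,
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 novelty_lengthscale = novelty_lengthscale,
                 n_decodes_per_vector = as.integer(n_decodes_per_vector),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Evolve integer genomes with an elitist GA
#'
#' Tournament selection (size 3), uniform crossover, bounded integer
#' mutation (+/- steps clamped to bounds), and elitism: the top
#' `ceiling(elitist_ratio * population_size)` individuals are copied
#' unchanged each generation, so the best fitness is monotone
#' non-decreasing. Deterministic given the config seed.
#'
#' @param config A [ga_config()].
#' @param fitness_fn `function(genome)` returning a finite scalar to
#'   maximize.
#' @param bounds List with integer vectors `lower` and `upper`
#'   (per-gene inclusive ranges).
#' @return List: `population` (matrix, rows sorted by decreasing fitness),
#'   `fitness` (sorted), `best_trace` (best fitness per generation,
#'   including the initial population).
#' @export
evolve <- function(config, fitness_fn, bounds) {
  lower <- as.integer(bounds$lower)
  upper <- as.integer(bounds$upper)
  if (any(lower > upper)) stop("infeasible bounds", call. = FALSE)
  g <- length(lower)
  rng <- local_rng(derive_seed(config$seed, "evolve"))
  np <- config$population_size
  pop <- sapply(seq_len(g), function(j) {
    lower[j] + rng$sample_int(upper[j] - lower[j] + 1L, np, replace = TRUE) - 1L
  })
  pop <- matrix(as.integer(pop), nrow = np)
  fit <- apply(pop, 1L, fitness_fn)
  ord <- order(-fit)
  pop <- pop[ord, , drop = FALSE]
  fit <- fit[ord]
  n_elite <- ceiling(config$elitist_ratio * np)
  best_trace <- fit[1L]
  if (config$generations > 0L) {
    for (gen in seq_len(config$generations)) {
      children <- matrix(0L, np - n_elite, g)
      for (c_i in seq_len(nrow(children))) {
        i1 <- min(rng$sample_int(np, 3L))
        i2 <- min(rng$sample_int(np, 3L)) # rank order => lower index is fitter
        p1 <- pop[i1, ]
        p2 <- pop[i2, ]
        child <- if (rng$runif(1L) < config$crossover_rate) {
          ifelse(rng$runif(g) < 0.5, p1, p2)
        } else p1
        mut <- rng$runif(g) < config$mutation_rate
        if (any(mut)) {
          step <- rng$sample(c(-2L, -1L, 1L, 2L), sum(mut), replace = TRUE)
          child[mut] <- pmin(pmax(child[mut] + step, lower[mut]), upper[mut])
        }
        children[c_i, ] <- as.integer(child)
      }
      pop <- rbind(pop[seq_len(n_elite), , drop = FALSE], children)
      fit <- c(fit[seq_len(n_elite)], apply(children, 1L, fitness_fn))
      ord <- order(-fit)
      pop <- pop[ord, , drop = FALSE]
      fit <- fit[ord]
      best_trace <- c(best_trace, fit[1L])
    }
  }
  list(population = pop, fitness = fit, best_trace = best_trace)
}

# ---- polymer-specific plumbing -------------------------------------------

# Genome layout for sequence inversion: four bead counts, head type index,
# tail type index, total run count. Count ranges default to the per-type
# ranges observed in the design set (the GA searches new sequences within
# the DoE composition hull).
genome_bounds <- function(count_lower = rep(0L, 4L),
                          count_upper = rep(12L, 4L),
                          max_runs = sum(count_upper)) {
  list(lower = c(as.integer(count_lower), 1L, 1L, 1L),
       upper = c(as.integer(count_upper), 4L, 4L, as.integer(max_runs)))
}

genome_to_features <- function(genome,
                               interaction_table = default_interaction_table()) {
  ab <- monomer_alphabet()
  counts <- stats::setNames(as.numeric(genome[1:4]), ab)
  v <- c(sum(counts),
         as.numeric(seq_len(4L) == genome[5L]),
         as.numeric(seq_len(4L) == genome[6L]),
         counts,
         sum(counts * interaction_table[ab]),
         genome[7L])
  stats::setNames(v, feature_names(reduced = TRUE))
}

#' GA fitness of a candidate feature vector
#'
#' `objective - novelty_weight * similarity - invalid_penalty * [INVALID]`:
#' the distilled regressor's prediction, minus a similarity-to-dataset
#' penalty `exp(-d^2 / l^2)` (d = minimum Euclidean distance to the design
#' set in standardized reduced-feature space), minus a flat penalty when the
#' vector cannot be decoded into a sequence.
#'
#' @param fv Named reduced feature vector (see
#'   `feature_names(reduced = TRUE)`).
#' @param regressor An `epal_distilled` model (or anything with a `predict`
#'   method on reduced features).
#' @param dataset_std List from [standardize_features()] applied to the
#'   design set's reduced features.
#' @param config A [ga_config()].
#' @param decode_seed Seed for the validity decode.
#' @return Finite scalar fitness.
#' @export
ga_fitness <- function(fv, regressor, dataset_std, config, decode_seed = 1L) {
  obj <- predict(regressor, matrix(fv, nrow = 1L,
                                   dimnames = list(NULL, names(fv))))
  pen <- 0
  if (config$novelty_weight > 0) {
    z <- (fv - dataset_std$center) / dataset_std$scale
    z[attr(dataset_std$scale, "constant")] <- 0
    d2 <- min(rowSums(sweep(dataset_std$standardized, 2L, z)^2))
    pen <- config$novelty_weight * exp(-d2 / config$novelty_lengthscale^2)
  }
  invalid <- is.na(backtrace_sequence(fv, max_tries = 50L, seed = decode_seed))
  as.numeric(obj - pen - invalid * config$invalid_penalty)
}

#' Invert a trained surrogate with the elitist GA
#'
#' Distills the requested objective (or a weighted sum) of the GP into a
#' fast tree regressor on the invertible feature schema, evolves integer
#' feature genomes against it, and decodes the top vectors into candidate
#' sequences.
#'
#' @param model A fitted `epal_surrogate` from a campaign over `design`.
#' @param design The design tibble the campaign ran on.
#' @param objective_index Objective to maximize (internal maximization
#'   orientation), or a weight vector for scalarization.
#' @param config A [ga_config()].
#' @param top_k Number of distinct top feature vectors to decode.
#' @return List of class `epal_inversion`: `distilled`, `ga` (the
#'   [evolve()] result), and `proposals` — a tibble of decoded sequences
#'   with predicted objective values and validity flags.
#' @export
invert_surrogate <- function(model, design, objective_index = 1L,
                             config = ga_config(), top_k = 10L) {
  distilled <- distill_surrogate(model, design, objective_index)
  red <- feature_names(reduced = TRUE)
  ds_red <- as.matrix(as.data.frame(design)[, red])
  ds_std <- standardize_features(ds_red)
  counts <- ds_red[, paste0("count_", monomer_alphabet()), drop = FALSE]
  bounds <- genome_bounds(count_lower = apply(counts, 2L, min),
                          count_upper = apply(counts, 2L, max))
  fitness_fn <- function(genome) {
    ga_fitness(genome_to_features(genome), distilled, ds_std, config,
               decode_seed = derive_seed(config$seed, sum(genome * seq_along(genome))))
  }
  ga <- evolve(config, fitness_fn, bounds)
  uniq <- !duplicated(ga$population)
  top <- ga$population[uniq, , drop = FALSE]
  top <- top[seq_len(min(top_k, nrow(top))), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(top))) {
    fv <- genome_to_features(top[i, ])
    for (d in seq_len(config$n_decodes_per_vector)) {
      s <- backtrace_sequence(fv, max_tries = 200L,
                              seed = derive_seed(config$seed, i * 1000L + d))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        vector_rank = i, decode = d, sequence = s, valid = !is.na(s),
        predicted = predict(distilled,
                            matrix(fv, nrow = 1L,
                                   dimnames = list(NULL, names(fv))))[1L])
    }
  }
  structure(list(distilled = distilled, ga = ga,
                 proposals = dplyr::bind_rows(rows), config = config),
            class = "epal_inversion")
}

#' Evaluate GA proposals against the design-of-experiments front
#'
#' Runs the oracle on each decoded sequence and flags any proposal that
#' Pareto-dominates a member of the known front. Distribution summaries of
#' the evaluated properties are returned alongside.
#'
#' @param proposals Tibble with a `sequence` column (invalid rows, `NA`
#'   sequence, are skipped), e.g. from [invert_surrogate()].
#' @param oracle `function(sequence)` returning the natural-orientation
#'   objective vector (typically [pseudo_simulate()] noiseless).
#' @param doe_front Objective matrix of the campaign's front, natural
#'   orientation.
#' @param directions Per-objective `"maximize"` / `"minimize"`.
#' @return List of class `epal_discovery_report`: `evaluated` (tibble with
#'   objective values and `dominates_front`), `n_dominating`, and `summary`
#'   (per-objective distribution stats).
#' @export
evaluate_discoveries <- function(proposals, oracle, doe_front, directions) {
  proposals <- tibble::as_tibble(proposals)
  valid <- proposals[!is.na(proposals$sequence), , drop = FALSE]
  sgn <- ifelse(directions == "minimize", -1, 1)
  front_or <- sweep(as.matrix(doe_front), 2L, sgn, "*")
  if (nrow(valid) == 0L) {
    return(structure(list(
      evaluated = tibble::tibble(sequence = character(0)),
      n_dominating = 0L, summary = tibble::tibble()),
      class = "epal_discovery_report"))
  }
  vals <- t(vapply(valid$sequence, oracle, numeric(ncol(front_or)),
                   USE.NAMES = FALSE))
  vals_or <- sweep(vals, 2L, sgn, "*")
  dom <- vapply(seq_len(nrow(vals_or)), function(i) {
    any(vapply(seq_len(nrow(front_or)), function(j) {
      dominates(vals_or[i, ], front_or[j, ])
    }, logical(1)))
  }, logical(1))
  evaluated <- dplyr::bind_cols(
    valid,
    tibble::as_tibble(as.data.frame(vals, col.names = colnames(front_or))),
    tibble::tibble(dominates_front = dom))
  obj_names <- colnames(vals) %||% paste0("objective_", seq_len(ncol(vals)))
  summary <- tibble::tibble(
    objective = obj_names,
    mean = colMeans(vals),
    sd = apply(vals, 2L, stats::sd),
    min = apply(vals, 2L, min),
    max = apply(vals, 2L, max))
  structure(list(evaluated = evaluated, n_dominating = sum(dom),
                 summary = summary),
            class = "epal_discovery_report")
}

#' @export
print.epal_discovery_report <- function(x, ...) {
  cat("GA discovery report: ", nrow(x$evaluated), " evaluated proposals, ",
      x$n_dominating, " dominate the DoE front\n", sep = "")
  invisible(x)
}
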
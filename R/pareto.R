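#' Pareto dominance between two objective vectors
#'
#' All objectives are oriented as maximization: `a` dominates `b` when it is
#' at least as good everywhere and strictly better somewhere.
#'
#' @param a,b Numeric vectors of equal length (one entry per objective).
#' @return `TRUE` iff `a >= b` elementwise with `a > b` in at least one
#'   coordinate. Irreflexive: `dominates(a, a)` is `FALSE`.
#' @export
#' @examples
#' dominates(c(2, 2), c(1, 1)) # TRUE
#' dominates(c(2, 0), c(1, 1)) # FALSE (incomparable)
dominates <- function(a, b) {
  if (length(a) != length(b)) {
    stop("objective vectors have different lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  all(a >= b) && any(a > b)
}

#' Mean-scaled epsilon-dominance
#'
#' `a` epsilon-dominates `b` when inflating each of `a`'s objectives by
#' `epsilon[i] * scale[i]` makes it at least as good as `b` everywhere.
#' The scale is typically `|mu|`, the absolute predicted mean, giving the
#' mean-scaled tolerance used throughout the active-learning loop.
#'
#' @param a,b Numeric objective vectors (maximization orientation).
#' @param epsilon Per-objective tolerance fractions (recycled if scalar).
#' @param scale Per-objective scale, typically `abs(mu)` (recycled if scalar).
#' @return Logical scalar.
#' @export
epsilon_dominates <- function(a, b, epsilon, scale = 1) {
  if (length(a) != length(b)) {
    stop("objective vectors have different lengths", call. = FALSE)
  }
  epsilon <- rep_len(epsilon, length(a))
  scale <- rep_len(scale, length(a))
  all(a + epsilon * abs(scale) >= b)
}

#' Identify Pareto-optimal rows of an objective matrix
#'
#' Exactly tied rows (identical objective vectors) are all kept
#' Pareto-optimal: neither dominates the other under strict dominance.
#'
#' @param points Numeric matrix or data frame, one row per candidate, one
#'   column per objective, all oriented as maximization.
#' @param method `"fast"` (sort-based prefilter, default) or `"reference"`
#'   (the plain O(n^2) double loop, kept as an independent oracle).
#' @return Logical vector, `TRUE` for non-dominated rows.
#' @export
#' @examples
#' pareto_mask(rbind(c(0, 1), c(1, 0), c(0.5, 0.5))) # all TRUE
pareto_mask <- function(points, method = c("fast", "reference")) {
  method <- match.arg(method)
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 1L) stop("need at least one point", call. = FALSE)
  if (n == 1L) return(TRUE)
  if (method == "reference") return(pareto_mask_reference(pts))
  # Sort lexicographically descending; a point can only be dominated by an
  # earlier point in this order, so sweep once keeping the running survivors.
  ord <- do.call(order, c(lapply(seq_len(ncol(pts)), function(j) -pts[, j])))
  sorted <- pts[ord, , drop = FALSE]
  keep <- rep(TRUE, n)
  front <- matrix(numeric(0), ncol = ncol(pts))
  for (i in seq_len(n)) {
    p <- sorted[i, ]
    if (nrow(front) > 0L) {
      geq <- front >= rep(p, each = nrow(front))
      gt <- front > rep(p, each = nrow(front))
      if (any(rowSums(geq) == ncol(pts) & rowSums(gt) > 0L)) {
        keep[i] <- FALSE
        next
      }
    }
    front <- rbind(front, p)
  }
  out <- logical(n)
  out[ord] <- keep
  out
}

# O(n^2) reference implementation; the independent oracle for the fast path.
pareto_mask_reference <- function(pts) {
  n <- nrow(pts)
  mask <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(pts[j, ], pts[i, ])) {
        mask[i] <- FALSE
        break
      }
    }
  }
  mask
}

#' Exact hypervolume indicator (up to three objectives)
#'
#' Lebesgue measure of the union of boxes spanned between a reference point
#' and each front member, all objectives oriented as maximization. Exact via
#' a dimension sweep for d <= 3; higher dimensions fall back to the
#' Monte-Carlo estimator with a warning.
#'
#' @param front Numeric matrix (rows = points, columns = objectives) or a
#'   single vector. Dominated members are allowed; they contribute nothing.
#' @param ref Reference point, dominated by every front member.
#' @param n_samples,seed Monte-Carlo settings for the d > 3 fallback.
#' @return Hypervolume as a single number; 0 for an empty front.
#' @export
#' @examples
#' hypervolume(c(1, 1), c(0, 0)) # 1
#' hypervolume(rbind(c(1, 2), c(2, 1)), c(0, 0)) # 3
hypervolume <- function(front, ref, n_samples = 100000L, seed = 1L) {
  if (is.null(dim(front))) front <- matrix(front, nrow = length(front) > 0L)
  front <- as.matrix(front)
  if (nrow(front) == 0L) return(0)
  d <- ncol(front)
  if (length(ref) != d) stop("reference point dimension mismatch", call. = FALSE)
  bad <- which(!apply(front, 1L, function(p) all(p >= ref)))
  if (length(bad) > 0L) {
    stop("front point(s) ", paste(bad, collapse = ", "),
         " do not dominate the reference point", call. = FALSE)
  }
  if (d > 3L) {
    warning("exact hypervolume implemented for d <= 3; using Monte-Carlo")
    return(hypervolume_mc(front, ref, n_samples = n_samples, seed = seed)$estimate)
  }
  if (d == 1L) return(max(front[, 1L]) - ref[1L])
  if (d == 2L) return(hv2d(front, ref))
  hv3d(front, ref)
}

# 2-D sweep: descending in objective 1, accumulate strips of new objective-2
# coverage.
hv2d <- function(front, ref) {
  ord <- order(-front[, 1L], -front[, 2L])
  pts <- front[ord, , drop = FALSE]
  hv <- 0
  y_cov <- ref[2L]
  for (i in seq_len(nrow(pts))) {
    if (pts[i, 2L] > y_cov) {
      hv <- hv + (pts[i, 1L] - ref[1L]) * (pts[i, 2L] - y_cov)
      y_cov <- pts[i, 2L]
    }
  }
  hv
}

# 3-D by slicing along objective 3: each slab's cross-section is the 2-D
# hypervolume of the points reaching at least that high.
hv3d <- function(front, ref) {
  z <- sort(unique(front[, 3L]), decreasing = TRUE)
  levels <- c(z, ref[3L])
  hv <- 0
  for (k in seq_along(z)) {
    hi <- levels[k]
    lo <- max(levels[k + 1L], ref[3L])
    if (hi <= lo) next
    in_slab <- front[, 3L] >= hi
    hv <- hv + (hi - lo) * hv2d(front[in_slab, 1:2, drop = FALSE], ref[1:2])
  }
  hv
}

#' Monte-Carlo hypervolume estimate
#'
#' Uniform sampling in the bounding box between `ref` and the front's
#' coordinate-wise maximum; the dominated fraction times the box volume
#' estimates the hypervolume. Serves as an independent check on the exact
#' algorithm and as the d > 3 fallback.
#'
#' @inheritParams hypervolume
#' @param n_samples Number of uniform samples.
#' @param seed Integer seed; the estimate is deterministic given it.
#' @return A list with `estimate` and `se` — the binomial standard error
#'   scaled by the box volume, computed from a Laplace-smoothed hit
#'   fraction so that estimates at the 0/1 boundary do not claim false
#'   certainty.
#' @export
hypervolume_mc <- function(front, ref, n_samples = 100000L, seed = 1L) {
  if (is.null(dim(front))) front <- matrix(front, nrow = length(front) > 0L)
  front <- as.matrix(front)
  if (nrow(front) == 0L) return(list(estimate = 0, se = 0))
  d <- ncol(front)
  upper <- apply(front, 2L, max)
  vol <- prod(upper - ref)
  if (vol <= 0) return(list(estimate = 0, se = 0))
  rng <- local_rng(seed)
  u <- matrix(rng$runif(n_samples * d), ncol = d)
  samp <- sweep(sweep(u, 2L, upper - ref, "*"), 2L, ref, "+")
  hit <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(front))) {
    cand <- !hit
    if (!any(cand)) break
    ok <- rowSums(samp[cand, , drop = FALSE] <=
                    rep(front[i, ], each = sum(cand))) == d
    hit[cand] <- ok
  }
  p <- mean(hit)
  p_sm <- (sum(hit) + 1) / (n_samples + 2)
  list(estimate = p * vol, se = sqrt(p_sm * (1 - p_sm) / n_samples) * vol)
}

#' Nadir point of a set of objective vectors
#'
#' The coordinate-wise minimum over the Pareto-optimal subset (maximization
#' orientation); dominated points do not influence it. The canonical
#' hypervolume reference point.
#'
#' @inheritParams pareto_mask
#' @return Numeric vector, one entry per objective.
#' @export
nadir_point <- function(points) {
  pts <- as.matrix(points)
  mask <- pareto_mask(pts)
  apply(pts[mask, , drop = FALSE], 2L, min)
}

#' Relative hypervolume error of a candidate front
#'
#' `(HV_max - HV_current) / HV_max`, where `HV_max` is the hypervolume of the
#' true Pareto subset of the full design space and both are measured from the
#' same reference point (the full space's nadir by default). Front members
#' falling below the reference point in some objective contribute only their
#' clipped-to-reference part, as is standard for nadir-referenced indicators.
#'
#' @param current_front Objective matrix of the candidate front (may be
#'   empty: a zero-row matrix gives error 1).
#' @param full_space Objective matrix of the entire design space.
#' @param ref Reference point; defaults to `nadir_point(full_space)`.
#' @return Relative error in `[0, 1]`.
#' @export
hypervolume_error <- function(current_front, full_space, ref = NULL) {
  full_space <- as.matrix(full_space)
  if (is.null(ref)) ref <- nadir_point(full_space)
  truth <- full_space[pareto_mask(full_space), , drop = FALSE]
  hv_max <- hypervolume(truth, ref)
  if (hv_max <= 0) stop("maximum hypervolume is zero; reference point ill-posed",
                        call. = FALSE)
  cf <- as.matrix(current_front)
  if (length(cf) == 0L || nrow(cf) == 0L) return(1)
  # clip to the reference so points outside the reference box are usable
  cf <- pmax(cf, rep(ref, each = nrow(cf)))
  keep <- apply(cf, 1L, function(p) any(p > ref))
  cf <- cf[keep, , drop = FALSE]
  if (nrow(cf) == 0L) return(1)
  (hv_max - hypervolume(cf, ref)) / hv_max
}
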
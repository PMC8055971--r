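#' The coarse-grained monomer alphabet
#'
#' Four bead types describing solvent and surface interactions of a
#' coarse-grained dispersant copolymer: `W` behaves as in a good solvent,
#' `R` as in a bad solvent, and `Ta` / `Tr` as in a theta solvent but with
#' different surface affinities.
#'
#' @return Character vector `c("W", "R", "Ta", "Tr")` in canonical order.
#' @export
monomer_alphabet <- function() c("W", "R", "Ta", "Tr")

#' Convert between bead vectors and bracket notation
#'
#' Sequences are serialized as e.g. `"[W][R][Ta]"`; the bracket string is
#' also the sequence's stable identifier (collisions are impossible by
#' construction).
#'
#' @param beads Character vector of bead symbols.
#' @param x A bracket-notation string.
#' @return `format_sequence()` a string; `parse_sequence()` a character
#'   vector of bead symbols.
#' @export
format_sequence <- function(beads) {
  bad <- setdiff(unique(beads), monomer_alphabet())
  if (length(bad) > 0L) {
    stop("unknown monomer symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  paste0("[", beads, "]", collapse = "")
}

#' @rdname format_sequence
#' @export
parse_sequence <- function(x) {
  stopifnot(length(x) == 1L, is.character(x))
  beads <- regmatches(x, gregexpr("\\[([^]]+)\\]", x))[[1]]
  beads <- gsub("\\[|\\]", "", beads)
  if (length(beads) == 0L) stop("empty or unparseable sequence: ", x, call. = FALSE)
  bad <- setdiff(unique(beads), monomer_alphabet())
  if (length(bad) > 0L) {
    stop("unknown monomer symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  beads
}

# Named count vector over the full alphabet (zeros included).
sequence_composition <- function(beads) {
  counts <- table(factor(beads, levels = monomer_alphabet()))
  stats::setNames(as.integer(counts), monomer_alphabet())
}

#' Draw a random arrangement of a monomer composition
#'
#' Uniformly shuffles the multiset of beads given by `composition`.
#'
#' @param composition Named integer vector (names from
#'   [monomer_alphabet()]), non-negative counts summing to at least 1.
#' @param seed Integer seed; deterministic given it.
#' @return A bracket-notation sequence string.
#' @export
#' @examples
#' random_sequence(c(W = 2, R = 2), seed = 1)
random_sequence <- function(composition, seed = 1L) {
  composition <- composition[composition > 0]
  if (length(composition) == 0L || sum(composition) < 1) {
    stop("composition must contain at least one bead", call. = FALSE)
  }
  bad <- setdiff(names(composition), monomer_alphabet())
  if (length(bad) > 0L) {
    stop("unknown monomer symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  beads <- rep(names(composition), times = composition)
  rng <- local_rng(seed)
  format_sequence(beads[rng$sample_int(length(beads))])
}

#' Full-factorial polymer design space
#'
#' Crosses every level (bead count) of every factor (bead type) and expands
#' each composition into `sequences_per_point` distinct random monomer
#' arrangements. With the default settings of 4 factors, levels
#' \{4, 6, 8, 10, 12\} and 5 sequences per design point this yields the
#' 3125-polymer design space.
#'
#' @param levels Integer vector of possible bead counts per type.
#' @param n_factors Number of bead types used (first `n_factors` of
#'   [monomer_alphabet()]); the remaining types get count 0.
#' @param sequences_per_point Distinct random arrangements per composition.
#' @param seed Integer master seed.
#' @param interaction_table Named per-bead interaction parameters used by
#'   [featurize()]; see [default_interaction_table()].
#' @param featurize If `TRUE` (default) the returned tibble carries one
#'   column per feature next to `id` and `sequence`.
#' @return A tibble with `length(levels)^n_factors * sequences_per_point`
#'   rows: columns `id`, `sequence`, the four bead counts, and (optionally)
#'   the feature columns.
#' @export
#' @examples
#' ds <- full_factorial_design(c(4, 6), n_factors = 2, sequences_per_point = 3)
#' nrow(ds) # 12
full_factorial_design <- function(levels = c(4, 6, 8, 10, 12),
                                  n_factors = 4L,
                                  sequences_per_point = 5L,
                                  seed = 1L,
                                  interaction_table = default_interaction_table(),
                                  featurize = TRUE) {
  if (length(levels) == 0L) stop("levels must be non-empty", call. = FALSE)
  if (sequences_per_point < 1L) stop("sequences_per_point must be >= 1", call. = FALSE)
  if (n_factors < 1L || n_factors > 4L) stop("n_factors must be in 1..4", call. = FALSE)
  types <- monomer_alphabet()[seq_len(n_factors)]
  grid <- expand.grid(rep(list(as.integer(levels)), n_factors),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- types
  seqs <- character(nrow(grid) * sequences_per_point)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    comp <- stats::setNames(as.integer(grid[g, ]), types)
    seen <- character(0)
    for (r in seq_len(sequences_per_point)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        s <- random_sequence(comp, seed = derive_seed(seed, g * 100003 + r * 131 + tries))
        if (!s %in% seen) break
        if (tries >= 1000L) {
          stop("could not draw a distinct arrangement for composition ",
               paste(names(comp), comp, sep = "=", collapse = ","),
               " after 1000 redraws", call. = FALSE)
        }
      }
      seen <- c(seen, s)
      k <- k + 1L
      seqs[k] <- s
    }
  }
  out <- tibble::tibble(id = seqs, sequence = seqs)
  if (featurize) {
    out <- dplyr::bind_cols(out, featurize_design(seqs, interaction_table))
  }
  out
}

#' Relative sequence entropy
#'
#' Shannon entropy (natural log) of the monomer-type frequency distribution,
#' normalized by `log(4)` — the maximum over the fixed four-letter alphabet —
#' so values are comparable across polymers regardless of how many types a
#' particular sequence uses.
#'
#' @param sequence Bracket-notation string or bead character vector.
#' @return Value in `[0, 1]`; 0 iff a homopolymer, 1 iff all four types are
#'   equifrequent.
#' @export
relative_sequence_entropy <- function(sequence) {
  beads <- if (length(sequence) == 1L && grepl("\\[", sequence[1])) {
    parse_sequence(sequence)
  } else sequence
  p <- sequence_composition(beads) / length(beads)
  p <- p[p > 0]
  -sum(p * log(p)) / log(4)
}

#' Run-length (cluster) statistics of a monomer sequence
#'
#' Describes the blockiness of the sequence through its maximal runs of
#' identical beads: a homopolymer of length N is one run of length N, a
#' strictly alternating sequence has N runs of length 1.
#'
#' @inheritParams relative_sequence_entropy
#' @return Named list: `n_runs`, `mean_run_length`, `max_run_length`
#'   (totals), and per-type `runs` / `max_run` named vectors over the full
#'   alphabet (0 for absent types).
#' @export
cluster_statistics <- function(sequence) {
  beads <- if (length(sequence) == 1L && grepl("\\[", sequence[1])) {
    parse_sequence(sequence)
  } else sequence
  r <- rle(beads)
  per_runs <- per_max <- stats::setNames(numeric(4), monomer_alphabet())
  for (t in unique(r$values)) {
    per_runs[t] <- sum(r$values == t)
    per_max[t] <- max(r$lengths[r$values == t])
  }
  list(
    n_runs = length(r$lengths),
    mean_run_length = mean(r$lengths),
    max_run_length = max(r$lengths),
    runs = per_runs,
    max_run = per_max
  )
}

#' Default per-bead interaction parameters
#'
#' Placeholder summed-interaction weights, exposed so every code path takes
#' the table as an input; replace with force-field-derived values when
#' available. Units are arbitrary energy units per bead.
#'
#' @return Named numeric vector over [monomer_alphabet()].
#' @export
default_interaction_table <- function() {
  c(W = 0.5, R = 1.5, Ta = 1.0, Tr = 2.0)
}

#' Names of the full feature schema
#'
#' Fixed order: degree of polymerization, relative sequence entropy, one-hot
#' head and tail end groups, per-type bead counts, summed interaction
#' parameter, and cluster (run-length) statistics.
#'
#' @param reduced If `TRUE`, return the invertible subset used for model
#'   inversion: counts, end groups, degree of polymerization, summed
#'   interaction and total run count (the relative entropy and the
#'   non-invertible run statistics are dropped).
#' @return Character vector of feature names in schema order.
#' @export
feature_names <- function(reduced = FALSE) {
  ab <- monomer_alphabet()
  full <- c("degree_of_polymerization", "rel_entropy",
            paste0("head_", ab), paste0("tail_", ab),
            paste0("count_", ab), "sum_interaction",
            "n_runs", "mean_run_length", "max_run_length",
            paste0("runs_", ab))
  if (!reduced) return(full)
  c("degree_of_polymerization",
    paste0("head_", ab), paste0("tail_", ab),
    paste0("count_", ab), "sum_interaction", "n_runs")
}

#' Featurize a monomer sequence
#'
#' Assembles the fixed-order numeric descriptor vector used by the
#' surrogates: chain length N, relative sequence entropy, one-hot encoded
#' head and tail end groups, per-type bead counts, the summed interaction
#' parameter `sum_i a(bead_i)`, and run-length statistics.
#'
#' @inheritParams relative_sequence_entropy
#' @param interaction_table Named numeric vector covering all four types.
#' @return Named numeric vector in [feature_names()] order.
#' @export
featurize <- function(sequence, interaction_table = default_interaction_table()) {
  ab <- monomer_alphabet()
  if (!all(ab %in% names(interaction_table))) {
    stop("interaction_table must cover all four monomer types", call. = FALSE)
  }
  beads <- if (length(sequence) == 1L && grepl("\\[", sequence[1])) {
    parse_sequence(sequence)
  } else sequence
  counts <- sequence_composition(beads)
  cl <- cluster_statistics(beads)
  v <- c(
    length(beads),
    relative_sequence_entropy(beads),
    as.numeric(ab == beads[1]),
    as.numeric(ab == beads[length(beads)]),
    as.numeric(counts),
    sum(interaction_table[beads]),
    cl$n_runs, cl$mean_run_length, cl$max_run_length,
    as.numeric(cl$runs)
  )
  stats::setNames(v, feature_names())
}

#' Featurize many sequences into a tibble
#'
#' @param sequences Character vector of bracket-notation sequences.
#' @inheritParams featurize
#' @return Tibble with one row per sequence, columns per [feature_names()].
#' @export
featurize_design <- function(sequences, interaction_table = default_interaction_table()) {
  m <- t(vapply(sequences, featurize, numeric(length(feature_names())),
                interaction_table = interaction_table, USE.NAMES = FALSE))
  colnames(m) <- feature_names()
  tibble::as_tibble(as.data.frame(m))
}

#' z-score standardization with training-set statistics
#'
#' Columns are centered and scaled using the mean and (population) standard
#' deviation of the training rows only, then the transform is applied to all
#' rows. Columns constant on the training set standardize to zero rather
#' than NaN.
#'
#' @param features Numeric matrix or data frame of features.
#' @param train_rows Integer indices of the training rows.
#' @return List with `standardized` (matrix, all rows), `center` and `scale`
#'   (per-column statistics; `scale` is 1 where the training column was
#'   constant, with attribute `constant` marking those columns).
#' @export
standardize_features <- function(features, train_rows = seq_len(nrow(features))) {
  x <- as.matrix(features)
  if (length(train_rows) == 0L) stop("training set is empty", call. = FALSE)
  tr <- x[train_rows, , drop = FALSE]
  center <- colMeans(tr)
  scale <- sqrt(colMeans(sweep(tr, 2L, center)^2))
  constant <- scale < 1e-12
  scale[constant] <- 1
  std <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  std[, constant] <- 0
  attr(scale, "constant") <- constant
  list(standardized = std, center = center, scale = scale)
}

#' Decode an invertible feature vector back into a monomer sequence
#'
#' The inverse of the reduced feature schema (see
#' `feature_names(reduced = TRUE)`): given per-type counts, one-hot end
#' groups and a target total run count, search for a sequence whose
#' recomputed invertible features match exactly. Because a feature vector
#' does not map to a unique arrangement, the decoder is randomized; it
#' returns `NA_character_` (INVALID) when the components are inconsistent
#' (non-integer or negative counts, end groups absent from the counts) or no
#' arrangement is found within `max_tries` attempts. INVALID is a value, not
#' an error — the genetic algorithm consumes it as a penalty.
#'
#' @param feature_vector Named numeric vector containing at least the
#'   reduced-schema entries (extra entries are ignored).
#' @param max_tries Randomized construction attempts before giving up.
#' @param seed Integer seed.
#' @return Bracket-notation sequence string, or `NA_character_`.
#' @export
backtrace_sequence <- function(feature_vector, max_tries = 200L, seed = 1L) {
  ab <- monomer_alphabet()
  fv <- feature_vector
  counts <- fv[paste0("count_", ab)]
  if (anyNA(counts) || any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    return(NA_character_)
  }
  counts <- stats::setNames(as.integer(round(counts)), ab)
  n <- sum(counts)
  if (n < 1L) return(NA_character_)
  head_oh <- fv[paste0("head_", ab)]
  tail_oh <- fv[paste0("tail_", ab)]
  if (anyNA(head_oh) || anyNA(tail_oh)) return(NA_character_)
  if (sum(round(head_oh) == 1) != 1L || sum(round(tail_oh) == 1) != 1L) {
    return(NA_character_)
  }
  head_t <- ab[round(head_oh) == 1]
  tail_t <- ab[round(tail_oh) == 1]
  if (counts[head_t] < 1L || counts[tail_t] < 1L) return(NA_character_)
  if (n == 1L && head_t != tail_t) return(NA_character_)
  target_runs <- fv[["n_runs"]]
  if (is.na(target_runs) || abs(target_runs - round(target_runs)) > 1e-8) {
    return(NA_character_)
  }
  target_runs <- as.integer(round(target_runs))
  present <- names(counts)[counts > 0]
  if (target_runs < length(present) || target_runs > n) return(NA_character_)
  if (length(present) == 1L) {
    if (target_runs != 1L) return(NA_character_)
    return(format_sequence(rep(present, n)))
  }
  want <- fv[feature_names(reduced = TRUE)]
  rng <- local_rng(seed)
  for (try in seq_len(max_tries)) {
    s <- try_build_sequence(counts, head_t, tail_t, target_runs, rng)
    if (is.null(s)) next
    got <- featurize(s)[feature_names(reduced = TRUE)]
    # N and sum_interaction follow from the counts; still verify the
    # components the caller supplied where present and finite
    chk <- intersect(names(want)[is.finite(want)], names(got))
    if (all(abs(got[chk] - want[chk]) < 1e-6)) return(s)
  }
  NA_character_
}

# One randomized attempt at a sequence with exactly `target_runs` maximal
# runs, given bead counts and fixed end-group types. Strategy: choose how
# many runs each type contributes, arrange the run labels with no two equal
# neighbours (head/tail pinned), then split each type's count across its runs.
try_build_sequence <- function(counts, head_t, tail_t, target_runs, rng) {
  present <- names(counts)[counts > 0]
  # runs per type: at least 1 each, at most count_t each, summing to target
  r <- stats::setNames(rep(1L, length(present)), present)
  extra <- target_runs - length(present)
  cap <- counts[present] - 1L
  if (extra > sum(cap)) return(NULL)
  while (extra > 0L) {
    room <- present[r[present] < counts[present]]
    if (length(room) == 0L) return(NULL)
    pick <- if (length(room) == 1L) room else room[rng$sample_int(length(room), 1L)]
    r[pick] <- r[pick] + 1L
    extra <- extra - 1L
  }
  # arrange run labels: head type first, tail type last, adjacent distinct
  labels <- rep(present, times = r)
  hi <- which(labels == head_t)[1]
  labels <- labels[-hi]
  ti <- which(labels == tail_t)[1]
  if (target_runs > 1L) {
    if (is.na(ti)) return(NULL)
    labels <- labels[-ti]
  } else if (head_t != tail_t) return(NULL)
  mid <- if (length(labels) > 0L) labels[rng$sample_int(length(labels))] else character(0)
  lab_seq <- c(head_t, mid, if (target_runs > 1L) tail_t)
  if (any(lab_seq[-1] == lab_seq[-length(lab_seq)])) return(NULL)
  # split counts across runs: random positive composition per type
  lens <- integer(length(lab_seq))
  for (t in unique(lab_seq)) {
    idx <- which(lab_seq == t)
    k <- length(idx)
    ct <- counts[t]
    if (k == 1L) {
      lens[idx] <- ct
    } else {
      cuts <- sort(rng$sample_int(ct - 1L, k - 1L))
      lens[idx] <- diff(c(0L, cuts, ct))
    }
  }
  format_sequence(rep(lab_seq, times = lens))
}
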
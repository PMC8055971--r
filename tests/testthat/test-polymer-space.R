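test_that("sequences round-trip through bracket notation", {
  beads <- c("W", "R", "Ta", "Tr", "W")
  expect_identical(parse_sequence(format_sequence(beads)), beads)
  expect_error(format_sequence(c("W", "X")), "unknown monomer")
  expect_error(parse_sequence("[W][X]"), "unknown monomer")
})

test_that("random sequences are seeded permutations of the composition", {
  expect_identical(random_sequence(c(W = 2)), "[W][W]")
  expect_error(random_sequence(c(W = 0)), "at least one bead")
  for (seed in 1:5) {
    s <- random_sequence(c(W = 1, R = 1), seed = seed)
    expect_true(s %in% c("[W][R]", "[R][W]"))
  }
  comp <- c(W = 4, R = 4, Ta = 4, Tr = 4)
  s <- parse_sequence(random_sequence(comp, seed = 3))
  expect_length(s, 16)
  expect_identical(as.integer(table(factor(s, levels = names(comp)))),
                   unname(as.integer(comp)))
  expect_identical(random_sequence(comp, seed = 9), random_sequence(comp, seed = 9))
})

test_that("full factorial design has |levels|^factors * seqs rows", {
  d1 <- full_factorial_design(c(4), n_factors = 4, sequences_per_point = 1)
  expect_equal(nrow(d1), 1)
  expect_length(parse_sequence(d1$sequence[1]), 16)

  d2 <- full_factorial_design(c(4, 6), n_factors = 2, sequences_per_point = 3)
  expect_equal(nrow(d2), 12)
  comps <- unique(vapply(d2$sequence, function(s) {
    paste(sort(table(parse_sequence(s))), collapse = ",")
  }, character(1)))
  expect_equal(anyDuplicated(d2$id), 0)
  # deterministic given seed
  d2b <- full_factorial_design(c(4, 6), n_factors = 2, sequences_per_point = 3)
  expect_identical(d2, d2b)
  # impossible uniqueness: a homopolymer composition has one arrangement
  expect_error(
    full_factorial_design(c(4), n_factors = 1, sequences_per_point = 2),
    "distinct arrangement")
  # cardinality invariant on a few random shapes
  for (nl in 1:3) {
    d <- full_factorial_design(seq(4, by = 2, length.out = nl) ,
                               n_factors = 2, sequences_per_point = 2,
                               featurize = FALSE)
    expect_equal(nrow(d), nl^2 * 2)
  }
})

test_that("relative sequence entropy is normalized over the 4-letter alphabet", {
  expect_equal(relative_sequence_entropy("[W][W][W][W]"), 0)
  expect_equal(relative_sequence_entropy("[W][R][Ta][Tr]"), 1)
  p <- c(1 / 3, 2 / 3)
  expect_equal(relative_sequence_entropy("[W][W][R][R][R][R]"),
               -sum(p * log(p)) / log(4))
  # bounds over random sequences
  for (seed in 1:10) {
    s <- random_sequence(c(W = 3, R = 5, Ta = 1), seed = seed)
    e <- relative_sequence_entropy(s)
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("cluster statistics are run-length encodings", {
  h <- cluster_statistics("[W][W][W]")
  expect_equal(h$n_runs, 1)
  expect_equal(h$max_run_length, 3)
  alt <- cluster_statistics("[W][R][W][R]")
  expect_equal(alt$n_runs, 4)
  expect_equal(alt$max_run_length, 1)
  mix <- cluster_statistics("[W][W][R][R][R][Ta]")
  expect_equal(mix$n_runs, 3)
  expect_equal(mix$mean_run_length, 2)
  expect_equal(unname(mix$max_run[c("W", "R", "Ta")]), c(2, 3, 1))
})

test_that("featurize assembles the fixed-order descriptor vector", {
  tbl <- c(W = 1, R = 1.5, Ta = 1, Tr = 1)
  fv <- featurize(strrep("[W]", 8), interaction_table = tbl)
  expect_identical(names(fv), feature_names())
  expect_equal(fv[["degree_of_polymerization"]], 8)
  expect_equal(fv[["sum_interaction"]], 8)
  expect_equal(fv[["rel_entropy"]], 0)
  fv2 <- featurize("[R][W][Ta]")
  expect_equal(unname(fv2[paste0("head_", monomer_alphabet())]), c(0, 1, 0, 0))
  expect_equal(unname(fv2[paste0("tail_", monomer_alphabet())]), c(0, 0, 1, 0))
  fv3 <- featurize("[W][R]", interaction_table = c(W = 0.5, R = 1.5, Ta = 0, Tr = 0))
  expect_equal(fv3[["sum_interaction"]], 2.0)
  expect_error(featurize("[W]", interaction_table = c(W = 1)), "cover")
  # purity and count consistency
  s <- random_sequence(c(W = 3, R = 2, Tr = 1), seed = 4)
  expect_identical(featurize(s), featurize(s))
  fv4 <- featurize(s)
  expect_equal(sum(fv4[paste0("count_", monomer_alphabet())]),
               fv4[["degree_of_polymerization"]])
})

test_that("standardization uses training-only population statistics", {
  x <- matrix(c(1, 3, 2, 5, 5, 5), ncol = 2) # col2 constant
  st <- standardize_features(x, train_rows = 1:2)
  expect_equal(st$standardized[1:2, 1], c(-1, 1)) # mean 2, population sd 1
  expect_equal(st$standardized[, 2], c(0, 0, 0)) # zero-variance rule
  # held-out row equal to the training mean maps to 0
  y <- rbind(c(0, 10), c(4, 14), c(2, 12))
  sty <- standardize_features(y, train_rows = 1:2)
  expect_equal(unname(sty$standardized[3, ]), c(0, 0))
  expect_error(standardize_features(x, integer(0)), "empty")
  # affine inverse recovers inputs
  z <- matrix(rnorm(30), 10, 3)
  stz <- standardize_features(z)
  back <- sweep(sweep(stz$standardized, 2, stz$scale, "*"), 2, stz$center, "+")
  expect_equal(back, z, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("backtracing inverts the reduced feature schema", {
  fv <- featurize("[W][W][W][W]")
  expect_identical(backtrace_sequence(fv), "[W][W][W][W]")
  # end group absent from counts is INVALID
  bad <- fv
  bad[paste0("head_", monomer_alphabet())] <- c(0, 1, 0, 0) # head R, count_R = 0
  expect_identical(backtrace_sequence(bad), NA_character_)
  # non-integer counts are INVALID
  frac <- fv
  frac[["count_W"]] <- 3.5
  expect_identical(backtrace_sequence(frac), NA_character_)
  # round trip: invertible components are reproduced exactly
  red <- feature_names(reduced = TRUE)
  for (seed in 1:20) {
    s <- random_sequence(c(W = 4, R = 3, Ta = 2, Tr = 3), seed = seed)
    fv <- featurize(s)
    s2 <- backtrace_sequence(fv, max_tries = 500, seed = seed)
    expect_false(is.na(s2))
    expect_equal(featurize(s2)[red], fv[red])
  }
})
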
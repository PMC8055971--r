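degenerate_rects <- function(values) {
  list(lower = values, upper = values, center = values)
}

test_that("greedy farthest-point sampling is maximin with index tie-breaks", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  expect_identical(select_initial_design(x, 2, start = 1), c(1L, 3L))
  # brute force: {0, 10} is the unique pair maximizing the pairwise distance
  pairs <- combn(3, 2)
  dists <- apply(pairs, 2, function(p) abs(x[p[1]] - x[p[2]]))
  expect_identical(sort(pairs[, which.max(dists)]), c(1L, 3L))
  # k = n returns everything
  expect_setequal(select_initial_design(x, 3, seed = 2), 1:3)
  expect_error(select_initial_design(x, 0), "positive")
  expect_error(select_initial_design(x, 5), "exceeds")
  # deterministic and distinct on a bigger space
  f <- matrix(runif(200, min = 0, max = 1), ncol = 2)
  i1 <- select_initial_design(f, 20, seed = 7)
  i2 <- select_initial_design(f, 20, seed = 7)
  expect_identical(i1, i2)
  expect_equal(anyDuplicated(i1), 0)
})

test_that("beta schedule follows the closed form and its monotonicities", {
  cfg <- epal_config(epsilon = rep(0.05, 3), delta = 0.05, beta_scale = 1 / 9)
  expect_equal(beta_t(1, 3125, 3, cfg),
               (1 / 9) * 2 * log(3 * 3125 * pi^2 * 1 / (6 * 0.05)))
  b <- sapply(1:20, beta_t, n_candidates = 100, n_objectives = 2, config = cfg)
  expect_true(all(diff(b) >= 0))
  expect_gt(beta_t(5, 200, 2, cfg), beta_t(5, 100, 2, cfg))
})

test_that("rectangles follow mu +/- sqrt(beta) sigma and only shrink", {
  pred <- list(mean = matrix(c(1, 1), 1), sd = matrix(c(0.1, 0.2), 1))
  r <- build_rectangles(pred, NULL, beta = 4)
  expect_equal(r$lower[1, ], c(0.8, 0.6))
  expect_equal(r$upper[1, ], c(1.2, 1.4))
  # zero sd gives degenerate point rectangles
  r0 <- build_rectangles(list(mean = pred$mean, sd = matrix(0, 1, 2)), NULL, 4)
  expect_equal(r0$lower, r0$upper)
  # previous subset of new Q: intersection returns previous
  prev <- list(lower = matrix(c(0.9, 0.9), 1), upper = matrix(c(1.1, 1.1), 1))
  r2 <- build_rectangles(pred, prev, beta = 4)
  expect_equal(r2$lower, prev$lower)
  expect_equal(r2$upper, prev$upper)
  # empty intersection falls back to the new interval with a warning
  far <- list(lower = matrix(c(5, 5), 1), upper = matrix(c(6, 6), 1))
  expect_warning(r3 <- build_rectangles(pred, far, beta = 4), "empty")
  expect_equal(r3$lower[1, ], c(0.8, 0.6))
  # measured points use the measurement and its noise
  lab <- label_table(tibble::tibble(candidate = 1, objective = 1,
                                    value = 2, noise_sd = 0), 2)
  r4 <- build_rectangles(pred, NULL, beta = 4, sampled_labels = lab)
  expect_equal(r4$lower[1, 1], 2)
  expect_equal(r4$upper[1, 1], 2)
})

test_that("the discard rule removes certainly dominated candidates", {
  st <- epal_state(2)
  rects <- list(lower = rbind(c(2, 2), c(0, 0)),
                upper = rbind(c(3, 3), c(1, 1)),
                center = rbind(c(2.5, 2.5), c(0.5, 0.5)))
  st2 <- epsilon_discard(st, rects, c(0, 0))
  expect_identical(st2$discarded, 2L)
  expect_identical(st2$unclassified, 1L)
  # overlapping rectangles at eps = 0: no certain dominance, no discard
  ov <- list(lower = rbind(c(0, 0), c(0.5, 0.5)),
             upper = rbind(c(2, 2), c(1.5, 1.5)),
             center = rbind(c(1, 1), c(1, 1)))
  expect_length(epsilon_discard(epal_state(2), ov, c(0, 0))$discarded, 0)
  # within the mean-scaled tolerance below the pessimistic corner
  tol <- list(lower = rbind(c(1, 1), c(0.9, 0.9)),
              upper = rbind(c(1.2, 1.2), c(1.04, 1.04)),
              center = rbind(c(1.1, 1.1), c(1, 1)))
  st3 <- epsilon_discard(epal_state(2), tol, c(0.05, 0.05))
  expect_identical(st3$discarded, 2L) # 1 + 0.05*1.1 = 1.055 >= 1.04
  st4 <- epsilon_discard(epal_state(2), tol, c(0, 0))
  expect_length(st4$discarded, 0) # 1 < 1.04 without the tolerance
})

test_that("the promotion rule certifies epsilon-accurate Pareto points", {
  # last unclassified candidate is promoted vacuously
  st <- epal_state(2)
  rects <- list(lower = rbind(c(2, 2), c(0, 0)),
                upper = rbind(c(3, 3), c(1, 1)),
                center = rbind(c(2.5, 2.5), c(0.5, 0.5)))
  st <- epsilon_discard(st, rects, c(0, 0))
  st <- epsilon_pareto_promote(st, rects, c(0, 0))
  expect_identical(st$pareto, 1L)
  expect_length(st$unclassified, 0)
  # pessimistic corner strictly above every other optimistic corner
  dom <- list(lower = rbind(c(2, 2), c(0, 0)),
              upper = rbind(c(2.5, 2.5), c(1.9, 1.9)),
              center = rbind(c(2.2, 2.2), c(1, 1)))
  stp <- epsilon_pareto_promote(epal_state(2), dom, c(0, 0))
  expect_true(1L %in% stp$pareto)
  # mutually overlapping rectangles: each could still be dominated, so
  # neither is promoted
  ov <- list(lower = rbind(c(0, 0), c(1, 1)),
             upper = rbind(c(2, 2), c(3, 3)),
             center = rbind(c(1, 1), c(2, 2)))
  expect_length(epsilon_pareto_promote(epal_state(2), ov, c(0, 0))$pareto, 0)
  # exact degenerate ties: both kept alive, neither discarded
  tie <- degenerate_rects(rbind(c(1, 2), c(1, 2)))
  sd1 <- epsilon_discard(epal_state(2), tie, c(0, 0))
  expect_length(sd1$discarded, 0)
  expect_length(epsilon_pareto_promote(sd1, tie, c(0, 0))$pareto, 2)
})

test_that("acquisition ranks by coefficient of variation and skips discarded", {
  st <- epal_state(3)
  # equal absolute widths, different means: small-mean candidate wins
  rects <- list(lower = rbind(c(0.5, 0.5), c(9.5, 9.5), c(0, 0)),
                upper = rbind(c(1.5, 1.5), c(10.5, 10.5), c(0.1, 0.1)),
                center = rbind(c(1, 1), c(10, 10), c(0.05, 0.05)))
  st$discarded <- 3L
  st$unclassified <- c(1L, 2L)
  expect_identical(acquisition(st, rects, 1), 1L)
  expect_identical(acquisition(st, rects, 2), c(1L, 2L))
  # never a discarded candidate, even with a huge rectangle
  rects$upper[3, ] <- c(100, 100)
  expect_false(3L %in% acquisition(st, rects, 3))
  # only-remaining candidate is chosen; nothing left signals termination
  st$sampled <- 1L
  expect_identical(acquisition(st, rects, 1), 2L)
  st$sampled <- c(1L, 2L)
  expect_length(acquisition(st, rects, 1), 0)
})

test_that("a noiseless mini-campaign recovers the exact Pareto set", {
  feats <- matrix(c(0, 0.5, 1, 0.2, 0.9, 0.1), ncol = 2)
  truth <- rbind(c(1, 0), c(0.4, 0.6), c(0, 1))
  oracle <- oracle_from_function(function(i) truth[i, ], noise_sd = 0)
  cfg <- epal_config(epsilon = c(1e-4, 1e-4), init_size = 2,
                     max_iterations = 30, n_restarts = 1)
  camp <- run_campaign(feats, oracle, cfg, seed = 2, truth = truth)
  expect_setequal(camp$state$pareto, which(brute_pareto(truth)))
  expect_length(camp$state$unclassified, 0)
})

test_that("max_iterations = 0 leaves the initialized state untouched", {
  b <- make_benchmark("two_obj_convex", size = 20, seed = 5)
  cfg <- epal_config(epsilon = c(0.05, 0.05), init_size = 4, max_iterations = 0)
  camp <- run_campaign(b$features, b$oracle, cfg, seed = 1, truth = b$truth)
  expect_equal(nrow(camp$history), 1)
  expect_equal(camp$history$iteration, 0L)
  expect_length(camp$state$pareto, 0)
  expect_length(camp$state$discarded, 0)
  expect_equal(length(camp$state$sampled), 4)
})

test_that("a loose tolerance classifies the space in fewer iterations", {
  b <- make_benchmark("two_obj_convex", size = 40, seed = 9)
  run_eps <- function(eps) {
    cfg <- epal_config(epsilon = rep(eps, 2), init_size = 6,
                       max_iterations = 80, n_restarts = 2)
    g <- glance(run_campaign(b$features, b$oracle, cfg, seed = 11,
                             truth = b$truth))
    g$iterations
  }
  suppressWarnings({
    it_loose <- run_eps(0.5)
    it_tight <- run_eps(0.02)
  })
  expect_lte(it_loose, it_tight)
})

test_that("campaigns are deterministic and tidy/glance expose the state", {
  b <- make_benchmark("two_obj_convex", size = 25, seed = 4)
  cfg <- quick_config(2)
  suppressWarnings({
    c1 <- run_campaign(b$features, b$oracle, cfg, seed = 3, truth = b$truth)
    c2 <- run_campaign(b$features, b$oracle, cfg, seed = 3, truth = b$truth)
  })
  expect_identical(c1$history, c2$history)
  td <- tidy(c1)
  expect_equal(nrow(td), 25)
  expect_setequal(unique(td$classification),
                  intersect(c("pareto", "discarded", "unclassified"),
                            td$classification))
  g <- glance(c1)
  expect_equal(g$n_pareto + g$n_discarded + g$n_unclassified, 25)
  p <- autoplot(c1)
  expect_s3_class(p, "ggplot")
})

test_that("oracle failures mark candidates unmeasurable and continue", {
  b <- make_benchmark("two_obj_convex", size = 20, seed = 6)
  flaky <- function(i) {
    if (i == 7) stop("simulation failed")
    b$oracle(i)
  }
  cfg <- epal_config(epsilon = c(0.1, 0.1), init_size = 5,
                     max_iterations = 40, n_restarts = 1)
  suppressWarnings(
    camp <- run_campaign(b$features, flaky, cfg, seed = 8, truth = b$truth))
  expect_false(7L %in% camp$state$sampled)
  expect_gte(nrow(camp$history), 2)
})
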
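# Independent single-output GP posterior (same Matern-5/2 formulas, written
# directly from the textbook equations) used as an oracle for the ICM model.
plain_gp_predict <- function(X, y, Xq, ell, sig2, noise2, jitter = 1e-6) {
  m52 <- function(r) {
    s <- sqrt(5) * r
    (1 + s + s^2 / 3) * exp(-s)
  }
  dist <- function(a, b) {
    sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0))
  }
  K <- sig2 * m52(dist(X, X) / ell)
  diag(K) <- diag(K) + noise2 + jitter
  Ks <- sig2 * m52(dist(Xq, X) / ell)
  Kinv_y <- solve(K, y)
  mean <- Ks %*% Kinv_y
  var <- sig2 - rowSums((Ks %*% solve(K)) * Ks)
  list(mean = as.numeric(mean), sd = sqrt(pmax(var, 0)))
}

make_labels <- function(values, noise_sd = NA_real_) {
  n <- nrow(values); m <- ncol(values)
  tibble::tibble(candidate = rep(seq_len(n), each = m),
                 objective = rep(seq_len(m), n),
                 value = as.numeric(t(values)),
                 noise_sd = noise_sd)
}

test_that("label tables validate their invariants", {
  lt <- label_table(tibble::tibble(candidate = c(1, 1, 2), objective = c(1, 3, 2),
                                   value = c(0.1, 0.2, 0.3)), 3)
  expect_s3_class(lt, "epal_label_table")
  expect_error(label_table(tibble::tibble(candidate = c(1, 1), objective = c(1, 1),
                                          value = c(1, 2)), 2), "duplicate")
  expect_error(label_table(tibble::tibble(candidate = 1, objective = 1,
                                          value = NaN), 1), "non-finite")
  expect_error(label_table(tibble::tibble(candidate = 1, objective = 5,
                                          value = 1), 2), "out of range")
})

test_that("rank-1 ICM with one output matches a single-output GP", {
  set.seed(21)
  X <- matrix(runif(16), ncol = 2)
  y <- sin(3 * X[, 1]) + X[, 2]
  model <- fit_surrogate(X, make_labels(matrix(y, ncol = 1)), 1,
                         n_restarts = 0)
  Xq <- matrix(runif(10), ncol = 2)
  got <- predict(model, Xq)
  th <- model$theta
  B <- th$w^2 + exp(th$log_kappa) # 1x1 coregionalization = kernel variance
  ys <- (y - model$y_center) / model$y_scale
  want <- plain_gp_predict(X, ys, Xq, exp(th$log_ell), B,
                           exp(2 * th$log_noise))
  expect_equal(got$mean[, 1], want$mean * model$y_scale + model$y_center,
               tolerance = 1e-6)
  expect_equal(got$sd[, 1], want$sd * model$y_scale, tolerance = 1e-6)
})

test_that("the GP interpolates noiseless data and reverts to the prior", {
  set.seed(4)
  X <- matrix(runif(20), ncol = 2)
  vals <- cbind(X[, 1]^2, 1 - X[, 2])
  model <- fit_surrogate(X, make_labels(vals, noise_sd = 1e-6), 2,
                         n_restarts = 3, seed = 2)
  at_train <- predict(model, X)
  expect_equal(at_train$mean, vals, tolerance = 1e-3, ignore_attr = TRUE)
  expect_lt(max(at_train$sd), 0.05)
  # far from all data the sd approaches the prior marginal sd
  far <- matrix(rep(100, 2), ncol = 2)
  pf <- predict(model, far)
  B <- model$cache$B
  prior_sd <- sqrt(diag(B)) * model$y_scale
  expect_equal(as.numeric(pf$sd), prior_sd, tolerance = 1e-3)
  # identical query rows get identical predictions
  two <- predict(model, rbind(X[1, ], X[1, ]))
  expect_equal(two$mean[1, ], two$mean[2, ])
})

test_that("partially missing objectives are handled and shared structure helps", {
  set.seed(8)
  X <- matrix(runif(30), ncol = 2)
  f <- sin(4 * X[, 1]) + X[, 2]
  vals <- cbind(f, 0.8 * f + 0.1)
  lab <- make_labels(vals, noise_sd = 0.01)
  # drop objective 2 for two-thirds of candidates
  keep2 <- seq(1, 15, by = 3)
  lab <- lab[!(lab$objective == 2 & !(lab$candidate %in% keep2)), ]
  model <- fit_surrogate(X, lab, 2, n_restarts = 3, seed = 5)
  pred <- predict(model, X)
  held <- setdiff(seq_len(15), keep2)
  rmse_icm <- sqrt(mean((pred$mean[held, 2] - vals[held, 2])^2))
  # independent GP for objective 2 sees only 5 points
  solo <- fit_surrogate(X[keep2, , drop = FALSE],
                        make_labels(matrix(vals[keep2, 2], ncol = 1),
                                    noise_sd = 0.01), 1,
                        n_restarts = 3, seed = 5)
  rmse_solo <- sqrt(mean((predict(solo, X)$mean[held, 1] - vals[held, 2])^2))
  expect_lt(rmse_icm, rmse_solo + 0.05)
})

test_that("coregionalization beats independent GPs in the low-data regime", {
  errs <- sapply(1:20, function(seed) {
    set.seed(seed + 300)
    X <- matrix(runif(24), ncol = 1)
    f <- sin(5 * X[, 1])
    vals <- cbind(f, -0.9 * f + 0.05 * cos(7 * X[, 1]))
    lab <- make_labels(vals, noise_sd = 0.01)
    keep2 <- 1:6
    lab <- lab[!(lab$objective == 2 & !(lab$candidate %in% keep2)), ]
    held <- setdiff(seq_len(24), keep2)
    icm <- fit_surrogate(X, lab, 2, n_restarts = 2, seed = seed)
    solo <- fit_surrogate(X[keep2, , drop = FALSE],
                          make_labels(matrix(vals[keep2, 2], ncol = 1),
                                      noise_sd = 0.01), 1,
                          n_restarts = 2, seed = seed)
    c(icm = sqrt(mean((predict(icm, X)$mean[held, 2] - vals[held, 2])^2)),
      solo = sqrt(mean((predict(solo, X)$mean[held, 1] - vals[held, 2])^2)))
  })
  expect_lt(mean(errs["icm", ]), mean(errs["solo", ]))
})

test_that("updates only shrink variance and respect the refit schedule", {
  set.seed(13)
  X <- matrix(runif(40), ncol = 2)
  vals <- cbind(X[, 1] + X[, 2], X[, 1] * X[, 2])
  lab_all <- make_labels(vals, noise_sd = 0.05)
  first <- lab_all[lab_all$candidate <= 10, ]
  model <- fit_surrogate(X, first, 2, n_restarts = 2, refit_every = 100,
                         seed = 3)
  sd_before <- predict(model, X)$sd
  new <- lab_all[lab_all$candidate %in% 11:12, ]
  m2 <- update_surrogate(model, new)
  expect_equal(m2$since_refit, 4L) # conditioned, not refit
  sd_after <- predict(m2, X)$sd
  expect_true(all(sd_after <= sd_before + 1e-8))
  # a labeled candidate's own sd shrinks
  expect_lt(sd_after[11, 1], sd_before[11, 1])
  # duplicates rejected, empty updates are no-ops
  expect_error(update_surrogate(m2, new), "duplicate")
  expect_identical(update_surrogate(m2, first[0, ])$since_refit, m2$since_refit)
  # schedule fires: refit_every = 2 triggers re-optimization
  m3 <- fit_surrogate(X, first, 2, n_restarts = 2, refit_every = 2, seed = 3)
  m4 <- update_surrogate(m3, new)
  expect_equal(m4$since_refit, 0L)
})

test_that("predictions are invariant to training-row order", {
  set.seed(17)
  X <- matrix(runif(20), ncol = 2)
  vals <- cbind(X[, 1], X[, 2]^2)
  lab <- make_labels(vals, noise_sd = 0.02)
  m1 <- fit_surrogate(X, lab, 2, n_restarts = 0)
  m2 <- fit_surrogate(X, lab[sample(nrow(lab)), ], 2, n_restarts = 0)
  p1 <- predict(m1, X); p2 <- predict(m2, X)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-8)
  expect_equal(p1$sd, p2$sd, tolerance = 1e-8)
})
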
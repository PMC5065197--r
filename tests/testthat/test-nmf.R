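test_that("init_factors is deterministic, in range, and seed-sensitive", {
  a <- init_factors(3, 2, 2, seed = 7)
  b <- init_factors(3, 2, 2, seed = 7)
  expect_identical(a, b)
  expect_equal(dim(a$W), c(3L, 2L))
  expect_equal(dim(a$H), c(2L, 2L))

  big <- init_factors(50, 40, 5, seed = 3)
  expect_true(min(big$W, big$H) > 0)
  expect_true(max(big$W, big$H) <= 1)

  c1 <- init_factors(5, 4, 2, seed = 1)
  c2 <- init_factors(5, 4, 2, seed = 2)
  expect_false(isTRUE(all.equal(c1$W, c2$W)))

  expect_error(init_factors(3, 2, 3, seed = 1), "exceeds")
  expect_error(init_factors(0, 2, 1, seed = 1), "positive")
})

test_that("kl_divergence matches hand values and the loop oracle", {
  # exact reconstruction
  W <- matrix(c(1, 2), 2, 1); H <- matrix(c(3, 4), 1, 2)
  expect_equal(kl_divergence(W %*% H, W, H), 0)
  # single entries, evaluated by hand
  expect_equal(kl_divergence(matrix(2), matrix(1), matrix(1)),
               2 * log(2) - 2 + 1)
  expect_equal(kl_divergence(matrix(0), matrix(0.5), matrix(1)), 0.5)
  # vectorised result equals an explicit double loop
  f <- random_factors(8, 3, 5, seed = 11)
  A <- random_counts(8, 5, seed = 12)
  expect_equal(kl_divergence(A, f$W, f$H), kl_loop_oracle(A, f$W, f$H))
  # domain error when mass sits where the model has none
  expect_error(kl_divergence(matrix(1), matrix(0), matrix(0)), "infinite")
})

test_that("the multiplicative update has A = WH as a fixed point", {
  f <- random_factors(10, 2, 6, seed = 4)
  A <- f$W %*% f$H
  out <- nmf_update_step(A, f$W, f$H)
  expect_lt(max(abs(out$W - f$W)), 1e-12)
  expect_lt(max(abs(out$H - f$H)), 1e-12)
})

test_that("each update step decreases the divergence and preserves positivity", {
  A <- random_counts(20, 10, seed = 9)
  f <- init_factors(20, 10, 3, seed = 2)
  W <- f$W; H <- f$H
  loss <- kl_divergence(A, W, H)
  for (i in 1:25) {
    out <- nmf_update_step(A, W, H)
    W <- out$W; H <- out$H
    new_loss <- kl_divergence(A, W, H)
    expect_lte(new_loss, loss + 1e-9)
    loss <- new_loss
  }
  expect_true(all(W > 0) && all(H > 0))
})

test_that("fit_nmf recovers an exactly representable rank-1 matrix", {
  A <- outer(c(1, 2, 3), c(4, 5))
  fit <- fit_nmf(A, k = 1, seed = 1)
  expect_lt(fit$loss, 1e-6)
  expect_equal(fit$loss, kl_divergence(A, fit$W, fit$H), tolerance = 1e-8)
})

test_that("fit_nmf is deterministic under a fixed seed and validates input", {
  A <- random_counts(15, 8, seed = 21)
  f1 <- fit_nmf(A, 2, seed = 5)
  f2 <- fit_nmf(A, 2, seed = 5)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_identical(f1$loss, f2$loss)

  Az <- A; Az["g3", ] <- 0
  expect_error(fit_nmf(Az, 2, seed = 1), "g3")
  expect_error(fit_nmf(A, 9, seed = 1), "exceeds")
})

test_that("loss trace sampled at checks is non-increasing", {
  A <- random_counts(40, 12, seed = 31)
  fit <- fit_nmf(A, 3, seed = 2, max_iter = 500, stall_checks = Inf)
  expect_true(all(diff(fit$loss_trace) <= 1e-9 * pmax(fit$loss_trace[-length(fit$loss_trace)], 1)))
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 500L)
})

test_that("Euclidean variant fits representable input and is monotone", {
  A <- outer(c(1, 2, 3), c(4, 5))
  fit <- fit_nmf_eu(A, k = 1, seed = 1)
  expect_lt(fit$loss, 1e-8)

  A2 <- random_counts(20, 10, seed = 8)
  f <- fit_nmf_eu(A2, 2, seed = 3, max_iter = 300, stall_checks = Inf)
  expect_true(all(diff(f$loss_trace) <= 1e-9 * pmax(f$loss_trace[-length(f$loss_trace)], 1)))
  g <- fit_nmf_eu(A2, 2, seed = 3, max_iter = 300, stall_checks = Inf)
  expect_identical(f$W, g$W)
})

test_that("tidy and glance summarize a fit", {
  A <- random_counts(10, 6, seed = 2)
  fit <- fit_nmf(A, 2, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * 6)
  gl <- glance(fit)
  expect_equal(gl$loss, fit$loss)
  expect_equal(gl$k, 2L)
})
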
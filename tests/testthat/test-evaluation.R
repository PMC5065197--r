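test_that("accuracy handles relabelings and partial agreement", {
  expect_equal(clustering_accuracy(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(clustering_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1)), 100)
  expect_equal(clustering_accuracy(c(1, 1, 1, 2), c(1, 1, 2, 2)), 75)
  expect_error(clustering_accuracy(c(1, 2), c(1, 2, 3)), "lengths")
})

test_that("Hungarian matching equals exhaustive permutation search", {
  set.seed(71)
  for (i in 1:60) {
    m <- sample(4:8, 1)
    kp <- sample(2:3, 1); kt <- sample(2:3, 1)
    pred <- sample(seq_len(kp), m, replace = TRUE)
    truth <- sample(seq_len(kt), m, replace = TRUE)
    expect_equal(clustering_accuracy(pred, truth),
                 accuracy_bruteforce(pred, truth),
                 label = sprintf("case %d", i))
  }
})

test_that("accuracy is symmetric under relabeling either argument", {
  set.seed(72)
  truth <- sample(1:3, 9, replace = TRUE)
  pred <- sample(1:3, 9, replace = TRUE)
  relab <- c(3, 1, 2)
  expect_equal(clustering_accuracy(relab[pred], truth),
               clustering_accuracy(pred, truth))
  expect_equal(clustering_accuracy(pred, relab[truth]),
               clustering_accuracy(pred, truth))
})

test_that("experiments are reproducible and internally consistent", {
  sim <- simulate_expression(n_signal = 80, n_irrelevant = 20, m = 12, k = 2,
                             seed = 4)
  r1 <- run_experiment(sim$A, sim$true_labels, 2, filter = "none",
                       n_runs = 6, base_seed = 3)
  r2 <- run_experiment(sim$A, sim$true_labels, 2, filter = "none",
                       n_runs = 6, base_seed = 3)
  expect_identical(r1$per_seed_accuracy, r2$per_seed_accuracy)
  expect_equal(r1$sem * sqrt(r1$n_runs), sd(r1$per_seed_accuracy),
               tolerance = 1e-10)
  expect_equal(r1$mean, mean(r1$per_seed_accuracy))

  expect_warning(
    r_single <- run_experiment(sim$A, sim$true_labels, 2, filter = "none",
                               n_runs = 1, base_seed = 1),
    "sem")
  expect_equal(r_single$sem, 0)
})

test_that("paired comparison matches the closed-form t statistic", {
  mk <- function(acc, id) structure(
    list(method_id = id, per_seed_accuracy = acc, mean = mean(acc),
         sem = sd(acc) / sqrt(length(acc)), n_runs = length(acc),
         seeds = seq_along(acc)), class = "nmf_experiment")
  set.seed(5)
  base <- 80 + rnorm(12)
  a <- mk(base + 5 + rnorm(12, sd = 2), "a")
  b <- mk(base, "b")
  cmp <- compare_methods(a, b)
  d <- a$per_seed_accuracy - b$per_seed_accuracy
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(t_oracle), df = length(d) - 1)
  expect_equal(cmp$statistic, t_oracle)
  expect_equal(cmp$p_value, p_oracle)
  expect_equal(cmp$mean_diff, mean(d))

  # swapping arguments flips the sign, same p
  rev <- compare_methods(b, a)
  expect_equal(rev$mean_diff, -cmp$mean_diff)
  expect_equal(rev$p_value, cmp$p_value)

  # degenerate conventions
  expect_warning(same <- compare_methods(a, a), "zero variance")
  expect_equal(same$p_value, 1)
  shifted <- mk(base + 2, "c")
  expect_warning(diff0 <- compare_methods(shifted, b), "zero variance")
  expect_equal(diff0$p_value, 0)
})

test_that("top_varying_subset agrees with a sort oracle and keeps order", {
  A <- random_counts(50, 10, seed = 40)
  expect_equal(top_varying_subset(A, 50), A)

  B <- rbind(flat = rep(5, 4), vary = c(1, 9, 2, 8))
  expect_equal(rownames(top_varying_subset(B, 1)), "vary")

  sub <- top_varying_subset(A, 20)
  v <- apply(A, 1, var)
  keep <- sort(order(v, decreasing = TRUE)[1:20])
  expect_equal(sub, A[keep, ])
  # original order preserved
  expect_identical(rownames(sub), rownames(A)[rownames(A) %in% rownames(sub)])

  expect_error(top_varying_subset(A, 51), "exceeds")
})

test_that("uniform noise perturbation respects its bounds and moments", {
  A <- random_counts(200, 50, seed = 60)
  expect_identical(noise_perturb(A, 0, seed = 1), A)

  mu <- 0.25
  Ap <- noise_perturb(A, mu, seed = 2)
  expect_true(all(Ap >= A))
  expect_true(all(Ap <= A + mu * max(A)))
  # mean of the added noise ~ mu * max / 2
  delta <- Ap - A
  expected <- mu * max(A) / 2
  se <- mu * max(A) / sqrt(12 * length(A))
  expect_lt(abs(mean(delta) - expected), 3 * se)

  expect_error(noise_perturb(A, -1, seed = 1), "nonnegative")
})
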
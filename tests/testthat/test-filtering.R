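test_that("embedded filter reproduces the interpolated-median example", {
  # rows built so the max-min spread is exactly (0.1, 0.5, 0.9, 0.3)
  u <- c(0.1, 0.5, 0.9, 0.3)
  W <- cbind(0, u)
  rep <- embedded_filter(W, gene_ids = paste0("g", 1:4), frac = 0.5)
  expect_equal(rep$threshold, 0.4)
  expect_setequal(rep$discarded_gene_ids, c("g1", "g4"))
  expect_setequal(rep$kept_gene_ids, c("g2", "g3"))
})

test_that("filter report is always a partition with an inclusive threshold", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    u <- round(runif(n, 0, 1), sample(1:3, 1))  # rounding forces ties
    W <- cbind(0, u)
    ids <- sprintf("g%03d", seq_len(n))
    frac <- runif(1, 0.1, 0.9)
    rep <- suppressWarnings(embedded_filter(W, ids, frac))
    expect_setequal(c(rep$kept_gene_ids, rep$discarded_gene_ids), ids)
    expect_length(intersect(rep$kept_gene_ids, rep$discarded_gene_ids), 0)
    # sort-based oracle for the inclusive rule
    thr <- unname(quantile(u, frac, type = 7))
    expect_setequal(rep$discarded_gene_ids, ids[u <= thr])
  }
})

test_that("degenerate spreads discard everything, with a warning", {
  W <- matrix(0.5, 4, 3)                         # identical rows
  expect_warning(rep <- embedded_filter(W, paste0("g", 1:4)), "discarded")
  expect_length(rep$kept_gene_ids, 0)

  W1 <- matrix(runif(4), 4, 1)                   # k = 1: spread is zero
  expect_warning(rep1 <- embedded_filter(W1, paste0("g", 1:4)), "discarded")
  expect_length(rep1$kept_gene_ids, 0)

  expect_error(embedded_filter(W, paste0("g", 1:4), frac = 1), "between 0 and 1")
})

test_that("variance filter keeps the most variable genes", {
  A <- rbind(a = c(0, 0, 0) + 1, b = c(1, 2, 3))  # +1 avoids a zero row
  rep <- variance_filter(A, keep_fraction = 0.5)
  expect_equal(rep$kept_gene_ids, "b")

  A2 <- random_counts(100, 10, seed = 3)
  rep2 <- variance_filter(A2, keep_fraction = 0.5)
  expect_length(rep2$kept_gene_ids, 50)
  # agreement with a full-sort oracle
  v <- apply(A2, 1, var)
  expect_setequal(rep2$kept_gene_ids,
                  rownames(A2)[order(v, decreasing = TRUE)[1:50]])

  rep_all <- variance_filter(A2, keep_fraction = 1)
  expect_length(rep_all$discarded_gene_ids, 0)
})

test_that("pipeline without filter equals fit + normalize composition", {
  A <- random_counts(30, 12, seed = 17)
  cl <- post_process_cluster(A, 3, seed = 9, scheme = "max", filter = "none")
  fit <- fit_nmf(A, 3, seed = 9)
  nrm <- normalize_factorization(fit$W, fit$H, "max")
  expect_equal(cl$H, nrm$H)
  expect_identical(cl$labels, unname(assign_clusters(nrm$H)))
  expect_null(cl$filter_report)
})

test_that("embedded pipeline discards at least half the genes at the median", {
  sim <- simulate_expression(n_signal = 120, n_irrelevant = 40, m = 18, k = 3,
                             seed = 3)
  cl <- post_process_cluster(sim$A, 3, seed = 2, filter = "embedded")
  n <- nrow(sim$A)
  expect_gte(length(cl$filter_report$discarded_gene_ids), floor(n / 2))
  expect_equal(nrow(cl$fit$W), length(cl$filter_report$kept_gene_ids))
})

test_that("pipeline is deterministic in all filter modes", {
  sim <- simulate_expression(n_signal = 60, n_irrelevant = 20, m = 12, k = 2,
                             seed = 8)
  for (filt in c("none", "embedded", "variance")) {
    a <- post_process_cluster(sim$A, 2, seed = 4, filter = filt)
    b <- post_process_cluster(sim$A, 2, seed = 4, filter = filt)
    expect_identical(a$H, b$H, label = filt)
    expect_identical(a$labels, b$labels, label = filt)
  }
})

test_that("embedded filter removes most planted irrelevant genes", {
  sim <- simulate_expression(n_signal = 200, n_irrelevant = 200, m = 30, k = 3,
                             expression_scale = 50, dominance = 5, seed = 12)
  cl <- post_process_cluster(sim$A, 3, seed = 1, filter = "embedded")
  removed <- mean(sim$irrelevant_gene_ids %in% cl$filter_report$discarded_gene_ids)
  expect_gte(removed, 0.8)
})

test_that("incompatible and degenerate pipeline configurations error", {
  A <- random_counts(10, 6, seed = 5)
  expect_error(post_process_cluster(A, 2, seed = 1, scheme = "none",
                                    filter = "embedded"), "normalization")
})
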
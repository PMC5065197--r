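# Independent oracles and small fixture builders used across the suite.

# Naive elementwise KL divergence by explicit loops (oracle for the
# vectorised implementation).
kl_loop_oracle <- function(A, W, H) {
  WH <- W %*% H
  total <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    a <- A[i, j]; b <- WH[i, j]
    total <- total + (if (a > 0) a * log(a / b) - a else 0) + b
  }
  total
}

# Exhaustive permutation-matching clustering accuracy (oracle for the
# Hungarian implementation). Enumerates all injective maps from predicted
# to true labels.
accuracy_bruteforce <- function(pred, truth) {
  pk <- sort(unique(pred)); tk <- sort(unique(truth))
  d <- max(length(pk), length(tk))
  # embed both label sets into 1..d and try every permutation
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  pred_i <- match(pred, pk); truth_i <- match(truth, tk)
  best <- 0
  for (p in perms(seq_len(d))) {
    hits <- sum(p[pred_i] == truth_i)
    best <- max(best, hits)
  }
  100 * best / length(pred)
}

# Random strictly positive factor pair with reproducible entries.
random_factors <- function(n, k, m, seed) {
  set.seed(seed)
  list(W = matrix(runif(n * k, 0.05, 3), n, k),
       H = matrix(runif(k * m, 0.05, 3), k, m))
}

# Small Poisson matrix with no zero rows, for generic fit tests.
random_counts <- function(n, m, seed, lambda = 20) {
  set.seed(seed)
  A <- matrix(rpois(n * m, lambda) + 1, n, m)
  dimnames(A) <- list(sprintf("g%d", seq_len(n)), sprintf("s%d", seq_len(m)))
  A
}
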
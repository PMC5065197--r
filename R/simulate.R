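sim_build_truth <- function(n_signal, n_irrelevant, m, k, expression_scale,
                            dominance, flatness) {
  if (k < 1 || m < 2 * k)
    stop("need m >= 2k so every cluster holds at least two samples", call. = FALSE)
  if (n_signal < k)
    stop("need at least one signal gene per metagene", call. = FALSE)
  if (dominance <= 1) stop("dominance must exceed 1", call. = FALSE)
  if (flatness < 0 || flatness >= 1)
    stop("flatness must lie in [0, 1)", call. = FALSE)
  if (expression_scale <= 0) stop("expression_scale must be positive", call. = FALSE)

  n <- n_signal + n_irrelevant
  # signal genes: home metagene round-robin, membership 1 there, small
  # memberships Uniform(0, 0.2) elsewhere
  home <- rep_len(seq_len(k), n_signal)
  W <- matrix(runif(n * k, 0, 0.2), n, k)
  W[cbind(seq_len(n_signal), home)] <- 1
  # irrelevant genes: near-constant membership rows with spread < flatness
  if (n_irrelevant > 0) {
    base <- runif(n_irrelevant, 0.4, 0.6)
    W[n_signal + seq_len(n_irrelevant), ] <-
      base + matrix(runif(n_irrelevant * k, 0, flatness), n_irrelevant, k)
  }
  gene_ids <- sprintf("g%04d", seq_len(n))
  rownames(W) <- gene_ids

  labels <- rep_len(seq_len(k), m)
  H <- matrix(expression_scale, k, m)
  H[cbind(labels, seq_len(m))] <- expression_scale * dominance
  colnames(H) <- sprintf("s%03d", seq_len(m))

  list(W = W, H = H, labels = labels,
       irrelevant = if (n_irrelevant > 0) gene_ids[n_signal + seq_len(n_irrelevant)]
                    else character(0))
}

sim_draw <- function(mu, c_scale, max_retries) {
  A <- matrix(rpois(length(mu), c_scale * mu), nrow(mu), ncol(mu)) / c_scale
  for (try in seq_len(max_retries)) {
    zr <- rowSums(A) == 0
    if (!any(zr)) break
    A[zr, ] <- matrix(rpois(sum(zr) * ncol(mu), c_scale * mu[zr, ]),
                      sum(zr), ncol(mu)) / c_scale
  }
  if (any(rowSums(A) == 0))
    stop("could not draw a matrix without all-zero rows; raise expression_scale",
         call. = FALSE)
  dimnames(A) <- dimnames(mu)
  A
}

#' Simulate Poisson-structured expression data with planted clusters
#'
#' Generates the data the factorization model assumes: a planted
#' membership matrix W_true (entries in [0, 1]) and metagene expression
#' matrix H_true define Poisson means W_true H_true, and each count
#' A_ij is drawn independently from Poisson((W_true H_true)_ij).
#'
#' Signal genes are assigned round-robin to a home metagene where their
#' membership is exactly 1 (so each metagene contains at least one gene
#' with full membership), with off-home memberships drawn Uniform(0, 0.2).
#' Irrelevant genes get near-constant membership rows whose spread is
#' below `flatness`; they carry expression but no class information, the
#' situation the embedded filter is designed to correct. Samples are
#' assigned round-robin to the k clusters; a sample's home metagene is
#' expressed `dominance` times the others, everything scaled by
#' `expression_scale`. Rows that come out all zero are redrawn (bounded
#' retries).
#'
#' @param n_signal Number of informative genes.
#' @param n_irrelevant Number of irrelevant (flat-membership) genes.
#' @param m Number of samples (>= 2k).
#' @param k Number of planted clusters / metagenes.
#' @param expression_scale Baseline Poisson mean scale (counts).
#' @param dominance Expression ratio of a sample's home metagene to the
#'   others; must exceed 1. Larger values give easier problems.
#' @param flatness Upper bound on the membership spread of irrelevant
#'   genes, in [0, 1).
#' @param seed Integer seed; the same seed regenerates the dataset.
#' @param max_retries Redraw attempts for all-zero rows.
#' @return Object of class `nmf_sim`: list with the count matrix `A`,
#'   `true_labels`, `W_true`, `H_true`, `irrelevant_gene_ids`, `seed`,
#'   and the generating `params`.
#' @examples
#' sim <- simulate_expression(n_signal = 30, n_irrelevant = 5, m = 12,
#'                            k = 3, seed = 1)
#' dim(sim$A)
#' @export
simulate_expression <- function(n_signal = 900L, n_irrelevant = 100L,
                                m = 60L, k = 3L, expression_scale = 50,
                                dominance = 5, flatness = 0.05, seed = 1L,
                                max_retries = 10L) {
  with_seed(seed, {
    tr <- sim_build_truth(n_signal, n_irrelevant, m, k, expression_scale,
                          dominance, flatness)
    A <- sim_draw(tr$W %*% tr$H, 1, max_retries)
    structure(list(A = A, true_labels = tr$labels, W_true = tr$W,
                   H_true = tr$H, irrelevant_gene_ids = tr$irrelevant,
                   seed = as.integer(seed),
                   params = list(n_signal = n_signal,
                                 n_irrelevant = n_irrelevant, m = m, k = k,
                                 expression_scale = expression_scale,
                                 dominance = dominance, flatness = flatness,
                                 c_scale = 1)),
              class = "nmf_sim")
  })
}

#' Simulate scaled-Poisson expression data
#'
#' Variant of [simulate_expression()] for the scaled-Poisson observation
#' model: X ~ Poisson(c * (W_true H_true)_ij) is drawn and A_ij = X / c
#' recorded, so entries are multiples of 1/c and the variance of A_ij is
#' (W_true H_true)_ij / c. With `c = 1` the model coincides with
#' [simulate_expression()].
#'
#' @inheritParams simulate_expression
#' @param c_scale Positive scaling constant c.
#' @return An `nmf_sim`; see [simulate_expression()].
#' @export
simulate_expression_scaled <- function(n_signal = 900L, n_irrelevant = 100L,
                                       m = 60L, k = 3L, expression_scale = 50,
                                       dominance = 5, flatness = 0.05,
                                       c_scale = 1, seed = 1L,
                                       max_retries = 10L) {
  if (c_scale <= 0) stop("c_scale must be positive", call. = FALSE)
  with_seed(seed, {
    tr <- sim_build_truth(n_signal, n_irrelevant, m, k, expression_scale,
                          dominance, flatness)
    A <- sim_draw(tr$W %*% tr$H, c_scale, max_retries)
    structure(list(A = A, true_labels = tr$labels, W_true = tr$W,
                   H_true = tr$H, irrelevant_gene_ids = tr$irrelevant,
                   seed = as.integer(seed),
                   params = list(n_signal = n_signal,
                                 n_irrelevant = n_irrelevant, m = m, k = k,
                                 expression_scale = expression_scale,
                                 dominance = dominance, flatness = flatness,
                                 c_scale = c_scale)),
              class = "nmf_sim")
  })
}

#' @export
print.nmf_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf("Simulated expression: %d genes (%d irrelevant) x %d samples, k = %d\n",
              nrow(x$A), p$n_irrelevant, ncol(x$A), p$k))
  cat(sprintf("  scale %g, dominance %g, seed %d\n",
              p$expression_scale, p$dominance, x$seed))
  invisible(x)
}
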
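#' @importFrom stats runif rpois quantile sd var cor t.test cophenetic hclust as.dist
#' @importFrom utils read.table write.table head
#' @importFrom rlang .data
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate a genes x samples expression matrix. Returns the matrix with
# dimnames guaranteed (synthesised when absent).
validate_expression <- function(A, forbid_zero_rows = FALSE) {
  if (is.data.frame(A)) A <- as.matrix(A)
  if (!is.matrix(A) || !is.numeric(A))
    stop("expression data must be a numeric matrix (genes in rows, samples in columns)",
         call. = FALSE)
  if (anyNA(A)) stop("expression matrix contains missing values", call. = FALSE)
  if (any(A < 0)) {
    bad <- which(A < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative entry at row %d, column %d; expression values must be nonnegative",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (nrow(A) < 1 || ncol(A) < 2)
    stop("need at least 1 gene and 2 samples", call. = FALSE)
  if (is.null(rownames(A))) rownames(A) <- sprintf("gene_%d", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- sprintf("sample_%d", seq_len(ncol(A)))
  if (anyDuplicated(rownames(A))) {
    dup <- rownames(A)[duplicated(rownames(A))][1]
    stop(sprintf("duplicate gene id: '%s'", dup), call. = FALSE)
  }
  if (anyDuplicated(colnames(A))) {
    dup <- colnames(A)[duplicated(colnames(A))][1]
    stop(sprintf("duplicate sample id: '%s'", dup), call. = FALSE)
  }
  if (forbid_zero_rows) {
    zr <- rowSums(A) == 0
    if (any(zr))
      stop(sprintf("gene '%s' has all-zero expression; drop zero rows before fitting",
                   rownames(A)[which(zr)[1]]), call. = FALSE)
  }
  A
}

#' Random initialization of NMF factor matrices
#'
#' Draws the entries of the initial factor pair independently from the
#' uniform distribution on (1e-4, 1]. Strict positivity matters: a zero
#' entry is absorbing under multiplicative updates and can never recover.
#'
#' @param n,m,k Dimensions: genes, samples, and factorization rank.
#' @param seed Integer seed; the same seed reproduces the same factors.
#' @return List with components `W` (n x k) and `H` (k x m).
#' @export
init_factors <- function(n, m, k, seed) {
  n <- as.integer(n); m <- as.integer(m); k <- as.integer(k)
  if (any(c(n, m, k) < 1)) stop("dimensions must be positive integers", call. = FALSE)
  if (k > min(n, m))
    stop(sprintf("rank k = %d exceeds min(n, m) = %d", k, min(n, m)), call. = FALSE)
  eps <- 1e-4
  with_seed(seed, {
    list(W = matrix(eps + runif(n * k) * (1 - eps), n, k),
         H = matrix(eps + runif(k * m) * (1 - eps), k, m))
  })
}

#' Generalized Kullback-Leibler divergence between A and WH
#'
#' The loss minimized by the multiplicative updates,
#' \deqn{L(A, WH) = \sum_{ij} A_{ij} \log(A_{ij}/(WH)_{ij}) - A_{ij} + (WH)_{ij},}
#' with the limit convention \eqn{0 \log(0/x) = 0}. Up to a constant this
#' is the negative log-likelihood of A under independent Poisson
#' observations with means \eqn{(WH)_{ij}}.
#'
#' @param A Nonnegative matrix being approximated.
#' @param W,H Factor matrices with conformable shapes.
#' @return Nonnegative scalar divergence.
#' @export
kl_divergence <- function(A, W, H) {
  WH <- W %*% H
  if (!all(dim(WH) == dim(A))) stop("non-conformable shapes", call. = FALSE)
  pos <- A > 0
  if (any(pos & WH == 0))
    stop("infinite divergence: A > 0 where WH = 0", call. = FALSE)
  d <- sum(WH) - sum(A) + sum(A[pos] * log(A[pos] / WH[pos]))
  # exact reconstruction can land a rounding hair below zero
  if (d < 0 && d > -1e-8) d <- 0
  d
}

#' One coupled multiplicative update (KL divergence)
#'
#' Applies the H update first, then the W update using the already-updated
#' H, matching the order in which the coupled rules are stated:
#' \deqn{H_{au} \leftarrow H_{au} \frac{\sum_i W_{ia} A_{iu}/(WH)_{iu}}{\sum_l W_{la}}, \quad
#'       W_{ia} \leftarrow W_{ia} \frac{\sum_u H_{au} A_{iu}/(WH)_{iu}}{\sum_v H_{av}}.}
#' Both factors are floored at 1e-12 afterwards so later divisions and
#' logs stay finite. The update never increases the divergence.
#'
#' @inheritParams kl_divergence
#' @return List with updated `W` and `H`.
#' @export
nmf_update_step <- function(A, W, H) {
  eps <- 1e-12
  WH <- W %*% H
  H <- H * crossprod(W, A / (WH + eps)) / (colSums(W) + eps)
  H[H < eps] <- eps
  WH <- W %*% H
  W <- W * tcrossprod(A / (WH + eps), H) /
    rep(rowSums(H) + eps, each = nrow(W))
  W[W < eps] <- eps
  list(W = W, H = H)
}

# canonical relabeling: two label vectors induce the same connectivity
# matrix iff their canonical forms are identical
canonical_labels <- function(labels) match(labels, unique(labels))

nmf_engine <- function(A, k, seed, max_iter, check_every, stall_checks,
                       update, loss_fun) {
  n <- nrow(A); m <- ncol(A)
  fac <- init_factors(n, m, k, seed)
  W <- fac$W; H <- fac$H
  prev_part <- NULL
  stall <- 0L
  converged <- FALSE
  n_iter <- 0L
  trace <- numeric(0)
  while (n_iter < max_iter) {
    fac <- update(A, W, H)
    W <- fac$W; H <- fac$H
    n_iter <- n_iter + 1L
    if (n_iter %% check_every == 0L || n_iter == max_iter) {
      trace <- c(trace, loss_fun(A, W, H))
      part <- canonical_labels(max.col(t(H), ties.method = "first"))
      if (!is.null(prev_part) && identical(part, prev_part)) {
        stall <- stall + 1L
        if (stall >= stall_checks) { converged <- TRUE; break }
      } else stall <- 0L
      prev_part <- part
    }
  }
  list(W = W, H = H, loss = loss_fun(A, W, H), loss_trace = trace,
       n_iter = n_iter, converged = converged)
}

#' Fit a basic NMF by Kullback-Leibler multiplicative updates
#'
#' Factorizes a nonnegative genes x samples matrix A into W (genes x k
#' metagenes) and H (k x samples metagene expression patterns) by
#' minimizing the generalized KL divergence with the coupled
#' multiplicative updates, starting from a seeded random initialization.
#'
#' The run stops when the sample partition induced by the column-wise
#' argmax of H has been unchanged at `stall_checks` consecutive checks
#' (spaced `check_every` iterations apart) or when `max_iter` iterations
#' are reached. The divergence is recorded at every check; it is
#' non-increasing along the iteration.
#'
#' @param A Nonnegative numeric matrix, genes in rows. All-zero rows are
#'   rejected: they carry no signal and break the updates.
#' @param k Factorization rank (number of metagenes), `k <= min(n, m)`.
#' @param seed Integer seed controlling the initialization.
#' @param max_iter Iteration cap.
#' @param check_every Iterations between convergence checks.
#' @param stall_checks Consecutive unchanged checks required to declare
#'   convergence. Pass `Inf` to always run to `max_iter`.
#' @return An object of class `nmf_fit`: a list with `W`, `H`, final
#'   `loss`, the per-check `loss_trace`, `n_iter`, `converged`, `seed`,
#'   `k`, and `method`.
#' @examples
#' A <- outer(c(1, 2, 3), c(4, 5))
#' fit <- fit_nmf(A, k = 1, seed = 1)
#' fit$loss
#' @export
fit_nmf <- function(A, k, seed, max_iter = 2000L, check_every = 10L,
                    stall_checks = 4L) {
  A <- validate_expression(A, forbid_zero_rows = TRUE)
  if (k > min(dim(A)))
    stop(sprintf("rank k = %d exceeds min(n, m) = %d", k, min(dim(A))), call. = FALSE)
  res <- nmf_engine(A, k, seed, max_iter, check_every, stall_checks,
                    update = nmf_update_step, loss_fun = kl_divergence)
  rownames(res$W) <- rownames(A)
  colnames(res$H) <- colnames(A)
  structure(c(res, list(seed = as.integer(seed), k = as.integer(k),
                        method = "kl")),
            class = "nmf_fit")
}

# Lee-Seung multiplicative updates for the squared Euclidean loss
eu_update_step <- function(A, W, H) {
  eps <- 1e-12
  H <- H * crossprod(W, A) / (crossprod(W, W %*% H) + eps)
  H[H < eps] <- eps
  W <- W * tcrossprod(A, H) / (W %*% tcrossprod(H) + eps)
  W[W < eps] <- eps
  list(W = W, H = H)
}

eu_loss <- function(A, W, H) sum((A - W %*% H)^2)

#' Fit NMF minimizing squared Euclidean distance
#'
#' Variant of [fit_nmf()] using the standard Lee-Seung Euclidean
#' multiplicative updates and the loss \eqn{\sum_{ij} (A_{ij} - (WH)_{ij})^2}.
#' Same initialization, stopping rule, and return shape.
#'
#' @inheritParams fit_nmf
#' @return An `nmf_fit` with `method = "euclidean"`.
#' @export
fit_nmf_eu <- function(A, k, seed, max_iter = 2000L, check_every = 10L,
                       stall_checks = 4L) {
  A <- validate_expression(A, forbid_zero_rows = TRUE)
  if (k > min(dim(A)))
    stop(sprintf("rank k = %d exceeds min(n, m) = %d", k, min(dim(A))), call. = FALSE)
  res <- nmf_engine(A, k, seed, max_iter, check_every, stall_checks,
                    update = eu_update_step, loss_fun = eu_loss)
  rownames(res$W) <- rownames(A)
  colnames(res$H) <- colnames(A)
  structure(c(res, list(seed = as.integer(seed), k = as.integer(k),
                        method = "euclidean")),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit (%s loss): %d genes x %d samples, k = %d\n",
              x$method, nrow(x$W), ncol(x$H), x$k))
  cat(sprintf("  loss = %.6g after %d iterations (%s)\n", x$loss, x$n_iter,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an NMF fit into a long tibble of metagene expression
#'
#' One row per (metagene, sample) entry of H.
#'
#' @param x An `nmf_fit`.
#' @param ... Unused.
#' @return Tibble with columns `metagene`, `sample`, `expression`.
#' @export
tidy.nmf_fit <- function(x, ...) {
  H <- x$H
  tibble::tibble(
    metagene = rep(seq_len(nrow(H)), times = ncol(H)),
    sample = rep(colnames(H) %||% as.character(seq_len(ncol(H))), each = nrow(H)),
    expression = as.vector(H)
  )
}

#' One-row summary of an NMF fit
#'
#' @param x An `nmf_fit`.
#' @param ... Unused.
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble::tibble(k = x$k, loss = x$loss, n_iter = x$n_iter,
                 converged = x$converged, method = x$method, seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
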
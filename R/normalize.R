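#' Normalization schemes for metagene columns
#'
#' Names of the supported column statistics: the maximum (infinity) norm,
#' the 1-, 2- and 3-norms, the sample standard deviation, and the 0.95,
#' 0.75 and 0.5 sample quantiles. Each maps a nonnegative column of W to
#' a positive scalar and is positively homogeneous of degree 1
#' (stat(c v) = c stat(v) for c > 0), the property that makes the
#' normalized factorization invariant under diagonal rescaling.
#'
#' @return Character vector of scheme names.
#' @export
norm_schemes <- function() c("max", "norm1", "norm2", "norm3", "sd", "q95", "q75", "q50")

#' Column statistic used for factor normalization
#'
#' @param v Nonnegative numeric vector (a column of W).
#' @param scheme One of [norm_schemes()].
#' @return Positive scalar.
#' @details Quantiles use the linear-interpolation definition
#'   (`stats::quantile` type 7). The standard deviation uses the n-1
#'   denominator. An all-zero column, or a constant column under the
#'   `sd` scheme, yields a zero statistic and is rejected: a degenerate
#'   metagene usually means the chosen rank is too large.
#' @export
column_statistic <- function(v, scheme = norm_schemes()) {
  scheme <- match.arg(scheme)
  if (!any(v > 0)) stop("degenerate column: all entries are zero", call. = FALSE)
  s <- switch(scheme,
    max = max(v),
    norm1 = sum(abs(v)),
    norm2 = sqrt(sum(v^2)),
    norm3 = sum(abs(v)^3)^(1 / 3),
    sd = sd(v),
    q95 = unname(quantile(v, 0.95, type = 7)),
    q75 = unname(quantile(v, 0.75, type = 7)),
    q50 = unname(quantile(v, 0.50, type = 7))
  )
  if (!is.finite(s) || s <= 0)
    stop(sprintf("degenerate column under scheme '%s' (statistic = %g)", scheme, s),
         call. = FALSE)
  s
}

#' Normalize a factorization by a column statistic
#'
#' Resolves the diagonal-rescaling ambiguity of NMF: for any positive
#' diagonal D, (W D^-1, D H) reconstructs the same product as (W, H), so
#' the raw factors are only defined up to a per-metagene scale. This
#' function picks the representative whose W columns have unit statistic:
#' D_j = stat(W[, j]), W' = W D^-1, H' = D H. The product W'H' equals WH
#' exactly, so the fit to the data is untouched; only the split between
#' the factors changes.
#'
#' Under the `max` scheme every entry of W' lies in [0, 1] and each
#' column attains 1, supporting the reading of W' entries as membership
#' weights of genes in metagenes.
#'
#' @param W,H Factor matrices from [fit_nmf()].
#' @param scheme Column statistic name, see [norm_schemes()].
#' @return Object of class `nmf_normalized`: list with `W`, `H`, the
#'   diagonal `d`, and `scheme`.
#' @export
normalize_factorization <- function(W, H, scheme = "max") {
  scheme <- match.arg(scheme, norm_schemes())
  if (nrow(H) != ncol(W)) stop("W and H are non-conformable", call. = FALSE)
  d <- vapply(seq_len(ncol(W)), function(j) {
    tryCatch(column_statistic(W[, j], scheme),
             error = function(e) stop(sprintf("metagene %d: %s", j, conditionMessage(e)),
                                      call. = FALSE))
  }, numeric(1))
  structure(list(W = sweep(W, 2, d, "/"), H = sweep(H, 1, d, "*"),
                 d = d, scheme = scheme),
            class = "nmf_normalized")
}

#' @export
print.nmf_normalized <- function(x, ...) {
  cat(sprintf("Normalized NMF factors (scheme '%s'): %d genes x %d metagenes x %d samples\n",
              x$scheme, nrow(x$W), ncol(x$W), ncol(x$H)))
  cat("  diagonal:", format(x$d, digits = 4), "\n")
  invisible(x)
}

#' Check invariance of normalization under diagonal rescaling
#'
#' Verifies that normalizing (W diag(d)^-1, diag(d) H) gives the same
#' (W', H') as normalizing (W, H), which degree-1 homogeneity of the
#' column statistic guarantees for every scheme.
#'
#' @param W,H Factor matrices.
#' @param scheme Column statistic name.
#' @param d Positive vector, the diagonal of the rescaling.
#' @param tol Entrywise absolute tolerance.
#' @return `TRUE` if the two normalized pairs agree within `tol`.
#' @export
rescaling_invariance_check <- function(W, H, scheme = "max", d, tol = 1e-10) {
  if (any(d <= 0)) stop("rescaling diagonal must be strictly positive", call. = FALSE)
  base <- normalize_factorization(W, H, scheme)
  resc <- normalize_factorization(sweep(W, 2, d, "/"), sweep(H, 1, d, "*"), scheme)
  max(abs(base$W - resc$W)) <= tol && max(abs(base$H - resc$H)) <= tol
}
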
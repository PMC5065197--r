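new_filter_report <- function(gene_ids, u, keep, threshold, frac, kind) {
  structure(list(kept_gene_ids = gene_ids[keep],
                 discarded_gene_ids = gene_ids[!keep],
                 u = stats::setNames(u, gene_ids),
                 threshold = threshold, frac = frac, kind = kind),
            class = "filter_report")
}

#' Embedded max-min gene filter
#'
#' Genes whose membership weights are nearly equal across all metagenes of
#' the normalized W cannot discriminate between the typical expression
#' programs and only add noise to the factorization. For each gene the
#' spread u_i = max_j W'_ij - min_j W'_ij is computed; genes with spread
#' at or below the `frac`-quantile of u (default: the median) are
#' discarded. The comparison is inclusive, so exact ties at the threshold
#' are all removed.
#'
#' The filter is "embedded" because u comes from a first NMF fit; the
#' usual pipeline ([post_process_cluster()]) refits on the kept genes.
#'
#' @param W_norm Normalized W matrix (genes x metagenes), e.g. the `W`
#'   component of [normalize_factorization()].
#' @param gene_ids Gene identifiers; defaults to `rownames(W_norm)`.
#' @param frac Fraction of genes targeted for removal, in (0, 1). The
#'   threshold is the `frac`-quantile (linear interpolation) of u.
#' @return A `filter_report`: kept and discarded gene ids, the spread
#'   vector `u`, the `threshold`, `frac`, and the filter `kind`.
#' @export
embedded_filter <- function(W_norm, gene_ids = rownames(W_norm), frac = 0.5) {
  if (!is.matrix(W_norm)) W_norm <- as.matrix(W_norm)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(nrow(W_norm)))
  if (length(gene_ids) != nrow(W_norm))
    stop("gene_ids length does not match W", call. = FALSE)
  if (!is.numeric(frac) || frac <= 0 || frac >= 1)
    stop("frac must lie strictly between 0 and 1", call. = FALSE)
  u <- apply(W_norm, 1, max) - apply(W_norm, 1, min)
  threshold <- unname(quantile(u, frac, type = 7))
  keep <- u > threshold
  if (!any(keep))
    warning("all genes fall at or below the spread threshold; every gene discarded",
            call. = FALSE)
  new_filter_report(gene_ids, u, keep, threshold, frac, "embedded")
}

#' Variance gene filter
#'
#' Ranks genes by the sample variance of their expression row (n-1
#' denominator) and keeps the top `ceiling(keep_fraction * n)`. Unlike
#' the embedded filter it is independent of any factorization, so the
#' pipeline needs only a single NMF fit.
#'
#' @param A Expression matrix, genes in rows.
#' @param keep_fraction Fraction of genes kept, in (0, 1].
#' @return A `filter_report` whose `u` holds the per-gene variances.
#' @export
variance_filter <- function(A, keep_fraction = 0.5) {
  A <- validate_expression(A)
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must lie in (0, 1]", call. = FALSE)
  v <- apply(A, 1, var)
  n_keep <- ceiling(keep_fraction * nrow(A))
  ord <- order(v, decreasing = TRUE)       # stable: ties keep original order
  keep <- logical(nrow(A))
  keep[ord[seq_len(n_keep)]] <- TRUE
  threshold <- if (n_keep < nrow(A)) v[ord[n_keep]] else -Inf
  new_filter_report(rownames(A), v, keep, threshold, keep_fraction, "variance")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("%s filter: kept %d / %d genes (threshold %.4g)\n",
              x$kind, length(x$kept_gene_ids),
              length(x$kept_gene_ids) + length(x$discarded_gene_ids),
              x$threshold))
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  tibble::tibble(gene_id = names(x$u),
                 statistic = unname(x$u),
                 kept = names(x$u) %in% x$kept_gene_ids)
}

#' Post-processing pipeline: NMF, normalization, optional filter, clustering
#'
#' Runs the full class-discovery pipeline on an expression matrix:
#'
#' * `filter = "none"`: one NMF fit; each row of H is multiplied by the
#'   chosen statistic of the matching W column; samples are assigned to
#'   the metagene with the largest normalized H entry.
#' * `filter = "embedded"`: a first fit and normalization produce the
#'   gene spreads u; genes at or below the `frac`-quantile of u are
#'   dropped; NMF is refit on the reduced matrix (with seed `seed + 1`,
#'   so the whole pipeline is reproducible from one integer) and the
#'   second fit's normalized H is clustered.
#' * `filter = "variance"`: the variance filter keeps the top
#'   `1 - frac` fraction of genes first; then a single fit and
#'   normalization as for `"none"`.
#'
#' `scheme = "none"` skips normalization (the unnormalized baseline);
#' it cannot be combined with the embedded filter, which needs the
#' normalized W.
#'
#' @param A Expression matrix, genes in rows.
#' @param k Number of clusters / metagenes.
#' @param seed Integer seed for the (first) NMF initialization.
#' @param scheme Normalization scheme name, or `"none"`.
#' @param filter `"embedded"`, `"variance"`, or `"none"`.
#' @param frac Fraction of genes removed by the filter (default 0.5).
#' @param ... Passed on to [fit_nmf()].
#' @return Object of class `nmf_cluster`: list with the final normalized
#'   `H`, an `assignment` tibble (`sample_id`, `cluster`, `strength`),
#'   the `filter_report` (or `NULL`), `labels` (integer vector), and the
#'   run configuration.
#' @export
post_process_cluster <- function(A, k, seed, scheme = "max",
                                 filter = c("embedded", "variance", "none"),
                                 frac = 0.5, ...) {
  filter <- match.arg(filter)
  scheme <- match.arg(scheme, c(norm_schemes(), "none"))
  if (scheme == "none" && filter == "embedded")
    stop("the embedded filter requires a normalization scheme", call. = FALSE)
  A <- validate_expression(A)
  report <- NULL

  if (filter == "variance") {
    report <- variance_filter(A, keep_fraction = 1 - frac)
    A <- A[report$kept_gene_ids, , drop = FALSE]
  }

  fit <- fit_nmf(A, k, seed, ...)

  if (filter == "embedded") {
    nrm0 <- normalize_factorization(fit$W, fit$H, scheme)
    report <- embedded_filter(nrm0$W, rownames(A), frac)
    if (length(report$kept_gene_ids) == 0)
      stop("embedded filter discarded every gene; nothing left to refit",
           call. = FALSE)
    A1 <- A[report$kept_gene_ids, , drop = FALSE]
    fit <- fit_nmf(A1, k, seed + 1L, ...)
  }

  H2 <- if (scheme == "none") fit$H
        else normalize_factorization(fit$W, fit$H, scheme)$H
  labels <- assign_clusters(H2)
  assignment <- tibble::tibble(
    sample_id = colnames(H2) %||% as.character(seq_len(ncol(H2))),
    cluster = as.integer(labels),
    strength = H2[cbind(labels, seq_len(ncol(H2)))]
  )
  structure(list(H = H2, assignment = assignment, labels = unname(labels),
                 filter_report = report, fit = fit,
                 k = as.integer(k), scheme = scheme, filter = filter,
                 frac = frac, seed = as.integer(seed)),
            class = "nmf_cluster")
}

#' @export
print.nmf_cluster <- function(x, ...) {
  cat(sprintf("NMF clustering: k = %d, scheme = %s, filter = %s, seed = %d\n",
              x$k, x$scheme, x$filter, x$seed))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
tidy.nmf_cluster <- function(x, ...) x$assignment

#' @export
glance.nmf_cluster <- function(x, ...) {
  tibble::tibble(k = x$k, scheme = x$scheme, filter = x$filter,
                 n_samples = length(x$labels),
                 n_genes_used = nrow(x$fit$W),
                 loss = x$fit$loss, seed = x$seed)
}
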
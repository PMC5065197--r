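#' Assign samples to clusters by the largest metagene coefficient
#'
#' Sample j goes to cluster i when H[i, j] is the largest entry of column
#' j. Ties resolve to the smallest row index.
#'
#' @param H k x m nonnegative matrix (typically normalized).
#' @return Integer vector of length m with values in 1..k, named by the
#'   column names of H when present.
#' @export
assign_clusters <- function(H) {
  if (!is.matrix(H)) H <- as.matrix(H)
  zero <- colSums(H) == 0
  if (any(zero)) {
    id <- colnames(H)[which(zero)[1]] %||% as.character(which(zero)[1])
    stop(sprintf("sample '%s' has an all-zero column in H", id), call. = FALSE)
  }
  labels <- max.col(t(H), ties.method = "first")
  names(labels) <- colnames(H)
  labels
}

#' Binary connectivity matrix of a cluster assignment
#'
#' Entry (i, j) is 1 when samples i and j share a cluster label.
#'
#' @param labels Integer vector of cluster labels.
#' @return Symmetric m x m 0/1 matrix with unit diagonal.
#' @export
connectivity_matrix <- function(labels) {
  outer(labels, labels, `==`) + 0
}

#' Consensus matrix over repeated seeded NMF runs
#'
#' Runs the fit-normalize-assign pipeline `nloop` times with seeds
#' `base_seed, base_seed + 1, ...` and averages the binary connectivity
#' matrices. When the clustering at rank k is stable, each pair of
#' samples is either almost always or almost never co-clustered, so the
#' entries concentrate near 0 and 1.
#'
#' By default no gene filter is applied (the rank-selection procedure
#' operates on the full matrix); pass `filter = "embedded"` to run the
#' filtered pipeline inside each loop.
#'
#' @param A Expression matrix, genes in rows.
#' @param k Factorization rank.
#' @param nloop Number of seeded runs (>= 2).
#' @param base_seed First seed.
#' @param scheme Normalization scheme (default `"max"`).
#' @param filter Gene filter inside each run; default `"none"`.
#' @param frac Filter fraction, see [post_process_cluster()].
#' @return Object of class `nmf_consensus`: list with the m x m matrix
#'   `C`, `nloop`, `k`, `scheme`, and `base_seed`.
#' @export
consensus_matrix <- function(A, k, nloop = 50L, base_seed = 1L,
                             scheme = "max", filter = "none", frac = 0.5) {
  if (nloop < 2) stop("nloop must be at least 2", call. = FALSE)
  A <- validate_expression(A)
  m <- ncol(A)
  C <- matrix(0, m, m)
  for (i in seq_len(nloop)) {
    cl <- post_process_cluster(A, k, seed = base_seed + i - 1L,
                               scheme = scheme, filter = filter, frac = frac)
    C <- C + connectivity_matrix(cl$labels)
  }
  C <- C / nloop
  dimnames(C) <- list(colnames(A), colnames(A))
  structure(list(C = C, nloop = as.integer(nloop), k = as.integer(k),
                 scheme = scheme, base_seed = as.integer(base_seed)),
            class = "nmf_consensus")
}

#' @export
print.nmf_consensus <- function(x, ...) {
  off <- x$C[upper.tri(x$C)]
  cat(sprintf("Consensus matrix: %d samples, k = %d, %d runs\n",
              nrow(x$C), x$k, x$nloop))
  cat(sprintf("  off-diagonal entries within 0.05 of {0,1}: %.1f%%\n",
              100 * mean(off <= 0.05 | off >= 0.95)))
  invisible(x)
}

#' Heatmap of a consensus matrix
#'
#' Samples are reordered by average-linkage hierarchical clustering of
#' 1 - C so that stable blocks appear along the diagonal.
#'
#' @param object An `nmf_consensus`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmf_consensus <- function(object, ...) {
  C <- object$C
  ord <- hclust(as.dist(1 - C), method = "average")$order
  C <- C[ord, ord]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(C)), times = ncol(C)),
    col = rep(seq_len(ncol(C)), each = nrow(C)),
    consensus = as.vector(C)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix (k = %d, %d runs)",
                                  object$k, object$nloop)) +
    ggplot2::theme_minimal()
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Measures how faithfully a hierarchical clustering of the
#' consensus-derived distances reproduces them: 1 - C is treated as a
#' distance matrix, average-linkage hierarchical clustering is applied,
#' and the Pearson correlation between the original distances and the
#' cophenetic distances of the resulting dendrogram is returned (each
#' sample pair counted once). A consensus matrix that is exactly block
#' binary yields r = 1 because 1 - C is then ultrametric.
#'
#' @param C An `nmf_consensus` or a bare m x m consensus matrix (m >= 3).
#' @return Correlation in [-1, 1].
#' @export
cophenetic_coefficient <- function(C) {
  if (inherits(C, "nmf_consensus")) C <- C$C
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop("C must be a square consensus matrix", call. = FALSE)
  if (nrow(C) < 3) stop("need at least 3 samples", call. = FALSE)
  d <- as.dist(1 - C)
  if (sd(as.vector(d)) == 0)
    stop("all pairwise consensus distances are equal; correlation undefined",
         call. = FALSE)
  hc <- hclust(d, method = "average")
  cor(as.vector(d), as.vector(cophenetic(hc)))
}

#' Scan factorization ranks by consensus stability
#'
#' For each k in `k_range`, builds a consensus matrix over `nloop`
#' seeded runs of the normalize-then-assign pipeline and computes its
#' cophenetic correlation coefficient. A larger coefficient means the
#' clustering at that rank is more reproducible across random
#' initializations, which is the evidence used to pick k. The
#' recommended rank is the smallest k attaining the maximum.
#'
#' @param A Expression matrix, genes in rows.
#' @param k_range Integer vector of candidate ranks (default 2:5).
#' @param nloop Runs per rank.
#' @param base_seed First seed (shared across ranks).
#' @param scheme Normalization scheme.
#' @return A tibble of class `nmf_rank_scan` with columns `k` and
#'   `cophenetic`; the recommended rank is in `attr(., "recommended_k")`
#'   and via [recommended_k()].
#' @export
select_k <- function(A, k_range = 2:5, nloop = 50L, base_seed = 1L,
                     scheme = "max") {
  r <- vapply(k_range, function(k) {
    cophenetic_coefficient(consensus_matrix(A, k, nloop = nloop,
                                            base_seed = base_seed,
                                            scheme = scheme))
  }, numeric(1))
  out <- tibble::tibble(k = as.integer(k_range), cophenetic = r)
  attr(out, "recommended_k") <- out$k[which.max(out$cophenetic)]
  class(out) <- c("nmf_rank_scan", class(out))
  out
}

#' Recommended rank from a rank scan
#'
#' @param scan Result of [select_k()].
#' @return The smallest k maximizing the cophenetic correlation.
#' @export
recommended_k <- function(scan) attr(scan, "recommended_k")

#' Cophenetic correlation versus rank
#'
#' @param object An `nmf_rank_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmf_rank_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$cophenetic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = object[object$k == recommended_k(object), ],
                        colour = "#b2182b", size = 3) +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "rank k", y = "cophenetic correlation") +
    ggplot2::theme_minimal()
}
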
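#' Permutation-matched clustering accuracy
#'
#' Cluster labels are arbitrary, so predicted clusters are matched
#' one-to-one to true classes by the assignment maximizing the number of
#' agreeing samples (Hungarian algorithm on the contingency table,
#' zero-padded to square when the label counts differ; unmatched
#' predicted clusters contribute nothing). The accuracy is the matched
#' agreement as a percentage of samples.
#'
#' @param pred,truth Integer (or factor) label vectors of equal length.
#' @return Accuracy in [0, 100].
#' @export
clustering_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth have different lengths", call. = FALSE)
  pred <- canonical_labels(pred)
  truth <- canonical_labels(truth)
  kp <- max(pred); kt <- max(truth)
  d <- max(kp, kt)
  tab <- matrix(0, d, d)
  for (i in seq_along(pred)) tab[pred[i], truth[i]] <- tab[pred[i], truth[i]] + 1
  perm <- clue::solve_LSAP(tab, maximum = TRUE)
  100 * sum(tab[cbind(seq_len(d), perm)]) / length(pred)
}

#' Repeated-seed clustering experiment
#'
#' Runs [post_process_cluster()] `n_runs` times with consecutive seeds
#' `base_seed, base_seed + 1, ...`, scores each run against the true
#' labels with [clustering_accuracy()], and summarizes the runs by their
#' mean accuracy and the standard error of the mean (sd / sqrt(n_runs)).
#'
#' @param A Expression matrix, genes in rows.
#' @param truth True class labels, one per sample.
#' @param k Number of clusters.
#' @param scheme Normalization scheme, or `"none"` for the unnormalized
#'   baseline.
#' @param filter Gene filter: `"embedded"`, `"variance"`, or `"none"`.
#' @param frac Filter fraction.
#' @param n_runs Number of seeded runs.
#' @param base_seed First seed. Two methods run from the same `base_seed`
#'   are paired run-by-run, which is what [compare_methods()] assumes.
#' @param method_id Label for the configuration; autogenerated if `NULL`.
#' @return Object of class `nmf_experiment`: per-seed accuracies plus
#'   `mean`, `sem`, `n_runs`, `method_id`, and the seeds used.
#' @export
run_experiment <- function(A, truth, k, scheme = "max", filter = "embedded",
                           frac = 0.5, n_runs = 100L, base_seed = 1L,
                           method_id = NULL) {
  if (is.null(method_id))
    method_id <- paste0(scheme, if (filter != "none") paste0("+", filter))
  seeds <- base_seed + seq_len(n_runs) - 1L
  acc <- vapply(seeds, function(s) {
    cl <- post_process_cluster(A, k, seed = s, scheme = scheme,
                               filter = filter, frac = frac)
    clustering_accuracy(cl$labels, truth)
  }, numeric(1))
  sem <- if (n_runs > 1) sd(acc) / sqrt(n_runs) else {
    warning("sem undefined for a single run; reported as 0", call. = FALSE)
    0
  }
  structure(list(method_id = method_id, per_seed_accuracy = acc,
                 mean = mean(acc), sem = sem, n_runs = as.integer(n_runs),
                 seeds = as.integer(seeds)),
            class = "nmf_experiment")
}

#' @export
print.nmf_experiment <- function(x, ...) {
  cat(sprintf("%s: mean accuracy %.2f%% (SEM %.2f, %d runs)\n",
              x$method_id, x$mean, x$sem, x$n_runs))
  invisible(x)
}

#' @export
tidy.nmf_experiment <- function(x, ...) {
  tibble::tibble(method = x$method_id, seed = x$seeds,
                 accuracy = x$per_seed_accuracy)
}

#' @export
glance.nmf_experiment <- function(x, ...) {
  tibble::tibble(method = x$method_id, mean = x$mean, sem = x$sem,
                 n_runs = x$n_runs)
}

#' Per-seed accuracies of one or more experiments
#'
#' @param object An `nmf_experiment`.
#' @param ... Further `nmf_experiment` objects to overlay.
#' @return A ggplot object (boxplot of per-seed accuracy by method).
#' @export
autoplot.nmf_experiment <- function(object, ...) {
  extra <- Filter(function(x) inherits(x, "nmf_experiment"), list(...))
  df <- dplyr::bind_rows(lapply(c(list(object), extra), tidy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "clustering accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Paired comparison of two clustering experiments
#'
#' Paired two-sided t-test on per-seed accuracy differences. The two
#' experiments must have equal `n_runs` and identical seed sequences so
#' that run i of each shares the random initialization of the data
#' pipeline. When the differences have zero variance the t statistic is
#' undefined; by convention p is reported as 0 if the means differ and 1
#' if the accuracies are identical (flagged with a warning).
#'
#' @param res_a,res_b `nmf_experiment` objects.
#' @return Tibble with `mean_diff` (a minus b), `statistic`, and
#'   `p_value`.
#' @export
compare_methods <- function(res_a, res_b) {
  if (res_a$n_runs != res_b$n_runs)
    stop("experiments have different numbers of runs", call. = FALSE)
  if (!identical(res_a$seeds, res_b$seeds))
    stop("experiments are not paired: seed sequences differ", call. = FALSE)
  d <- res_a$per_seed_accuracy - res_b$per_seed_accuracy
  if (sd(d) == 0) {
    warning("zero variance in paired differences; degenerate p-value convention used",
            call. = FALSE)
    return(tibble::tibble(mean_diff = mean(d), statistic = NA_real_,
                          p_value = if (mean(d) == 0) 1 else 0))
  }
  tt <- t.test(res_a$per_seed_accuracy, res_b$per_seed_accuracy,
               paired = TRUE, alternative = "two.sided")
  tibble::tibble(mean_diff = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value)
}

#' Keep the most variable genes
#'
#' Subsets the expression matrix to the `n_genes` rows with the largest
#' sample variance, preserving the original row order. Used for sweeps
#' over the number of input genes.
#'
#' @param A Expression matrix, genes in rows.
#' @param n_genes Number of genes to keep.
#' @return The reduced expression matrix.
#' @export
top_varying_subset <- function(A, n_genes) {
  A <- validate_expression(A)
  if (n_genes > nrow(A))
    stop(sprintf("n_genes = %d exceeds the %d genes available", n_genes, nrow(A)),
         call. = FALSE)
  v <- apply(A, 1, var)
  sel <- sort(order(v, decreasing = TRUE)[seq_len(n_genes)])
  A[sel, , drop = FALSE]
}

#' Perturb an expression matrix with additive uniform noise
#'
#' Adds mu * r to every entry, with r drawn independently from
#' Uniform[0, max(A)] — the robustness probe in which the noise amplitude
#' scales with the largest expression value in the matrix. Entries only
#' grow: A <= A' <= A + mu * max(A).
#'
#' @param A Expression matrix.
#' @param mu Nonnegative noise multiplier.
#' @param seed Integer seed.
#' @return Perturbed matrix of the same shape.
#' @export
noise_perturb <- function(A, mu, seed) {
  A <- validate_expression(A)
  if (mu < 0) stop("mu must be nonnegative", call. = FALSE)
  if (mu == 0) return(A)
  r <- with_seed(seed, matrix(runif(length(A), 0, max(A)), nrow(A), ncol(A)))
  A + mu * r
}
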
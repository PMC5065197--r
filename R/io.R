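guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         tsv = "tsv", txt = "tsv", csv = "csv", gct = "gct",
         stop(sprintf("cannot infer format from '%s'; pass format explicitly",
                      basename(path)), call. = FALSE))
}

#' Read an expression matrix from delimited text or GCT 1.2
#'
#' Delimited layout: first row holds sample ids, first column gene ids,
#' the body numeric expression values. GCT 1.2: a `#1.2` header line, a
#' dimensions line, then a table whose first two columns are Name and
#' Description. Negative values, non-numeric cells, and duplicate gene or
#' sample ids are rejected with the offending coordinate named.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"`, or `"gct"`.
#' @return Numeric matrix with gene ids as rownames, sample ids as
#'   colnames.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  if (format == "auto") format <- guess_format(path)

  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3 || trimws(lines[1]) != "#1.2")
      stop("malformed GCT: first line must be '#1.2'", call. = FALSE)
    dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]]))
    if (length(dims) != 2 || anyNA(dims))
      stop("malformed GCT: second line must give 'n_genes n_samples'", call. = FALSE)
    tab <- read.table(text = lines[-(1:2)], header = TRUE, sep = "\t",
                      check.names = FALSE, colClasses = "character")
    if (nrow(tab) != dims[1] || ncol(tab) - 2 != dims[2])
      stop(sprintf("GCT dimension line says %d x %d but table is %d x %d",
                   dims[1], dims[2], nrow(tab), ncol(tab) - 2), call. = FALSE)
    gene_ids <- tab[[1]]
    body <- tab[, -(1:2), drop = FALSE]
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "character")
    if (ncol(tab) < 3)
      stop("expression table needs a gene-id column and at least 2 samples",
           call. = FALSE)
    gene_ids <- tab[[1]]
    body <- tab[, -1, drop = FALSE]
  }

  vals <- suppressWarnings(
    vapply(body, function(col) as.numeric(col), numeric(nrow(body))))
  if (nrow(body) == 1) vals <- matrix(vals, nrow = 1)
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], colnames(body)[bad[1, 2]]), call. = FALSE)
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 gene_ids[neg[1, 1]], colnames(body)[neg[1, 2]]), call. = FALSE)
  rownames(vals) <- gene_ids
  validate_expression(vals)
}

#' Write an expression matrix as delimited text
#'
#' Values are written with 17 significant digits so that reading the file
#' back reproduces the doubles exactly.
#'
#' @param A Expression matrix with dimnames.
#' @param path Output path.
#' @param format `"auto"`, `"tsv"`, or `"csv"`.
#' @export
write_expression <- function(A, path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  A <- validate_expression(A)
  if (format == "auto") format <- guess_format(path)
  if (format == "gct") stop("GCT output is not supported; use tsv or csv", call. = FALSE)
  sep <- if (format == "csv") "," else "\t"
  body <- apply(A, 2, function(col) sprintf("%.17g", col))
  if (nrow(A) == 1) body <- matrix(body, nrow = 1, dimnames = list(NULL, colnames(A)))
  out <- cbind(gene_id = rownames(A), as.data.frame(body, check.names = FALSE))
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Expects two delimited columns without a header: sample id and label.
#' Labels are re-encoded to integers 1..k in order of first appearance.
#' When `sample_ids` is supplied the rows are aligned to that order and
#' any missing or unknown sample is an error.
#'
#' @param path File path (tab, comma, or whitespace delimited).
#' @param sample_ids Optional sample order to align to.
#' @return Named integer vector of labels.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  tab <- read.table(path, header = FALSE, sep = sep, colClasses = "character")
  if (ncol(tab) != 2)
    stop("label file must have exactly two columns: sample_id, label", call. = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample id in label file: '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, ids)
    if (length(missing) > 0)
      stop(sprintf("label file is missing samples: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    unknown <- setdiff(ids, sample_ids)
    if (length(unknown) > 0)
      stop(sprintf("label file has unknown samples: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    tab <- tab[match(sample_ids, ids), ]
    ids <- tab[[1]]
  }
  stats::setNames(match(tab[[2]], unique(tab[[2]])), ids)
}

#' Write per-sample labels or cluster assignments
#'
#' @param labels Named vector of labels (names are sample ids), or an
#'   `nmf_cluster` whose assignment tibble is written with its strength
#'   column.
#' @param path Output path (tab-delimited).
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "nmf_cluster")) {
    out <- labels$assignment
    out$strength <- sprintf("%.17g", out$strength)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(sample_id = names(labels) %||% seq_along(labels),
                      label = as.vector(labels))
    # plain label files carry no header so they read back as written
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
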
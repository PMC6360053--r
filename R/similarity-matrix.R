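#' Construct a labelled similarity matrix
#'
#' A square, symmetric, label-indexed matrix with entries in \[0, 1\].
#' Asymmetry up to `tol` is repaired by averaging with the transpose;
#' values up to `tol` outside \[0, 1\] are clipped. Anything worse errors.
#'
#' @param values square numeric matrix with matching row/column names.
#' @param role optional tag recording what the matrix holds, one of
#'   `"FS"`, `"SS"`, `"KM"`, `"KD"`, `"Sm"`, `"Sd"`.
#' @param tol numeric tolerance for symmetry and range repair.
#' @return A numeric matrix of class `"similarity_matrix"` with a `role`
#'   attribute.
#' @export
similarity_matrix <- function(values, role = NULL, tol = 1e-8) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("similarity matrix must have row and column labels")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column labels must match in the same order")
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    stop(sprintf("matrix is not symmetric (max |M - t(M)| = %.3g)", asym))
  values <- (values + t(values)) / 2
  lo <- min(values)
  hi <- max(values)
  if (lo < -tol || hi > 1 + tol)
    stop(sprintf("entries outside [0, 1]: range [%.6g, %.6g]", lo, hi))
  values[] <- pmin(pmax(values, 0), 1)
  if (!is.null(role))
    role <- match.arg(role, c("FS", "SS", "KM", "KD", "Sm", "Sd"))
  structure(values, role = role, class = c("similarity_matrix", class(unclass(values))))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  role <- attr(x, "role")
  cat(sprintf("<similarity_matrix%s> %d x %d\n",
              if (is.null(role)) "" else paste0(" ", role), nrow(x), ncol(x)))
  invisible(x)
}

#' Read a labelled square similarity matrix from TSV
#'
#' The file's first row and first column carry labels. The row and column
#' label sets must agree (columns are re-aligned to row order when they
#' merely differ in order); the matrix must be symmetric to `1e-8` and its
#' values in \[0, 1\] up to the same slack.
#'
#' @param path path to the TSV file.
#' @param labels optional character vector (e.g. the miRNA labels of an
#'   association matrix); the result is re-indexed to this order. May be a
#'   subset of the file's labels (a curated similarity resource typically
#'   covers more entities than one association catalogue).
#' @param role passed to [similarity_matrix()].
#' @return A `similarity_matrix`.
#' @export
read_similarity_matrix <- function(path, labels = NULL, role = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("similarity file must have a label column plus values")
  rn <- trimws(as.character(tab[[1L]]))
  M <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  colnames(M) <- trimws(colnames(M))
  if (length(rn) != ncol(M))
    stop("similarity matrix is not square: ", length(rn), " rows, ",
         ncol(M), " value columns")
  if (!setequal(rn, colnames(M))) {
    only_r <- setdiff(rn, colnames(M))
    only_c <- setdiff(colnames(M), rn)
    stop("row/column label mismatch; rows only: ",
         paste(only_r, collapse = ", "), "; columns only: ",
         paste(only_c, collapse = ", "))
  }
  rownames(M) <- rn
  M <- M[, rn, drop = FALSE]
  out <- similarity_matrix(M, role = role)
  if (!is.null(labels)) {
    if (!all(labels %in% rn))
      stop("requested labels absent from the matrix: ",
           paste(setdiff(labels, rn), collapse = ", "))
    out <- similarity_matrix(unclass(out)[labels, labels, drop = FALSE],
                             role = role)
  }
  out
}

# Labelled matrix writer shared by similarity matrices and score matrices.
# %.17g keeps doubles exact on round-trip.
write_matrix_tsv <- function(M, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("", colnames(M)), collapse = "\t"), con)
  for (i in seq_len(nrow(M))) {
    writeLines(paste(c(rownames(M)[i], sprintf("%.17g", M[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a similarity (or score) matrix as labelled TSV
#'
#' Values are printed with enough digits that [read_similarity_matrix()]
#' reproduces them exactly.
#'
#' @param M labelled numeric matrix.
#' @param path output path.
#' @export
write_similarity_matrix <- function(M, path) write_matrix_tsv(M, path)
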
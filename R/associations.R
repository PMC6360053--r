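#' Construct a disease x miRNA association matrix
#'
#' Wraps a binary matrix whose rows are diseases and columns are miRNAs.
#' Row `i` is the interaction profile of disease `i`; column `j` the
#' interaction profile of miRNA `j`.
#'
#' @param A numeric or integer matrix of 0/1 entries with unique, non-empty
#'   row and column names.
#' @return An integer matrix of class `"mda_matrix"`.
#' @export
mda_matrix <- function(A) {
  if (!is.matrix(A)) stop("`A` must be a matrix")
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("association matrix needs disease row names and miRNA column names")
  if (anyDuplicated(rownames(A))) stop("duplicate disease labels")
  if (anyDuplicated(colnames(A))) stop("duplicate miRNA labels")
  storage.mode(A) <- "integer"
  if (any(is.na(A)) || any(A != 0L & A != 1L))
    stop("association matrix entries must be 0 or 1")
  class(A) <- c("mda_matrix", class(unclass(A)))
  A
}

#' @export
print.mda_matrix <- function(x, ...) {
  cat(sprintf("<mda_matrix> %d diseases x %d miRNAs, %d known associations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Disease labels of an association matrix
#' @param A an `mda_matrix`.
#' @return Character vector of labels.
#' @export
diseases <- function(A) rownames(A)

#' miRNA labels of an association matrix
#' @rdname diseases
#' @export
mirnas <- function(A) colnames(A)

# Read a 2+ column TSV, skipping '#' comments and blank lines; returns the
# first two trimmed fields plus original line numbers (for error messages).
read_two_col_tsv <- function(path, header = FALSE, what = "record") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  lines <- lines[keep]
  if (header && length(lines)) {
    lines <- lines[-1]
    idx <- idx[-1]
  }
  if (!length(lines)) stop("no ", what, "s found in '", path, "'")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("malformed ", what, " at line ", idx[bad[1]],
         " of '", path, "': expected at least 2 tab-separated fields")
  a <- trimws(vapply(parts, `[[`, character(1), 1L))
  b <- trimws(vapply(parts, `[[`, character(1), 2L))
  empty <- which(!nzchar(a) | !nzchar(b))
  if (length(empty))
    stop("empty field at line ", idx[empty[1]], " of '", path, "'")
  list(a = a, b = b, line = idx)
}

#' Read a disease-miRNA association list
#'
#' Reads a two-column TSV (`disease<TAB>miRNA`) and builds the binary
#' adjacency matrix. Duplicate pairs collapse to a single 1. Label order on
#' each axis is first-appearance order; downstream functions index by label,
#' so the ordering is cosmetic. Lines starting with `#` are skipped.
#'
#' @param path path to the TSV file.
#' @param header logical; if `TRUE` the first non-comment line is dropped.
#' @param normalize_case logical; lowercase labels on both axes before
#'   matching (for merging heterogeneous sources; default keeps case, since
#'   ontology names are case-sensitive in practice).
#' @return An [mda_matrix()].
#' @export
read_associations <- function(path, header = FALSE, normalize_case = FALSE) {
  rec <- read_two_col_tsv(path, header = header, what = "association")
  d <- rec$a
  m <- rec$b
  if (normalize_case) {
    d <- tolower(d)
    m <- tolower(m)
  }
  dl <- unique(d)
  ml <- unique(m)
  A <- matrix(0L, length(dl), length(ml), dimnames = list(dl, ml))
  A[cbind(match(d, dl), match(m, ml))] <- 1L
  mda_matrix(A)
}

#' Write an association matrix back to a two-column TSV
#'
#' Inverse of [read_associations()] up to line order: one
#' `disease<TAB>miRNA` row per known association, in row-major order.
#'
#' @param A an `mda_matrix`.
#' @param path output path.
#' @export
write_associations <- function(A, path) {
  ij <- which(t(unclass(A)) == 1L, arr.ind = TRUE)  # row-major order
  lines <- sprintf("%s\t%s", rownames(A)[ij[, 2L]], colnames(A)[ij[, 1L]])
  writeLines(lines, path)
  invisible(path)
}
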
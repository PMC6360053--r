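#' KNN recommendation: densify the association network
#'
#' For every disease the `k` most similar *other* diseases are looked up in
#' the integrated disease similarity; a miRNA edge is recommended when at
#' least `vote_threshold` of those neighbours carry it. Recommended edges
#' are unioned with the original ones, so augmentation only ever adds
#' edges. `knn_augment_by_mirna()` is the mirror image, voting over the
#' disease axis with miRNA neighbours.
#'
#' Ties at the k-th similarity are broken by ascending label index so runs
#' are deterministic; an entity is never its own neighbour. The default
#' `vote_threshold` of a strict majority (`floor(k/2) + 1`) reflects the
#' reading that "most" neighbours must agree.
#'
#' @param A an [mda_matrix()] (the training associations).
#' @param S integrated similarity over the voting axis (`Sd` for diseases,
#'   `Sm` for miRNAs), labels matching `A`'s axis.
#' @param k number of neighbours, `>= 1` and less than the axis size.
#' @param vote_threshold minimum agreeing neighbours, in `[1, k]`.
#' @return A binary matrix of the same shape and labels as `A`, elementwise
#'   `>= A`.
#' @export
knn_augment_by_disease <- function(A, S, k = 3, vote_threshold = floor(k / 2) + 1) {
  check_knn_args(nrow(A), rownames(A), S, k, vote_threshold, "disease")
  X <- unclass(A)
  out <- X
  n <- nrow(X)
  for (i in seq_len(n)) {
    nb <- knn_neighbors(unclass(S), i, k)
    votes <- colSums(X[nb, , drop = FALSE])
    out[i, votes >= vote_threshold] <- 1L
  }
  out[X == 1L] <- 1L
  out
}

#' @rdname knn_augment_by_disease
#' @export
knn_augment_by_mirna <- function(A, S, k = 3, vote_threshold = floor(k / 2) + 1) {
  check_knn_args(ncol(A), colnames(A), S, k, vote_threshold, "miRNA")
  X <- unclass(A)
  out <- X
  n <- ncol(X)
  for (j in seq_len(n)) {
    nb <- knn_neighbors(unclass(S), j, k)
    votes <- rowSums(X[, nb, drop = FALSE])
    out[votes >= vote_threshold, j] <- 1L
  }
  out[X == 1L] <- 1L
  out
}

# k most-similar other indices for entity i; descending similarity,
# ascending index among ties.
knn_neighbors <- function(S, i, k) {
  cand <- seq_len(nrow(S))[-i]
  cand[order(-S[i, cand], cand)][seq_len(k)]
}

check_knn_args <- function(n, labels, S, k, vote_threshold, axis) {
  if (k < 1L) stop("`k` must be at least 1")
  if (k >= n) stop("`k` must be smaller than the number of ", axis, "s (", n, ")")
  if (vote_threshold < 1L || vote_threshold > k)
    stop("`vote_threshold` must lie in [1, k]")
  if (!identical(rownames(S), labels))
    stop("similarity labels do not match the ", axis, " labels of `A`")
  invisible(TRUE)
}
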
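#' Semantic contribution of ancestor terms to a disease
#'
#' The contribution of a term `t` in the ancestor closure `T(D)` to the
#' semantic value of disease `D` is 1 for `D` itself, and otherwise
#' `delta` times the largest contribution among `t`'s children that lie in
#' `T(D)`. The decay factor `delta` makes remote ancestors count less;
#' children outside `T(D)` lie on no path from `D` and contribute nothing.
#'
#' @param dag a [disease_dag()].
#' @param D disease term, a node of `dag`.
#' @param delta decay factor in (0, 1]; default 0.5.
#' @return Named numeric vector over `T(D)`; `D` maps to 1.
#' @export
semantic_contribution <- function(dag, D, delta = 0.5) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1)
    stop("`delta` must be a single number in (0, 1]")
  td <- dag_ancestors(dag, D)
  memo <- new.env(parent = emptyenv())
  assign(D, 1, envir = memo)
  contrib <- function(t) {
    got <- get0(t, envir = memo)
    if (!is.null(got)) return(got)
    kids <- intersect(dag$children[[t]], td)
    # every proper ancestor of D has at least one child on a path from D
    val <- delta * max(vapply(kids, contrib, numeric(1)))
    assign(t, val, envir = memo)
    val
  }
  out <- vapply(td, contrib, numeric(1))
  names(out) <- td
  out
}

#' Semantic value of a disease
#'
#' Sum of the semantic contributions of all terms in the ancestor closure
#' `T(D)`; at least 1 (the self-contribution).
#'
#' @inheritParams semantic_contribution
#' @return A single number `>= 1`.
#' @export
semantic_value <- function(dag, D, delta = 0.5) {
  sum(semantic_contribution(dag, D, delta))
}

#' Disease semantic similarity matrix from an ontology DAG
#'
#' Two diseases that share a larger part of their ancestor DAGs are more
#' similar: `SS(i, j)` sums, over terms shared by `T(d_i)` and `T(d_j)`,
#' the contributions of the term to both diseases, normalised by the two
#' semantic values. Diagonal entries are 1 for mapped diseases.
#'
#' Labels that do not map to a DAG node get all-zero rows and columns
#' (including the diagonal) with a warning; the downstream integration step
#' then falls back to the kernel similarity for those diseases.
#'
#' @param dag a [disease_dag()].
#' @param labels ordered character vector of disease labels.
#' @param delta decay factor in (0, 1].
#' @return A [similarity_matrix()] with role `"SS"`.
#' @export
disease_semantic_similarity <- function(dag, labels, delta = 0.5) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate disease labels")
  mapped <- labels %in% dag$nodes
  if (any(!mapped))
    warning("diseases not mapped to DAG nodes (semantic similarity set to 0): ",
            paste(labels[!mapped], collapse = ", "))
  contribs <- vector("list", length(labels))
  dv <- numeric(length(labels))
  for (i in which(mapped)) {
    contribs[[i]] <- semantic_contribution(dag, labels[i], delta)
    dv[i] <- sum(contribs[[i]])
  }
  n <- length(labels)
  SS <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    if (!mapped[i]) next
    SS[i, i] <- 1
    for (j in seq_len(n)) {
      if (j <= i || !mapped[j]) next
      shared <- intersect(names(contribs[[i]]), names(contribs[[j]]))
      if (length(shared)) {
        SS[i, j] <- SS[j, i] <-
          sum(contribs[[i]][shared] + contribs[[j]][shared]) / (dv[i] + dv[j])
      }
    }
  }
  similarity_matrix(SS, role = "SS")
}

#' Gaussian interaction-profile kernel similarity
#'
#' Each entity is represented by its binary interaction profile (a row of
#' `profiles`). The kernel is `exp(-gamma * ||IP_a - IP_b||^2)` with the
#' bandwidth normalised by the average profile density:
#' `gamma = gamma_prime / mean(||IP_i||^2)`. Individual all-zero profiles
#' are fine as long as the mean squared norm is positive.
#'
#' @param profiles numeric matrix, one profile per row, with row names.
#' @param gamma_prime bandwidth base, > 0; default 1.
#' @param role passed to [similarity_matrix()] (`"KM"` or `"KD"`).
#' @return A `similarity_matrix`; the realised bandwidth is attached as
#'   attribute `"gamma"`.
#' @export
gaussian_kernel <- function(profiles, gamma_prime = 1, role = NULL) {
  if (!is.matrix(profiles)) stop("`profiles` must be a matrix")
  if (!is.numeric(gamma_prime) || length(gamma_prime) != 1L || gamma_prime <= 0)
    stop("`gamma_prime` must be a single positive number")
  storage.mode(profiles) <- "double"
  sq <- rowSums(profiles^2)
  msq <- mean(sq)
  if (msq == 0)
    stop("degenerate kernel: all interaction profiles are zero")
  gamma <- gamma_prime / msq
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # numerical noise from the expansion
  K <- exp(-gamma * d2)
  diag(K) <- 1
  if (is.null(rownames(K))) rownames(K) <- colnames(K) <- rownames(profiles)
  out <- similarity_matrix(K, role = role)
  attr(out, "gamma") <- gamma
  out
}

#' @describeIn gaussian_kernel kernel over miRNA profiles (columns of `A`).
#' @param A an [mda_matrix()].
#' @export
gaussian_kernel_mirna <- function(A, gamma_prime = 1) {
  gaussian_kernel(t(unclass(A)), gamma_prime, role = "KM")
}

#' @describeIn gaussian_kernel kernel over disease profiles (rows of `A`).
#' @export
gaussian_kernel_disease <- function(A, gamma_prime = 1) {
  gaussian_kernel(unclass(A), gamma_prime, role = "KD")
}

#' Integrate a primary similarity with a kernel similarity
#'
#' Elementwise fusion: where the primary similarity (miRNA functional
#' similarity, or disease semantic similarity) is zero the kernel value is
#' used alone; elsewhere the two are averaged. Zero is tested with a small
#' tolerance since primary matrices typically arrive from files.
#'
#' @param sim_a primary similarity matrix (roles FS or SS).
#' @param sim_k kernel similarity matrix (roles KM or KD) on the same
#'   labels in the same order.
#' @param role role tag for the result (`"Sm"` or `"Sd"`).
#' @param zero_tol values with `|x| <= zero_tol` count as zero.
#' @return A `similarity_matrix`.
#' @export
integrate_similarity <- function(sim_a, sim_k, role = NULL, zero_tol = 1e-12) {
  if (!identical(rownames(sim_a), rownames(sim_k)))
    stop("label mismatch between the two similarity matrices")
  a <- unclass(sim_a)
  k <- unclass(sim_k)
  out <- ifelse(abs(a) <= zero_tol, k, (a + k) / 2)
  dimnames(out) <- dimnames(k)
  similarity_matrix(out, role = role)
}
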
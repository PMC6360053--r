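#' Planted-block bipartite association matrix
#'
#' Generates a sparse binary disease x miRNA matrix with aligned block
#' structure: diseases and miRNAs are split into `n_blocks` contiguous,
#' near-equal groups, and a pair gets an edge with probability `p_in`
#' within a block and `p_out` across blocks. This emulates the shape of
#' curated association catalogues - sparse overall, with clusters of
#' related diseases sharing miRNAs - and plants a recoverable signal for
#' end-to-end tests. The defaults give a 30 x 30, 3-block matrix with a
#' strong planted contrast.
#'
#' @param n_diseases,n_mirnas axis sizes.
#' @param n_blocks number of aligned blocks; block sizes differ by at most 1.
#' @param p_in,p_out within/cross-block edge probabilities in \[0, 1\],
#'   `p_in >= p_out`.
#' @param seed integer seed; the draw is a pure function of the arguments.
#' @return An [mda_matrix()] with attributes `disease_blocks` and
#'   `mirna_blocks` (named integer vectors).
#' @export
make_bipartite <- function(n_diseases = 30, n_mirnas = 30, n_blocks = 3,
                           p_in = 0.5, p_out = 0.02, seed = 1) {
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1)
    stop("edge probabilities must lie in [0, 1]")
  if (p_in < p_out) stop("`p_in` must be at least `p_out`")
  if (n_blocks < 1 || n_blocks > min(n_diseases, n_mirnas))
    stop("`n_blocks` out of range")
  bd <- sort(rep_len(seq_len(n_blocks), n_diseases))
  bm <- sort(rep_len(seq_len(n_blocks), n_mirnas))
  P <- p_out + (p_in - p_out) * outer(bd, bm, `==`)
  A <- withr::with_seed(seed,
    matrix(rbinom(length(P), 1L, P), n_diseases, n_mirnas))
  dimnames(A) <- list(sprintf("D%02d", seq_len(n_diseases)),
                      sprintf("M%02d", seq_len(n_mirnas)))
  out <- mda_matrix(A)
  attr(out, "disease_blocks") <- stats::setNames(bd, rownames(A))
  attr(out, "mirna_blocks") <- stats::setNames(bm, colnames(A))
  out
}

#' Random rooted-tree DAG over disease terms
#'
#' Node `i > 1` gets one parent drawn uniformly among lower-indexed nodes
#' (a random rooted tree, acyclic by construction); with probability
#' `extra_edge_prob` each remaining (node, lower-indexed node) pair adds a
#' further child->parent edge, giving terms multiple parents as in real
#' disease ontologies.
#'
#' @param n number of terms (>= 1).
#' @param extra_edge_prob probability of each extra edge.
#' @param seed integer seed.
#' @param labels optional node names (length `n`); default `T01, T02, ...`.
#' @return A [disease_dag()].
#' @export
make_dag <- function(n, extra_edge_prob = 0.1, seed = 1, labels = NULL) {
  if (n < 1) stop("`n` must be at least 1")
  if (is.null(labels)) labels <- sprintf("T%02d", seq_len(n))
  if (length(labels) != n) stop("`labels` must have length `n`")
  edges <- withr::with_seed(seed, {
    e <- NULL
    for (i in seq_len(n)[-1]) {
      parent <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
      e <- rbind(e, c(i, parent))
      extra <- setdiff(seq_len(i - 1L), parent)
      add <- extra[stats::runif(length(extra)) < extra_edge_prob]
      if (length(add)) e <- rbind(e, cbind(i, add))
    }
    e
  })
  if (is.null(edges)) return(disease_dag(labels))
  disease_dag(labels, cbind(labels[edges[, 1L]], labels[edges[, 2L]]))
}

#' Block-consistent functional similarity matrix
#'
#' Stand-in for a curated miRNA functional similarity resource (synthetic):
#' similarity 0.8 within a block and 0.1 across, plus symmetric Gaussian
#' noise clipped to \[0, 1\], with unit diagonal.
#'
#' @param blocks named integer vector assigning each miRNA label to a block
#'   (e.g. the `mirna_blocks` attribute of [make_bipartite()]).
#' @param noise_sd standard deviation of the noise (>= 0).
#' @param seed integer seed.
#' @return A [similarity_matrix()] with role `"FS"`.
#' @export
make_fs <- function(blocks, noise_sd = 0.05, seed = 1) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (is.null(names(blocks))) stop("`blocks` must be named by miRNA label")
  n <- length(blocks)
  base <- matrix(0.1, n, n)
  base[outer(blocks, blocks, `==`)] <- 0.8
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, matrix(rnorm(n * n, 0, noise_sd), n, n))
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    base <- base + noise
  }
  base[] <- pmin(pmax(base, 0), 1)
  diag(base) <- 1
  dimnames(base) <- list(names(blocks), names(blocks))
  similarity_matrix(base, role = "FS")
}

#' Permutation null for an association matrix
#'
#' Shuffles the entries of `A` uniformly (preserving the number of known
#' associations but destroying any structure); used as the label-shuffle
#' null against which signal recovery is measured.
#'
#' @param A an [mda_matrix()].
#' @param seed integer seed.
#' @return An [mda_matrix()] of the same shape and labels.
#' @export
permute_associations <- function(A, seed = 1) {
  X <- unclass(A)
  Xp <- X
  Xp[] <- withr::with_seed(seed, sample(as.vector(X)))
  mda_matrix(Xp)
}
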
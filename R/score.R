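#' Quadrangular neighbourhood of a disease-miRNA pair
#'
#' In a bipartite network `X`, the common neighbours (CN) of a disease
#' `d_i` and a miRNA `m_j` are the interior nodes of all length-3 paths
#' `d_i - m_k - d_l - m_j` (quadrangular closures once the seed pair is
#' added). Local community links (LCL) are the edges of `X` whose two
#' endpoints are both common neighbours. If the seed edge `(i, j)` itself
#' exists it is removed before anything is counted, and the degrees in
#' `degree_sum` are taken after that removal, so known and unknown pairs
#' with the same surrounding topology get identical counts.
#'
#' This is the plain-R reference implementation; the batch scorer
#' [cjc_batch()] computes the same quantities in compiled code.
#'
#' @param X binary disease x miRNA matrix.
#' @param i disease row index.
#' @param j miRNA column index.
#' @return A list with `cn_mirnas`, `cn_diseases` (integer indices),
#'   `cn_count`, `lcl_count`, `degree_sum`.
#' @export
pair_neighborhood <- function(X, i, j) {
  X <- unclass(X)
  stopifnot(i >= 1, i <= nrow(X), j >= 1, j <= ncol(X))
  X2 <- X
  X2[i, j] <- 0L
  u <- as.vector(crossprod(X2, X2[, j]))  # u[k] = #{l : X2[l,k] & X2[l,j]}
  cn_m <- which(X2[i, ] == 1L & u >= 1L)
  v <- as.vector(X2 %*% X2[i, ])          # v[l] = #{k : X2[l,k] & X2[i,k]}
  cn_d <- which(X2[, j] == 1L & v >= 1L)
  lcl <- sum(X2[cn_d, cn_m, drop = FALSE])
  list(cn_mirnas = cn_m,
       cn_diseases = cn_d,
       cn_count = length(cn_m) + length(cn_d),
       lcl_count = as.integer(lcl),
       degree_sum = as.integer(sum(X2[i, ]) + sum(X2[, j])))
}

#' CN-LCL index of one pair in one network
#'
#' `cn_count * lcl_count / degree_sum` from [pair_neighborhood()], where
#' `degree_sum` is the size of the union of the two seed nodes'
#' neighbourhoods (disjoint sets in a bipartite graph, hence the sum of the
#' two degrees). Returns 0 for an isolated seed (guarding 0/0).
#'
#' @inheritParams pair_neighborhood
#' @return A non-negative number.
#' @export
cjc <- function(X, i, j) {
  pn <- pair_neighborhood(X, i, j)
  if (pn$degree_sum == 0L) return(0)
  pn$cn_count * pn$lcl_count / pn$degree_sum
}

#' Batch CN-LCL index over many pairs
#'
#' Compiled equivalent of calling [cjc()] per pair; used by the scoring
#' and cross-validation code paths.
#'
#' @param X binary disease x miRNA matrix.
#' @param pairs two-column integer matrix of (disease row, miRNA column)
#'   indices.
#' @return A data frame with columns `cn`, `lcl`, `degree_sum`, `cjc`.
#' @export
cjc_batch <- function(X, pairs) {
  X <- unclass(X)
  storage.mode(X) <- "integer"
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns")
  cjc_batch_cpp(X, pairs)
}

#' Bundle the original and augmented association networks
#'
#' @param mda original binary association matrix.
#' @param sda disease-KNN augmented matrix (elementwise `>= mda`).
#' @param sma miRNA-KNN augmented matrix (elementwise `>= mda`).
#' @return A list of class `"network_triple"`.
#' @export
network_triple <- function(mda, sda, sma) {
  mda <- unclass(mda); sda <- unclass(sda); sma <- unclass(sma)
  if (!identical(dimnames(mda), dimnames(sda)) ||
      !identical(dimnames(mda), dimnames(sma)))
    stop("the three networks must share one label space")
  if (any(sda < mda) || any(sma < mda))
    stop("augmented networks must contain every original edge")
  structure(list(mda = mda, sda = sda, sma = sma), class = "network_triple")
}

#' Fit the full NBMDA model
#'
#' From a (training) association matrix and optional side information,
#' computes the Gaussian interaction-profile kernels, the integrated
#' similarities, and the two KNN-augmented networks. When `fs` (miRNA
#' functional similarity) or `ss` (disease semantic similarity) is absent
#' the corresponding kernel is used alone.
#'
#' @param A an [mda_matrix()] of training associations.
#' @param fs optional miRNA functional similarity (labels = `mirnas(A)`).
#' @param ss optional disease semantic similarity (labels = `diseases(A)`),
#'   e.g. from [disease_semantic_similarity()].
#' @param config an [nbmda_config()] supplying `k`, `vote_threshold` and
#'   the kernel bandwidth bases.
#' @return A list of class `"nbmda_model"` holding the network triple and
#'   all intermediate similarity matrices.
#' @export
nbmda_fit <- function(A, fs = NULL, ss = NULL, config = nbmda_config()) {
  KM <- gaussian_kernel_mirna(A, config$gamma_prime_m)
  KD <- gaussian_kernel_disease(A, config$gamma_prime_d)
  Sm <- if (is.null(fs)) KM else integrate_similarity(fs, KM, role = "Sm")
  Sd <- if (is.null(ss)) KD else integrate_similarity(ss, KD, role = "Sd")
  sda <- knn_augment_by_disease(A, Sd, config$k, config$vote_threshold)
  sma <- knn_augment_by_mirna(A, Sm, config$k, config$vote_threshold)
  structure(list(networks = network_triple(unclass(A), sda, sma),
                 km = KM, kd = KD, sm = Sm, sd = Sd, config = config),
            class = "nbmda_model")
}

#' @export
print.nbmda_model <- function(x, ...) {
  nt <- x$networks
  cat(sprintf(paste0("<nbmda_model> %d diseases x %d miRNAs; edges: ",
                     "MDA %d, SDA %d, SMA %d (k = %d, votes >= %d)\n"),
              nrow(nt$mda), ncol(nt$mda), sum(nt$mda), sum(nt$sda),
              sum(nt$sma), x$config$k, x$config$vote_threshold))
  invisible(x)
}

#' Score selected disease-miRNA pairs
#'
#' The NBMDA score of a pair is the geometric mean of its CN-LCL index in
#' the original network and the two augmented networks, with the seed edge
#' removed independently in each network. A zero index in any network
#' annihilates the score.
#'
#' @param model an [nbmda_fit()] result (or a [network_triple()]).
#' @param pairs two-column integer matrix of (disease, miRNA) indices.
#' @return Numeric vector of scores, one per row of `pairs`.
#' @export
score_pairs <- function(model, pairs) {
  nt <- if (inherits(model, "nbmda_model")) model$networks else model
  c1 <- cjc_batch(nt$mda, pairs)$cjc
  c2 <- cjc_batch(nt$sda, pairs)$cjc
  c3 <- cjc_batch(nt$sma, pairs)$cjc
  (c1 * c2 * c3)^(1 / 3)
}

#' Score every disease-miRNA pair
#'
#' @inheritParams score_pairs
#' @param diagnostics if `TRUE`, attach the three per-network index
#'   matrices as attribute `"per_network"`.
#' @return A labelled numeric matrix of scores (class `"score_matrix"`).
#' @export
score_all <- function(model, diagnostics = FALSE) {
  nt <- if (inherits(model, "nbmda_model")) model$networks else model
  nd <- nrow(nt$mda)
  nm <- ncol(nt$mda)
  pairs <- cbind(rep(seq_len(nd), times = nm), rep(seq_len(nm), each = nd))
  per <- lapply(nt[c("mda", "sda", "sma")],
                function(X) matrix(cjc_batch(X, pairs)$cjc, nd, nm,
                                   dimnames = dimnames(nt$mda)))
  scores <- (per$mda * per$sda * per$sma)^(1 / 3)
  out <- structure(scores, class = c("score_matrix", class(unclass(scores))))
  if (diagnostics) attr(out, "per_network") <- per
  out
}

#' Ranked candidate miRNAs for one disease
#'
#' Ranks the miRNAs *not* already associated with the disease by
#' descending score; ties are broken by ascending miRNA index (a stable,
#' deterministic order).
#'
#' @param scores score matrix from [score_all()].
#' @param A the association matrix the scores were computed against; only
#'   pairs with `A == 0` are candidates.
#' @param disease disease label.
#' @param top_n maximum number of candidates returned (default 50).
#' @return A data frame with columns `rank`, `mirna`, `score`, of class
#'   `"ranked_predictions"`, with the disease label as attribute.
#' @export
rank_for_disease <- function(scores, A, disease, top_n = 50) {
  i <- match(disease, rownames(A))
  if (is.na(i)) stop("unknown disease '", disease, "'")
  cand <- which(unclass(A)[i, ] == 0L)
  ord <- cand[order(-unclass(scores)[i, cand], cand)]
  ord <- head(ord, top_n)
  out <- data.frame(rank = seq_along(ord),
                    mirna = colnames(A)[ord],
                    score = unclass(scores)[i, ord],
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, disease = disease,
            class = c("ranked_predictions", class(out)))
}

#' Write ranked predictions as TSV
#'
#' Three columns `rank`, `mirna`, `score`; scores printed with 6
#' significant digits. An empty prediction set yields a header-only file.
#'
#' @param preds a [rank_for_disease()] result (or any data frame with
#'   columns `rank`, `mirna`, `score`).
#' @param path output path.
#' @export
write_predictions <- function(preds, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("rank\tmirna\tscore", con)
  if (nrow(preds))
    writeLines(sprintf("%d\t%s\t%.6g", preds$rank, preds$mirna,
                       preds$score), con)
  invisible(path)
}
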
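#' Cross-validation / ROC result container
#'
#' @param auc area under the ROC curve.
#' @param roc data frame with columns `fpr`, `tpr` tracing the curve from
#'   (0, 0) to (1, 1), both coordinates non-decreasing.
#' @param per_repeat_aucs per-repeat AUCs (k-fold only), or `NULL`.
#' @param settings named list snapshot of the configuration used.
#' @return A list of class `"eval_result"`.
#' @export
eval_result <- function(auc, roc, per_repeat_aucs = NULL, settings = list()) {
  stopifnot(auc >= 0, auc <= 1,
            all(diff(roc$fpr) >= 0), all(diff(roc$tpr) >= 0))
  structure(list(auc = auc, roc = roc, per_repeat_aucs = per_repeat_aucs,
                 settings = settings),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> AUC = %.4f", x$auc))
  if (!is.null(x$per_repeat_aucs) && length(x$per_repeat_aucs) > 1L)
    cat(sprintf(" (%d repeats, sd %.4f)", length(x$per_repeat_aucs),
                stats::sd(x$per_repeat_aucs)))
  cat(sprintf("; %d ROC points\n", nrow(x$roc)))
  invisible(x)
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' ROC curve and AUC from positive and negative scores
#'
#' The AUC is the Mann-Whitney rank-sum statistic with mid-ranks for ties,
#' `(R_pos - n_pos(n_pos+1)/2) / (n_pos * n_neg)`; the ROC curve is a
#' threshold sweep over the distinct scores (ties produce diagonal
#' segments), whose trapezoidal area equals the rank-sum value.
#'
#' @param pos_scores,neg_scores non-empty numeric vectors.
#' @return An [eval_result()].
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    stop("both score lists must be non-empty")
  np <- length(pos_scores)
  nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  th <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(pos_scores >= t), numeric(1)) / np
  fpr <- vapply(th, function(t) sum(neg_scores >= t), numeric(1)) / nn
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  eval_result(auc = auc, roc = roc)
}

# ROC from per-positive hit rates: u[i] is the fraction of that
# iteration's negatives scored below positive i (ties counted half). The
# curve is the empirical CDF of 1 - u, traced with its step corners so the
# trapezoidal area equals mean(u) exactly.
roc_from_hitrates <- function(u) {
  x <- sort(1 - u)
  n <- length(u)
  ux <- unique(x)
  Fv <- cumsum(tabulate(match(x, ux), nbins = length(ux))) / n
  Fprev <- c(0, head(Fv, -1))
  data.frame(fpr = c(0, rep(ux, each = 2), 1),
             tpr = c(0, as.vector(rbind(Fprev, Fv)), 1))
}

# Per-positive hit rate against its iteration's negatives (mid-rank ties).
hitrate <- function(s_pos, s_neg) {
  (sum(s_neg < s_pos) + 0.5 * sum(s_neg == s_pos)) / length(s_neg)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is held out in turn: it is zeroed in a copy of
#' the association matrix, the model is refit from that training copy
#' (kernels, integrated similarities, KNN augmentation - in `"dynamic"`
#' mode; `"static"` fits once from the full matrix), and the held-out
#' pair is scored together with every pair unknown in the *full* matrix.
#' The AUC aggregates, over positives, the fraction of that iteration's
#' negatives they outscore (mid-rank ties); the ROC curve is the matching
#' rank-cutoff sweep, so its trapezoidal area equals the AUC.
#'
#' @param A an [mda_matrix()] with at least 2 known associations.
#' @param fs,ss optional side-information similarities (see [nbmda_fit()]).
#' @param config an [nbmda_config()].
#' @param scorer optional stub for harness testing: a
#'   `function(A_train, pairs)` returning one score per pair, used instead
#'   of the NBMDA model.
#' @return An [eval_result()].
#' @export
run_loocv <- function(A, fs = NULL, ss = NULL, config = nbmda_config(),
                      scorer = NULL) {
  X <- unclass(A)
  pos <- which(X == 1L, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop("need at least 2 known associations")
  neg <- which(X == 0L, arr.ind = TRUE)
  if (!nrow(neg)) stop("no unknown pairs to rank against")
  static_model <- NULL
  if (is.null(scorer) && config$similarity_mode == "static")
    static_model <- nbmda_fit(A, fs, ss, config)
  u <- numeric(nrow(pos))
  for (t in seq_len(nrow(pos))) {
    At <- X
    At[pos[t, 1L], pos[t, 2L]] <- 0L
    prs <- rbind(pos[t, , drop = FALSE], neg)
    s <- if (!is.null(scorer)) {
      scorer(At, prs)
    } else {
      m <- if (is.null(static_model)) {
        nbmda_fit(mda_matrix(At), fs, ss, config)
      } else static_model
      score_pairs(m, prs)
    }
    u[t] <- hitrate(s[1L], s[-1L])
  }
  eval_result(auc = mean(u), roc = roc_from_hitrates(u),
              settings = c(unclass(config), list(mode = "loocv")))
}

#' Repeated k-fold cross-validation
#'
#' Per repeat `r` (seeded from `seed + r`) the known associations are
#' shuffled and split into `folds` near-equal disjoint subsets. Each fold
#' is zeroed in the training matrix, the model refit (in `"dynamic"`
#' mode), and the fold's edges scored against every pair unknown in the
#' full matrix. The per-repeat AUC pools all positives of that repeat;
#' the reported AUC is the mean over repeats (identical to the pooled
#' value, since every positive appears once per repeat), and
#' `per_repeat_aucs` retains the spread.
#'
#' @inheritParams run_loocv
#' @return An [eval_result()] with `per_repeat_aucs` filled in.
#' @export
run_kfold <- function(A, fs = NULL, ss = NULL, config = nbmda_config(),
                      scorer = NULL) {
  X <- unclass(A)
  pos <- which(X == 1L, arr.ind = TRUE)
  if (nrow(pos) < config$folds)
    stop("need at least `folds` known associations")
  neg <- which(X == 0L, arr.ind = TRUE)
  if (!nrow(neg)) stop("no unknown pairs to rank against")
  static_model <- NULL
  if (is.null(scorer) && config$similarity_mode == "static")
    static_model <- nbmda_fit(A, fs, ss, config)
  n <- nrow(pos)
  per_repeat <- numeric(config$repeats)
  u_all <- numeric(0)
  for (r in seq_len(config$repeats)) {
    perm <- withr::with_seed(config$seed + r, sample.int(n))
    fold_id <- rep_len(seq_len(config$folds), n)  # sizes differ by <= 1
    u_rep <- numeric(n)
    filled <- 0L
    for (f in seq_len(config$folds)) {
      test <- pos[perm[fold_id == f], , drop = FALSE]
      At <- X
      At[test] <- 0L
      prs <- rbind(test, neg)
      s <- if (!is.null(scorer)) {
        scorer(At, prs)
      } else {
        m <- if (is.null(static_model)) {
          nbmda_fit(mda_matrix(At), fs, ss, config)
        } else static_model
        score_pairs(m, prs)
      }
      nt <- nrow(test)
      sn <- s[-seq_len(nt)]
      for (t in seq_len(nt)) {
        u_rep[filled + t] <- hitrate(s[t], sn)
      }
      filled <- filled + nt
    }
    per_repeat[r] <- mean(u_rep)
    u_all <- c(u_all, u_rep)
  }
  eval_result(auc = mean(per_repeat), roc = roc_from_hitrates(u_all),
              per_repeat_aucs = per_repeat,
              settings = c(unclass(config), list(mode = "kfold")))
}
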
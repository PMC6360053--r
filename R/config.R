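#' Model and evaluation configuration
#'
#' Collects every tunable in one validated list. Defaults follow common
#' practice for this model family: `k = 3` neighbours with a strict
#' majority vote, semantic decay `delta = 0.5`, kernel bandwidth bases of
#' 1, and 5-fold cross-validation repeated 100 times.
#'
#' @param k neighbour count for KNN augmentation (>= 1).
#' @param vote_threshold minimum agreeing neighbours in `[1, k]`; default
#'   `floor(k/2) + 1`, a strict majority.
#' @param delta semantic contribution decay factor in (0, 1].
#' @param gamma_prime_m,gamma_prime_d Gaussian kernel bandwidth bases (> 0)
#'   for the miRNA and disease kernels.
#' @param folds number of cross-validation folds (>= 2).
#' @param repeats number of k-fold repeats (>= 1).
#' @param seed integer seed; repeat `r` of k-fold CV draws from `seed + r`.
#' @param similarity_mode `"dynamic"` recomputes kernels and augmentation
#'   from each training matrix (no test-edge leakage); `"static"` computes
#'   them once from the full matrix.
#' @return A list of class `"nbmda_config"`.
#' @export
nbmda_config <- function(k = 3,
                         vote_threshold = NULL,
                         delta = 0.5,
                         gamma_prime_m = 1,
                         gamma_prime_d = 1,
                         folds = 5,
                         repeats = 100,
                         seed = 1,
                         similarity_mode = c("dynamic", "static")) {
  similarity_mode <- match.arg(similarity_mode)
  chk_num <- function(x, name, lo = -Inf, hi = Inf, int = FALSE,
                      lo_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop("`", name, "` must be a single number")
    if (int && x != as.integer(x)) stop("`", name, "` must be an integer")
    if (x < lo || x > hi || (lo_open && x == lo))
      stop("`", name, "` out of range: ", x)
    x
  }
  k <- as.integer(chk_num(k, "k", lo = 1, int = TRUE))
  if (is.null(vote_threshold)) vote_threshold <- k %/% 2L + 1L
  vote_threshold <- as.integer(chk_num(vote_threshold, "vote_threshold",
                                       lo = 1, hi = k, int = TRUE))
  structure(list(
    k = k,
    vote_threshold = vote_threshold,
    delta = chk_num(delta, "delta", lo = 0, hi = 1, lo_open = TRUE),
    gamma_prime_m = chk_num(gamma_prime_m, "gamma_prime_m", lo = 0, lo_open = TRUE),
    gamma_prime_d = chk_num(gamma_prime_d, "gamma_prime_d", lo = 0, lo_open = TRUE),
    folds = as.integer(chk_num(folds, "folds", lo = 2, int = TRUE)),
    repeats = as.integer(chk_num(repeats, "repeats", lo = 1, int = TRUE)),
    seed = as.integer(chk_num(seed, "seed", int = TRUE)),
    similarity_mode = similarity_mode
  ), class = "nbmda_config")
}

#' @export
print.nbmda_config <- function(x, ...) {
  cat("<nbmda_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Load configuration from a YAML file with overrides
#'
#' Precedence: package defaults < file values < `overrides`. Keys must be
#' arguments of [nbmda_config()]; an unknown key errors listing the valid
#' ones, and out-of-range values error through the constructor.
#'
#' @param path path to a flat YAML file, or `NULL` for defaults only.
#' @param overrides named list of values taking precedence over the file
#'   (e.g. from command-line flags).
#' @return An [nbmda_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  valid <- setdiff(names(formals(nbmda_config)), "...")
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("config file must be a flat key/value document")
  }
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), valid)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(valid, collapse = ", "))
  do.call(nbmda_config, vals)
}
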
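# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition (path enumeration, per-pair formula
# evaluation, pairwise concordance counting) and share no code with the
# implementations they check.

# Enumerate every length-3 path d_i - m_k - d_l - m_j in X with the seed
# edge (i, j) removed; interior nodes are the common neighbours.
oracle_neighborhood <- function(X, i, j) {
  X2 <- X
  X2[i, j] <- 0L
  cn_m <- integer(0)
  cn_d <- integer(0)
  for (k in seq_len(ncol(X2))) {
    for (l in seq_len(nrow(X2))) {
      if (X2[i, k] == 1L && X2[l, k] == 1L && X2[l, j] == 1L) {
        cn_m <- union(cn_m, k)
        cn_d <- union(cn_d, l)
      }
    }
  }
  lcl <- 0L
  for (l in cn_d) for (k in cn_m) lcl <- lcl + X2[l, k]
  # |N(d_i) union N(m_j)| over distinct labelled nodes (disjoint in a
  # bipartite graph, but computed as a genuine union here)
  nbrs <- union(sprintf("m%d", which(X2[i, ] == 1L)),
                sprintf("d%d", which(X2[, j] == 1L)))
  list(cn_count = length(cn_m) + length(cn_d),
       lcl_count = as.integer(lcl),
       degree_sum = length(nbrs),
       cn_mirnas = sort(cn_m),
       cn_diseases = sort(cn_d))
}

oracle_cjc <- function(X, i, j) {
  o <- oracle_neighborhood(X, i, j)
  if (o$degree_sum == 0L) return(0)
  o$cn_count * o$lcl_count / o$degree_sum
}

# Contribution of each ancestor t to D: max over all upward paths D -> t
# of delta^length(path), found by exhaustive path enumeration.
oracle_contribution <- function(dag, D, delta = 0.5) {
  best <- c(stats::setNames(1, D))
  walk <- function(node, depth) {
    for (p in dag$parents[[node]]) {
      val <- delta^(depth + 1)
      if (is.na(best[p]) || val > best[p]) best[p] <<- val
      walk(p, depth + 1)
    }
  }
  walk(D, 0)
  best
}

# Direct per-pair evaluation of the Gaussian interaction-profile kernel.
oracle_kernel <- function(profiles, gamma_prime = 1) {
  gamma <- gamma_prime / mean(rowSums(profiles^2))
  n <- nrow(profiles)
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- exp(-gamma * sum((profiles[i, ] - profiles[j, ])^2))
    }
  }
  K
}

# AUC by counting concordant positive/negative pairs (ties worth 1/2).
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

trapz <- function(fpr, tpr) sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
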
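test_that("pair neighbourhoods match hand-derived toy cases", {
  X <- toy3()   # edges (d1,m2), (d2,m2), (d2,m1)
  pn <- pair_neighborhood(X, 1, 1)
  expect_equal(unname(pn$cn_mirnas), 2L)
  expect_equal(unname(pn$cn_diseases), 2L)
  expect_equal(pn$cn_count, 2L)
  expect_equal(pn$lcl_count, 1L)
  expect_equal(pn$degree_sum, 2L)
  expect_equal(cjc(X, 1, 1), 1)

  # adding the seed edge itself changes nothing: it is removed first and
  # degrees are taken after removal
  Xs <- X
  Xs[1, 1] <- 1L
  expect_equal(pair_neighborhood(Xs, 1, 1)[c("cn_count", "lcl_count", "degree_sum")],
               pn[c("cn_count", "lcl_count", "degree_sum")])
  expect_equal(cjc(Xs, 1, 1), 1)

  # isolated seed: no neighbours, guarded 0/0
  Z <- labelled_matrix(0, 3, 3)
  pz <- pair_neighborhood(Z, 1, 1)
  expect_equal(pz$cn_count, 0L)
  expect_equal(pz$degree_sum, 0L)
  expect_equal(cjc(Z, 1, 1), 0)

  # no quadrangle -> zero index
  Y <- labelled_matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(cjc(Y, 1, 2), 0)
})

test_that("complete bipartite K22 agrees with brute force on every pair", {
  K22 <- labelled_matrix(1, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(cjc(K22, i, j), oracle_cjc(K22, i, j))
    expect_equal(cjc(K22, i, j), 1)  # CN=2, LCL=1, degrees 1+1 after removal
  }
})

test_that("reference, compiled batch and brute-force oracle agree exactly", {
  for (seed in 1:40) {
    nd <- 3 + seed %% 8
    nm <- 3 + (seed * 3) %% 8
    X <- rand_bipartite(nd, nm, 0.1 + 0.5 * (seed %% 6) / 5, seed = 4000 + seed)
    pairs <- cbind(rep(seq_len(nd), times = nm), rep(seq_len(nm), each = nd))
    batch <- cjc_batch(X, pairs)
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      o <- oracle_neighborhood(X, i, j)
      r <- pair_neighborhood(X, i, j)
      expect_identical(r$cn_count, o$cn_count)
      expect_identical(r$lcl_count, o$lcl_count)
      expect_identical(r$degree_sum, o$degree_sum)
      expect_identical(sort(unname(r$cn_mirnas)), o$cn_mirnas)
      expect_identical(sort(unname(r$cn_diseases)), o$cn_diseases)
      expect_identical(batch$cn[p], o$cn_count)
      expect_identical(batch$lcl[p], o$lcl_count)
      expect_identical(batch$degree_sum[p], o$degree_sum)
      expect_equal(batch$cjc[p], oracle_cjc(X, i, j), tolerance = 1e-12)
    }
  }
})

test_that("scores geometric-average the three per-network indices", {
  X <- rand_bipartite(8, 8, 0.4, seed = 91)
  # identical networks: the geometric mean collapses to the single index
  nt <- network_triple(X, X, X)
  sc <- score_all(nt, diagnostics = TRUE)
  per <- attr(sc, "per_network")
  expect_equal(unclass(sc)[, ], per$mda[, ], tolerance = 1e-12)
  # a zero in any network annihilates the score
  expect_true(all(unclass(sc)[per$mda == 0] == 0))

  # distinct augmented networks: cube root of the product, seed removal
  # applied independently per network
  A <- mda_matrix(X)
  m <- nbmda_fit(A, config = nbmda_config(k = 3, seed = 1))
  s <- score_all(m, diagnostics = TRUE)
  pn <- attr(s, "per_network")
  expect_equal(unclass(s)[, ], ((pn$mda * pn$sda * pn$sma)^(1 / 3))[, ],
               tolerance = 1e-12)
  expect_equal(s[2, 3], score_pairs(m, cbind(2, 3)), tolerance = 1e-12)
  expect_true(all(unclass(s) >= 0))
})

test_that("relabelling permutes scores consistently", {
  X <- rand_bipartite(7, 9, 0.35, seed = 55)
  nt <- network_triple(X, X, X)
  sc <- unclass(score_all(nt))
  perm <- c(3, 1, 2, 7, 5, 4, 6)
  Xp <- X[perm, ]
  scp <- unclass(score_all(network_triple(Xp, Xp, Xp)))
  expect_equal(scp, sc[perm, ], tolerance = 1e-12)
})

test_that("network triples enforce the augmentation-only invariant", {
  X <- toy3()
  bad <- X
  bad[2, 2] <- 0L
  expect_error(network_triple(X, bad, X), "every original edge")
  Y <- X
  rownames(Y) <- c("a", "b")
  expect_error(network_triple(X, X, Y), "label space")
})

test_that("per-disease ranking excludes known pairs and respects ties", {
  A <- mda_matrix(labelled_matrix(c(1, 0, 0, 0, 0, 0), 2, 3))
  sc <- matrix(0, 2, 3, dimnames = dimnames(A))
  sc[1, 3] <- 0.7
  r <- rank_for_disease(sc, A, "d1", top_n = 50)
  expect_identical(r$mirna, c("m3", "m2"))      # m1 known, excluded
  expect_equal(r$score, c(0.7, 0))
  expect_identical(r$rank, 1:2)                 # top_n > candidates: all
  zero <- rank_for_disease(matrix(0, 2, 3, dimnames = dimnames(A)),
                           A, "d2", top_n = 2)
  expect_identical(zero$mirna, c("m1", "m2"))   # all-tie: index order
  expect_error(rank_for_disease(sc, A, "dX"), "unknown disease")
})
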
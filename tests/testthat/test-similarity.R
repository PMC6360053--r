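test_that("semantic contributions follow the decayed-max recursion", {
  dag <- chain_dag()
  expect_equal(semantic_contribution(dag, "C"),
               c(C = 1, B = 0.5, A = 0.25))
  expect_equal(semantic_value(dag, "C"), 1.75)

  iso <- disease_dag("D")
  expect_equal(semantic_contribution(iso, "D"), c(D = 1))
  expect_equal(semantic_value(iso, "D"), 1)

  dd <- diamond_dag()
  expect_equal(semantic_contribution(dd, "C"),
               c(C = 1, B1 = 0.5, B2 = 0.5, A = 0.25))
  expect_equal(semantic_value(dd, "C"), 2.25)

  expect_error(semantic_contribution(dag, "nope"), "not in DAG")
  expect_error(semantic_contribution(dag, "C", delta = 1.5), "delta")
})

test_that("semantic contributions match exhaustive path enumeration", {
  for (seed in 1:25) {
    dag <- make_dag(n = 9, extra_edge_prob = 0.35, seed = seed)
    D <- dag$nodes[1 + seed %% 9]
    got <- semantic_contribution(dag, D, delta = 0.5)
    want <- oracle_contribution(dag, D, delta = 0.5)
    expect_setequal(names(got), names(want))
    expect_equal(got[names(want)], want, tolerance = 1e-12)
    # proper ancestors contribute strictly less than 1 when delta < 1
    expect_true(all(got[setdiff(names(got), D)] < 1))
  }
})

test_that("disease semantic similarity matches hand computation", {
  dag <- read_dag(write_tsv_lines("B\tA"))
  SS <- disease_semantic_similarity(dag, c("A", "B"))
  expect_equal(SS["A", "B"], 0.6)   # (1 + 0.5) / (1 + 1.5)
  expect_equal(diag(unclass(SS)), c(A = 1, B = 1))

  # disjoint ancestor sets give zero similarity
  two <- disease_dag(c("A", "B", "X", "Y"),
                     rbind(c("B", "A"), c("Y", "X")))
  SS2 <- disease_semantic_similarity(two, c("B", "Y"))
  expect_equal(SS2["B", "Y"], 0)
})

test_that("unmapped diseases get zero semantic rows and a warning", {
  dag <- chain_dag()
  expect_warning(SS <- disease_semantic_similarity(dag, c("A", "Zz")),
                 "Zz")
  expect_equal(unclass(SS)["Zz", ], c(A = 0, Zz = 0))
  expect_equal(SS["A", "A"], 1)
  # integration then falls back to the kernel for that disease
  K <- similarity_matrix(matrix(c(1, 0.3, 0.3, 1), 2,
                                dimnames = list(c("A", "Zz"), c("A", "Zz"))))
  Sd <- integrate_similarity(SS, K)
  expect_equal(Sd["A", "Zz"], 0.3)
  expect_equal(Sd["Zz", "Zz"], 1)
})

test_that("gaussian kernel matches its closed form and the per-pair oracle", {
  A <- mda_matrix(labelled_matrix(diag(2), 2, 2))
  KM <- gaussian_kernel_mirna(A)
  expect_equal(KM["m1", "m2"], exp(-2), tolerance = 1e-12)
  expect_equal(attr(KM, "gamma"), 1)
  expect_equal(KM["m1", "m1"], 1)

  for (seed in 1:30) {
    nd <- 3 + seed %% 10
    nm <- 3 + (seed * 7) %% 10
    X <- rand_bipartite(nd, nm, 0.4, seed = 1000 + seed)
    if (all(X == 0)) next
    KM <- gaussian_kernel_mirna(mda_matrix(X))
    KD <- gaussian_kernel_disease(mda_matrix(X))
    expect_equal(unclass(KM)[, ], oracle_kernel(t(X))[, ],
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(unclass(KD)[, ], oracle_kernel(X)[, ],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("doubling profile density halves the kernel bandwidth", {
  X <- rand_bipartite(8, 12, 0.3, seed = 5)
  X2 <- rbind(X, X)  # duplicate diseases: miRNA profile norms double
  rownames(X2) <- sprintf("d%d", seq_len(nrow(X2)))
  g1 <- attr(gaussian_kernel(t(X)), "gamma")
  g2 <- attr(gaussian_kernel(t(X2)), "gamma")
  expect_equal(g2, g1 / 2, tolerance = 1e-12)
})

test_that("degenerate kernels are rejected, zero profiles tolerated", {
  Z <- mda_matrix(labelled_matrix(rep(0, 6), 2, 3))
  expect_error(gaussian_kernel_mirna(Z), "degenerate")
  # one all-zero column is fine while the mean norm is positive
  X <- labelled_matrix(c(1, 0, 0, 0, 1, 0), 2, 3)
  KM <- gaussian_kernel_mirna(mda_matrix(X))
  expect_true(all(is.finite(KM)))
  expect_equal(KM["m3", "m3"], 1)
})

test_that("similarity integration averages, with kernel fallback at zero", {
  lab <- list(c("a", "b"), c("a", "b"))
  Sa <- similarity_matrix(matrix(c(1, 0.4, 0.4, 1), 2, dimnames = lab))
  K <- similarity_matrix(matrix(c(1, 0.6, 0.6, 1), 2, dimnames = lab))
  expect_equal(integrate_similarity(Sa, K)["a", "b"], 0.5)
  expect_equal(integrate_similarity(Sa, K)["a", "a"], 1)

  S0 <- similarity_matrix(matrix(c(1, 0, 0, 1), 2, dimnames = lab))
  expect_equal(integrate_similarity(S0, K)["a", "b"], 0.6)
  # fully zero off-diagonal primary: result off-diagonal equals the kernel
  expect_equal(unclass(integrate_similarity(S0, K))["a", "b"], K["a", "b"])

  Sx <- similarity_matrix(matrix(c(1, 0.4, 0.4, 1), 2,
                                 dimnames = list(c("x", "y"), c("x", "y"))))
  expect_error(integrate_similarity(Sx, K), "label mismatch")
})

test_that("similarity matrices keep their invariants on random inputs", {
  for (seed in 1:10) {
    X <- rand_bipartite(8, 8, 0.35, seed = 2000 + seed)
    if (all(X == 0)) next
    A <- mda_matrix(X)
    dag <- make_dag(8, extra_edge_prob = 0.3, seed = seed,
                    labels = rownames(X))
    for (S in list(gaussian_kernel_mirna(A), gaussian_kernel_disease(A),
                   disease_semantic_similarity(dag, rownames(X)))) {
      M <- unclass(S)
      expect_true(max(abs(M - t(M))) <= 1e-12)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(unname(diag(M)), rep(1, nrow(M)))
    }
  }
})
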
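# Small builders shared across test files. All randomness is seeded.

labelled_matrix <- function(x, nd, nm) {
  matrix(as.integer(x), nd, nm,
         dimnames = list(sprintf("d%d", seq_len(nd)),
                         sprintf("m%d", seq_len(nm))))
}

# random binary disease x miRNA matrix at a given density
rand_bipartite <- function(nd, nm, density, seed) {
  withr::with_seed(seed, labelled_matrix(rbinom(nd * nm, 1, density), nd, nm))
}

# the 3-edge toy used throughout: edges (d1,m2), (d2,m2), (d2,m1)
toy3 <- function() labelled_matrix(c(0, 1, 1, 1), 2, 2)

# chain DAG  C -> B -> A  (child -> parent)
chain_dag <- function() {
  disease_dag(c("A", "B", "C"), rbind(c("B", "A"), c("C", "B")))
}

# diamond DAG  C -> {B1, B2} -> A
diamond_dag <- function() {
  disease_dag(c("A", "B1", "B2", "C"),
              rbind(c("B1", "A"), c("B2", "A"), c("C", "B1"), c("C", "B2")))
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
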
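#' Construct a disease-term DAG
#'
#' Directed acyclic ancestor graph over disease terms, stored as
#' child-to-parent edges. Used to compute semantic similarity between
#' diseases: `T(D)`, the ancestor closure of a term `D`, is the set of
#' nodes reachable from `D` over child->parent edges (always containing
#' `D` itself).
#'
#' @param nodes character vector of term names (isolated nodes allowed).
#' @param edges two-column character matrix, first column child, second
#'   parent. May be `NULL`/empty.
#' @return A list of class `"disease_dag"` with elements `nodes`,
#'   `parents` (named list child -> parents) and `children` (parent ->
#'   children).
#' @export
disease_dag <- function(nodes, edges = NULL) {
  nodes <- unique(as.character(nodes))
  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  children <- parents
  if (!is.null(edges) && nrow(edges) > 0L) {
    ch <- as.character(edges[, 1L])
    pa <- as.character(edges[, 2L])
    if (any(ch == pa))
      stop("self-edge on node '", ch[which(ch == pa)[1L]], "'")
    missing <- setdiff(unique(c(ch, pa)), nodes)
    if (length(missing))
      stop("edge endpoints not declared as nodes: ",
           paste(missing, collapse = ", "))
    for (i in seq_along(ch)) {
      parents[[ch[i]]] <- union(parents[[ch[i]]], pa[i])
      children[[pa[i]]] <- union(children[[pa[i]]], ch[i])
    }
  }
  dag <- structure(list(nodes = nodes, parents = parents, children = children),
                   class = "disease_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc))
    stop("cycle detected: ", paste(c(cyc, cyc[1L]), collapse = " -> "))
  dag
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> %d terms, %d edges\n",
              length(x$nodes), sum(lengths(x$parents))))
  invisible(x)
}

# Iterative DFS over child->parent edges; returns one cycle (as a node
# vector) or NULL. Hand-rolled so the error can name the offending cycle.
find_cycle <- function(dag) {
  state <- stats::setNames(integer(length(dag$nodes)), dag$nodes) # 0 new 1 open 2 done
  for (start in dag$nodes) {
    if (state[start] != 0L) next
    stack <- list(list(node = start, next_i = 1L))
    state[start] <- 1L
    path <- start
    while (length(stack)) {
      top <- stack[[length(stack)]]
      pars <- dag$parents[[top$node]]
      if (top$next_i <= length(pars)) {
        stack[[length(stack)]]$next_i <- top$next_i + 1L
        nxt <- pars[top$next_i]
        if (state[nxt] == 1L)
          return(path[seq(match(nxt, path), length(path))])
        if (state[nxt] == 0L) {
          state[nxt] <- 1L
          stack[[length(stack) + 1L]] <- list(node = nxt, next_i = 1L)
          path <- c(path, nxt)
        }
      } else {
        state[top$node] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
      }
    }
  }
  NULL
}

#' Read a disease DAG from a child-parent edge list
#'
#' Two-column TSV `child<TAB>parent`; `#` comments skipped. Acyclicity is
#' verified on read; a violation errors naming one cycle.
#'
#' @param path path to the edge-list TSV.
#' @return A [disease_dag()].
#' @export
read_dag <- function(path) {
  rec <- read_two_col_tsv(path, what = "edge")
  disease_dag(nodes = unique(c(rec$a, rec$b)),
              edges = cbind(rec$a, rec$b))
}

#' Write a disease DAG as a child-parent edge list
#' @param dag a `disease_dag`.
#' @param path output path. Isolated nodes are written as comment lines so
#'   the file round-trips the edge set.
#' @export
write_dag <- function(dag, path) {
  lines <- character(0)
  for (ch in dag$nodes)
    for (pa in dag$parents[[ch]])
      lines <- c(lines, sprintf("%s\t%s", ch, pa))
  writeLines(lines, path)
  invisible(path)
}

#' Ancestor closure of a term
#'
#' All nodes reachable from `D` over child->parent edges, including `D`.
#'
#' @param dag a `disease_dag`.
#' @param D a node name.
#' @return Character vector of node names (first element is `D`).
#' @export
dag_ancestors <- function(dag, D) {
  if (!D %in% dag$nodes) stop("node '", D, "' not in DAG")
  seen <- D
  frontier <- D
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}
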
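#' Directed acyclic graph over categorical variables
#'
#' A DAG is represented as a named list of parent-name vectors plus the
#' state set of every node. All structure-learning and fitting functions
#' operate on this representation.
#'
#' @param nodes Named list: node name -> character vector of states.
#' @param edges Optional list of length-2 character vectors
#'   `c(parent, child)` (or a 2-column matrix).
#' @return Object of class `or_dag` with elements `nodes` (state sets) and
#'   `parents` (named list of parent vectors).
#' @export
#' @examples
#' dag_new(list(A = c("a0", "a1"), B = c("b0", "b1")), list(c("A", "B")))
dag_new <- function(nodes, edges = list()) {
  stopifnot(is.list(nodes), !is.null(names(nodes)))
  parents <- setNames(vector("list", length(nodes)), names(nodes))
  for (n in names(nodes)) parents[[n]] <- character(0)
  g <- structure(list(nodes = nodes, parents = parents), class = "or_dag")
  if (is.matrix(edges)) edges <- split(edges, seq_len(nrow(edges)))
  for (e in edges) g <- dag_add_edge(g, e[1], e[2])
  g
}

#' @export
print.or_dag <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat(sprintf("<or_dag> %d node(s), %d edge(s)\n", length(x$nodes), ne))
  for (n in names(x$parents)) {
    if (length(x$parents[[n]]) > 0) {
      cat("  ", paste(x$parents[[n]], collapse = ", "), " -> ", n, "\n", sep = "")
    }
  }
  invisible(x)
}

dag_check_node <- function(dag, n) {
  if (!n %in% names(dag$nodes)) stop("unknown node '", n, "'", call. = FALSE)
}

#' DAG edge editing
#'
#' Add, delete, or reverse a directed edge, preserving acyclicity (adding
#' or reversing an edge that would create a cycle is an error).
#'
#' @param dag An [dag_new()] object.
#' @param from,to Node names.
#' @return The modified `or_dag`.
#' @export
dag_add_edge <- function(dag, from, to) {
  dag_check_node(dag, from); dag_check_node(dag, to)
  if (from == to) stop("self-loop ", from, " -> ", to, call. = FALSE)
  if (from %in% dag$parents[[to]]) return(dag)
  dag$parents[[to]] <- sort(c(dag$parents[[to]], from))
  if (dag_has_cycle(dag)) {
    stop("edge ", from, " -> ", to, " would create a cycle", call. = FALSE)
  }
  dag
}

#' @rdname dag_add_edge
#' @export
dag_delete_edge <- function(dag, from, to) {
  dag_check_node(dag, from); dag_check_node(dag, to)
  dag$parents[[to]] <- setdiff(dag$parents[[to]], from)
  dag
}

#' @rdname dag_add_edge
#' @export
dag_reverse_edge <- function(dag, from, to) {
  if (!from %in% dag$parents[[to]]) {
    stop("no edge ", from, " -> ", to, " to reverse", call. = FALSE)
  }
  dag <- dag_delete_edge(dag, from, to)
  dag_add_edge(dag, to, from)
}

#' Edge list of a DAG
#' @param dag An `or_dag`.
#' @return Two-column character matrix (`from`, `to`), lexicographically
#'   ordered; zero rows for an empty graph.
#' @export
dag_edges <- function(dag) {
  out <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
  for (n in sort(names(dag$parents))) {
    for (p in dag$parents[[n]]) out <- rbind(out, c(p, n))
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Test a DAG for cycles
#' @param dag An `or_dag`.
#' @return `TRUE` if the directed graph contains a cycle.
#' @export
dag_has_cycle <- function(dag) {
  is.null(dag_topological_order(dag))
}

#' Topological order of a DAG
#' @param dag An `or_dag`.
#' @return Character vector of node names, parents before children, or
#'   `NULL` if the graph is cyclic.
#' @export
dag_topological_order <- function(dag) {
  remaining <- names(dag$nodes)
  parents <- dag$parents
  order <- character(0)
  while (length(remaining) > 0) {
    free <- remaining[vapply(remaining, function(n) {
      length(intersect(parents[[n]], remaining)) == 0
    }, logical(1))]
    if (length(free) == 0) return(NULL)
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  order
}

#' Undirected skeleton of a DAG
#' @param dag An `or_dag`.
#' @return Character vector of undirected edges `"a--b"` with `a < b`,
#'   sorted; convenient for comparing learned and true structures.
#' @export
dag_skeleton <- function(dag) {
  e <- dag_edges(dag)
  if (nrow(e) == 0) return(character(0))
  und <- apply(e, 1, function(r) paste(sort(r), collapse = "--"))
  sort(unique(und))
}
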
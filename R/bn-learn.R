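#' Score-based hill-climbing structure learning
#'
#' Greedy best-improvement search over DAGs starting from the empty graph.
#' At each step all legal single-edge additions, deletions, and reversals
#' are scored (exploiting score decomposability with a per-family cache)
#' and the highest-scoring strictly improving move is applied; the search
#' stops when no move improves the score or `max_iter` is reached. The
#' accepted-move score sequence is strictly increasing. Ties between
#' equally scoring moves are broken lexicographically by (kind, from, to),
#' so the result is deterministic; `seed` is accepted for interface
#' stability but only influences exact floating-point ties (which the
#' lexicographic rule already resolves).
#'
#' @param data Data frame of factors/characters, one column per variable.
#' @param score `"bic"` (default; penalized, see [bic_score()]), `"aic"`
#'   (penalty 1 per free parameter; less conservative at small samples),
#'   `"bdeu"` (Bayesian-Dirichlet equivalent marginal likelihood,
#'   equivalent sample size 10), or `"loglik"` (raw maximized likelihood,
#'   which prefers dense graphs -- retained for fidelity experiments).
#' @param states Optional named list of state sets; defaults to the
#'   observed factor levels (or sorted unique values) of each column.
#' @param forbidden,required Optional lists of `c(from, to)` edges that may
#'   never / must always be present. Required edges are installed first; a
#'   required set that forces a cycle is an error.
#' @param max_iter Maximum accepted moves (default 100).
#' @param seed Optional integer, see above.
#' @return A list of class `or_hc_fit`: `dag`, `score` (final total),
#'   `trace` (score after each accepted move), `n_iter`.
#' @export
#' @examples
#' d <- data.frame(A = factor(rep(c("a", "b"), 50)),
#'                 B = factor(rep(c("x", "y"), 50)))
#' hill_climb(d)$dag  # independent columns: empty graph under BIC
hill_climb <- function(data, score = c("bic", "aic", "bdeu", "loglik"),
                       states = NULL,
                       forbidden = list(), required = list(),
                       max_iter = 100, seed = NULL) {
  score <- match.arg(score)
  if (nrow(data) < 1) stop("need at least one data row", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vars <- names(data)
  if (is.null(states)) {
    states <- lapply(data, function(col) {
      if (is.factor(col)) levels(col) else sort(unique(as.character(col)))
    })
  }
  for (v in vars) data[[v]] <- factor(data[[v]], levels = states[[v]])

  dag <- dag_new(states)
  for (e in required) dag <- dag_add_edge(dag, e[1], e[2])
  forb_key <- vapply(forbidden, function(e) paste(e[1], e[2]), "")
  req_key <- vapply(required, function(e) paste(e[1], e[2]), "")

  fam_cache <- new.env(parent = emptyenv())
  fscore <- function(node, parents) {
    key <- paste(node, paste(parents, collapse = ","), sep = "|")
    if (!is.null(fam_cache[[key]])) return(fam_cache[[key]])
    s <- family_score(data, node, parents, states, score)
    fam_cache[[key]] <- s
    s
  }
  node_score <- setNames(vapply(vars, function(n) {
    fscore(n, dag$parents[[n]])
  }, numeric(1)), vars)
  total <- sum(node_score)
  trace <- total

  legal_add <- function(dag, from, to) {
    !(from %in% dag$parents[[to]]) && from != to &&
      !(paste(from, to) %in% forb_key) &&
      !dag_has_cycle(dag_add_edge_unchecked(dag, from, to))
  }
  dag_add_edge_unchecked <- function(dag, from, to) {
    dag$parents[[to]] <- sort(c(dag$parents[[to]], from))
    dag
  }

  n_iter <- 0
  repeat {
    if (n_iter >= max_iter) break
    best <- NULL  # list(kind, from, to, delta, new_scores)
    consider <- function(kind, from, to, delta, new_scores) {
      if (delta <= 1e-12) return()
      if (is.null(best) || delta > best$delta + 1e-12 ||
          (abs(delta - best$delta) <= 1e-12 &&
           paste(kind, from, to) < paste(best$kind, best$from, best$to))) {
        best <<- list(kind = kind, from = from, to = to, delta = delta,
                      new_scores = new_scores)
      }
    }
    for (from in vars) {
      for (to in vars) {
        if (from == to) next
        present <- from %in% dag$parents[[to]]
        if (!present) {
          if (legal_add(dag, from, to)) {
            s_new <- fscore(to, sort(c(dag$parents[[to]], from)))
            consider("add", from, to, s_new - node_score[[to]],
                     setNames(list(s_new), to))
          }
        } else {
          if (!(paste(from, to) %in% req_key)) {
            # delete
            s_new <- fscore(to, setdiff(dag$parents[[to]], from))
            consider("delete", from, to, s_new - node_score[[to]],
                     setNames(list(s_new), to))
            # reverse: delete from->to, add to->from
            d2 <- dag_delete_edge(dag, from, to)
            if (!(paste(to, from) %in% forb_key) &&
                !dag_has_cycle(dag_add_edge_unchecked(d2, to, from))) {
              s_to <- fscore(to, setdiff(dag$parents[[to]], from))
              s_from <- fscore(from, sort(c(dag$parents[[from]], to)))
              delta <- (s_to - node_score[[to]]) + (s_from - node_score[[from]])
              consider("reverse", from, to, delta,
                       setNames(list(s_to, s_from), c(to, from)))
            }
          }
        }
      }
    }
    if (is.null(best)) break
    dag <- switch(best$kind,
                  add = dag_add_edge(dag, best$from, best$to),
                  delete = dag_delete_edge(dag, best$from, best$to),
                  reverse = dag_reverse_edge(dag, best$from, best$to))
    for (n in names(best$new_scores)) node_score[[n]] <- best$new_scores[[n]]
    total <- sum(node_score)
    trace <- c(trace, total)
    n_iter <- n_iter + 1
  }
  structure(list(dag = dag, score = total, trace = trace, n_iter = n_iter),
            class = "or_hc_fit")
}

#' @export
print.or_hc_fit <- function(x, ...) {
  cat(sprintf("<or_hc_fit> score %.3f after %d move(s)\n", x$score, x$n_iter))
  print(x$dag)
  invisible(x)
}

#' Naive Bayes structure and parameters
#'
#' Builds the star DAG with the target as sole parent of every attribute
#' and fits its conditional probability tables like [fit_cpts()]. The
#' result is a regular [fit_cpts()] network usable by [classify()]
#' unchanged.
#'
#' @param data Data frame of factors/characters.
#' @param target Name of the class column.
#' @param alpha Laplace smoothing pseudo-count (default 1).
#' @param states Optional named list of state sets.
#' @return An `or_bn` (see [fit_cpts()]).
#' @export
naive_bayes <- function(data, target, alpha = 1, states = NULL) {
  if (!target %in% names(data)) {
    stop("target '", target, "' is not a column of data", call. = FALSE)
  }
  if (is.null(states)) {
    states <- lapply(data, function(col) {
      if (is.factor(col)) levels(col) else sort(unique(as.character(col)))
    })
  }
  dag <- dag_new(states)
  for (a in setdiff(names(data), target)) dag <- dag_add_edge(dag, target, a)
  fit_cpts(dag, data, alpha = alpha)
}
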
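# Exact inference by variable elimination over dense table factors.
# A factor is list(vars = character, val = array with one dimension per
# variable, dimnames = state names). Networks here are small (a handful of
# nodes with 3-6 states), so dense tables are both simple and fast.

factor_from_cpt <- function(bn, node) {
  vars <- c(node, bn$dag$parents[[node]])
  val <- bn$cpts[[node]]
  if (length(vars) == 1) {
    val <- array(as.numeric(val), dim = length(bn$dag$nodes[[node]]),
                 dimnames = setNames(list(bn$dag$nodes[[node]]), node))
  }
  list(vars = vars, val = val)
}

# Restrict a factor to observed states of evidence variables (dropping
# those dimensions).
factor_reduce <- function(f, evidence) {
  keep <- intersect(f$vars, names(evidence))
  if (length(keep) == 0) return(f)
  idx <- lapply(f$vars, function(v) {
    if (v %in% keep) {
      i <- match(evidence[[v]], dimnames(f$val)[[which(f$vars == v)]])
      if (is.na(i)) stop("'", evidence[[v]], "' is not a state of node '", v,
                         "'", call. = FALSE)
      i
    } else {
      seq_len(dim(f$val)[which(f$vars == v)])
    }
  })
  val <- do.call(`[`, c(list(f$val), idx, list(drop = FALSE)))
  rem <- setdiff(f$vars, keep)
  dn <- dimnames(val)[match(rem, f$vars)]
  if (length(rem) == 0) {
    list(vars = character(0), val = sum(val))  # scalar factor
  } else {
    list(vars = rem,
         val = array(val, dim = dim(val)[match(rem, f$vars)],
                     dimnames = setNames(dn, rem)))
  }
}

factor_product <- function(f, g) {
  if (length(f$vars) == 0) return(list(vars = g$vars, val = g$val * as.numeric(f$val)))
  if (length(g$vars) == 0) return(list(vars = f$vars, val = f$val * as.numeric(g$val)))
  vars <- union(f$vars, g$vars)
  dims <- lapply(vars, function(v) {
    if (v %in% f$vars) dimnames(f$val)[[which(f$vars == v)]]
    else dimnames(g$val)[[which(g$vars == v)]]
  })
  names(dims) <- vars
  grid_dim <- vapply(dims, length, 1L)
  idx_grid <- arrayInd(seq_len(prod(grid_dim)), grid_dim)
  # index each input by the union-grid coordinates of its own dimensions
  expand <- function(h) {
    sub <- idx_grid[, match(h$vars, vars), drop = FALSE]
    hval <- array(as.numeric(h$val),
                  dim = vapply(h$vars, function(v) length(dims[[v]]), 1L))
    as.numeric(hval[sub])
  }
  val <- array(expand(f) * expand(g), dim = grid_dim, dimnames = dims)
  list(vars = vars, val = val)
}

factor_marginalize <- function(f, var) {
  i <- which(f$vars == var)
  if (length(i) == 0) return(f)
  rem <- f$vars[-i]
  if (length(rem) == 0) {
    return(list(vars = character(0), val = sum(f$val)))
  }
  val <- apply(f$val, seq_along(f$vars)[-i], sum)
  val <- array(val, dim = dim(f$val)[-i], dimnames = dimnames(f$val)[-i])
  list(vars = rem, val = val)
}

#' Posterior distribution of a query node
#'
#' Exact posterior `P(query | evidence)` computed by variable elimination:
#' CPT factors are reduced by the evidence, hidden variables are summed
#' out in a greedy smallest-factor order, and the result is normalized.
#' Missing-flagged attributes are handled by simply omitting them from the
#' evidence (they are marginalized).
#'
#' @param bn An [fit_cpts()] network.
#' @param query Name of the query node.
#' @param evidence Named list or character vector of observed states for a
#'   (possibly empty) subset of the other nodes.
#' @return Named numeric vector of class `or_posterior`: one probability
#'   per state of `query`, summing to 1.
#' @export
posterior <- function(bn, query, evidence = list()) {
  dag_check_node(bn$dag, query)
  evidence <- as.list(evidence)
  if (query %in% names(evidence)) {
    stop("query node cannot also be evidence", call. = FALSE)
  }
  for (v in names(evidence)) {
    dag_check_node(bn$dag, v)
    if (!evidence[[v]] %in% bn$dag$nodes[[v]]) {
      stop("'", evidence[[v]], "' is not a state of node '", v, "'",
           call. = FALSE)
    }
  }

  nodes <- names(bn$dag$nodes)
  # fast path: all non-query nodes observed -> posterior over query states
  # is the joint factorization with the query slot swept
  if (length(evidence) == length(nodes) - 1) {
    states <- bn$dag$nodes[[query]]
    w <- vapply(states, function(s) {
      asg <- c(evidence, setNames(list(s), query))
      prod(vapply(nodes, function(n) cpt_entry(bn, n, asg), numeric(1)))
    }, numeric(1))
    z <- sum(w)
    if (z <= 0) stop("evidence has probability 0 under the model", call. = FALSE)
    return(structure(w / z, class = "or_posterior", query = query))
  }

  factors <- lapply(nodes, function(n) {
    factor_reduce(factor_from_cpt(bn, n), evidence)
  })
  hidden <- setdiff(nodes, c(query, names(evidence)))
  for (h in hidden) {
    involved <- vapply(factors, function(f) h %in% f$vars, logical(1))
    if (!any(involved)) next
    prod_f <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved], list(factor_marginalize(prod_f, h)))
  }
  res <- Reduce(factor_product, factors)
  # res involves only the query (plus scalar weight factors)
  stopifnot(setdiff(res$vars, query) == character(0))
  val <- res$val
  if (length(res$vars) == 0) stop("internal: query eliminated", call. = FALSE)
  w <- as.numeric(val)
  names(w) <- dimnames(val)[[which(res$vars == query)]]
  w <- w[bn$dag$nodes[[query]]]
  z <- sum(w)
  if (z <= 0) stop("evidence has probability 0 under the model", call. = FALSE)
  structure(w / z, class = "or_posterior", query = query)
}

#' @export
print.or_posterior <- function(x, ...) {
  cat(sprintf("<or_posterior> P(%s | evidence):\n", attr(x, "query")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Classify the target node
#'
#' Returns the argmax state of the posterior of `target` given the
#' evidence, with ties broken by the target's fixed state order (a tie is
#' reported via a message).
#'
#' @param bn An [fit_cpts()] network.
#' @param target Target node name.
#' @param evidence Named list/vector of observed attribute states;
#'   missing-flagged attributes should be omitted.
#' @return List with `label` (chosen state) and `posterior`
#'   (an [posterior()] vector).
#' @export
classify <- function(bn, target, evidence = list()) {
  post <- posterior(bn, target, evidence)
  mx <- max(post)
  ties <- which(post >= mx - 1e-12)
  if (length(ties) > 1) {
    message("classify: posterior tie between ",
            paste(names(post)[ties], collapse = ", "),
            "; choosing first in state order")
  }
  list(label = names(post)[ties[1]], posterior = post)
}
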
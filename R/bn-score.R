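# Scoring of candidate structures against a discrete data table. Both the
# maximized log-likelihood and BIC decompose into per-family terms
# (node + parent set), which hill climbing exploits through score caching.

# Coerce a data.frame of factors/characters to the node state sets of a dag;
# checks every dag node has a column and every value is a known state.
check_data_nodes <- function(dag, data) {
  missing <- setdiff(names(dag$nodes), names(data))
  if (length(missing) > 0) {
    stop("data is missing node column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Maximized log-likelihood contribution of one family:
# sum over parent configs a and states x of N(x,a) * log(N(x,a) / N(a)).
family_loglik <- function(data, node, parents, states) {
  x <- factor(data[[node]], levels = states[[node]])
  if (length(parents) == 0) {
    counts <- table(x)
    n <- sum(counts)
    nz <- counts[counts > 0]
    return(sum(nz * log(nz / n)))
  }
  cfg <- interaction(data[parents], drop = FALSE, lex.order = TRUE)
  counts <- table(cfg, x)
  rowsums <- rowSums(counts)
  ll <- 0
  for (i in seq_len(nrow(counts))) {
    nz <- counts[i, counts[i, ] > 0]
    if (length(nz) > 0) ll <- ll + sum(nz * log(nz / rowsums[i]))
  }
  ll
}

# Free parameters of one family: (|states| - 1) * prod(parent cardinalities).
family_dim <- function(node, parents, states) {
  (length(states[[node]]) - 1) * prod(vapply(states[parents], length, 1L))
}

#' Maximized log-likelihood of a structure
#'
#' The log-likelihood of the data under the DAG with maximum-likelihood
#' conditional probability tables:
#' `sum over nodes, parent configurations a and states x of
#' N(x, a) * log(N(x, a) / N(a))` with `0 log 0 = 0`. Adding an edge can
#' never decrease this quantity, which is why raw likelihood scoring
#' prefers dense graphs and a complexity penalty (see [bic_score()]) is
#' used by default for structure search.
#'
#' @param dag An [dag_new()] object.
#' @param data Data frame with one column per node (factor or character).
#' @return Log-likelihood (non-positive).
#' @export
log_likelihood <- function(dag, data) {
  check_data_nodes(dag, data)
  sum(vapply(names(dag$nodes), function(n) {
    family_loglik(data, n, dag$parents[[n]], dag$nodes)
  }, numeric(1)))
}

#' BIC score of a structure
#'
#' `log_likelihood(dag, data) - (log(N) / 2) * k` where `k` is the number
#' of free parameters `sum_i (|states_i| - 1) * prod_{p in parents(i)}
#' |states_p|`. Decomposable: changing one node's parent set changes only
#' that node's term. Higher is better.
#'
#' @inheritParams log_likelihood
#' @return BIC score.
#' @export
bic_score <- function(dag, data) {
  check_data_nodes(dag, data)
  n <- nrow(data)
  k <- sum(vapply(names(dag$nodes), function(nd) {
    family_dim(nd, dag$parents[[nd]], dag$nodes)
  }, numeric(1)))
  log_likelihood(dag, data) - (log(n) / 2) * k
}

# Bayesian-Dirichlet (BDeu) family marginal log-likelihood with equivalent
# sample size ess: sum over parent configs a of
#   lgamma(a0) - lgamma(a0 + N(a)) + sum_x [lgamma(ax + N(x,a)) - lgamma(ax)]
# with ax = ess / (r * q), a0 = ess / q.
family_bdeu <- function(data, node, parents, states, ess = 10) {
  x <- factor(data[[node]], levels = states[[node]])
  r <- length(states[[node]])
  if (length(parents) == 0) {
    counts <- matrix(table(x), nrow = 1)
  } else {
    cfg <- interaction(data[parents], drop = FALSE, lex.order = TRUE)
    counts <- unclass(table(cfg, x))
  }
  q <- nrow(counts)
  ax <- ess / (r * q)
  a0 <- ess / q
  sum(lgamma(a0) - lgamma(a0 + rowSums(counts))) +
    sum(lgamma(ax + counts) - lgamma(ax))
}

# Per-family score used by hill climbing;
# score = "bic", "aic", "loglik" or "bdeu".
family_score <- function(data, node, parents, states, score) {
  if (score == "bdeu") {
    return(family_bdeu(data, node, parents, states))
  }
  ll <- family_loglik(data, node, parents, states)
  switch(score,
         bic = ll - (log(nrow(data)) / 2) * family_dim(node, parents, states),
         aic = ll - family_dim(node, parents, states),
         loglik = ll)
}
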
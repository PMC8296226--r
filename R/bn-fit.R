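#' Fit conditional probability tables
#'
#' Maximum-likelihood (optionally Laplace-smoothed) CPTs for a given
#' structure: `P(x | a) = (N(x, a) + alpha) / (N(a) + alpha * |states|)`.
#' With `alpha = 0` this is the pure maximum-likelihood estimate; a parent
#' configuration never seen in the data then gets a uniform row with a
#' warning.
#'
#' @param dag An [dag_new()] object.
#' @param data Data frame with one column per node.
#' @param alpha Pseudo-count, `>= 0` (default 0).
#' @return Object of class `or_bn`: `dag` plus `cpts`, a named list of
#'   arrays. Each CPT is an array whose first dimension indexes the node's
#'   states and remaining dimensions its parents' states (dimnames carry
#'   the state names); columns over the first dimension sum to 1.
#' @export
fit_cpts <- function(dag, data, alpha = 0) {
  check_data_nodes(dag, data)
  stopifnot(alpha >= 0)
  states <- dag$nodes
  for (v in names(states)) data[[v]] <- factor(data[[v]], levels = states[[v]])
  cpts <- list()
  for (node in names(states)) {
    parents <- dag$parents[[node]]
    r <- length(states[[node]])
    if (length(parents) == 0) {
      counts <- table(data[[node]])
      p <- (as.numeric(counts) + alpha) / (sum(counts) + alpha * r)
      cpt <- array(p, dim = r, dimnames = setNames(list(states[[node]]), node))
    } else {
      counts <- table(data[c(node, parents)])
      cfg_n <- apply(counts, seq_along(parents) + 1, sum)
      if (alpha == 0 && any(cfg_n == 0)) {
        warning("node '", node, "': ", sum(cfg_n == 0),
                " unseen parent configuration(s) given uniform rows",
                call. = FALSE)
      }
      probs <- sweep(counts + alpha, seq_along(parents) + 1,
                     cfg_n + alpha * r, "/")
      if (alpha == 0) {
        # uniform fallback for unseen parent configs
        uni <- array(rep(cfg_n == 0, each = r), dim = dim(counts))
        probs[uni] <- 1 / r
      }
      cpt <- array(as.numeric(probs), dim = dim(counts),
                   dimnames = dimnames(counts))
    }
    cpts[[node]] <- cpt
  }
  structure(list(dag = dag, cpts = cpts), class = "or_bn")
}

#' @export
print.or_bn <- function(x, ...) {
  cat(sprintf("<or_bn> %d node(s), %d edge(s)\n", length(x$dag$nodes),
              sum(lengths(x$dag$parents))))
  for (n in names(x$dag$parents)) {
    p <- x$dag$parents[[n]]
    cat(sprintf("  %s (%d states)%s\n", n, length(x$dag$nodes[[n]]),
                if (length(p) > 0) paste0(" | ", paste(p, collapse = ", ")) else ""))
  }
  invisible(x)
}

# CPT entry P(node = assignment[node] | parents at assignment).
cpt_entry <- function(bn, node, assignment) {
  cpt <- bn$cpts[[node]]
  idx <- lapply(c(node, bn$dag$parents[[node]]), function(v) {
    s <- assignment[[v]]
    i <- match(s, bn$dag$nodes[[v]])
    if (is.na(i)) stop("'", s, "' is not a state of node '", v, "'",
                       call. = FALSE)
    i
  })
  do.call(`[`, c(list(cpt), idx))
}

#' Joint probability of a full assignment
#'
#' The network factorization: the product over nodes of
#' `P(node | parents)` evaluated at the assignment.
#'
#' @param bn An [fit_cpts()] network.
#' @param assignment Named list or character vector assigning a state to
#'   every node.
#' @return Probability in `[0, 1]`.
#' @export
joint_probability <- function(bn, assignment) {
  assignment <- as.list(assignment)
  missing <- setdiff(names(bn$dag$nodes), names(assignment))
  if (length(missing) > 0) {
    stop("assignment is missing node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  prod(vapply(names(bn$dag$nodes), function(n) cpt_entry(bn, n, assignment),
              numeric(1)))
}

#' Sample observations from a network
#'
#' Ancestral sampling in topological order; used for parameter- and
#' structure-recovery experiments.
#'
#' @param bn An [fit_cpts()] network.
#' @param n Number of rows.
#' @param seed Optional integer seed.
#' @return Data frame of factors, one column per node.
#' @export
sample_bn <- function(bn, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ord <- dag_topological_order(bn$dag)
  out <- setNames(vector("list", length(ord)), ord)
  for (node in ord) {
    states <- bn$dag$nodes[[node]]
    parents <- bn$dag$parents[[node]]
    draws <- character(n)
    if (length(parents) == 0) {
      p <- as.numeric(bn$cpts[[node]])
      draws <- sample(states, n, replace = TRUE, prob = p)
    } else {
      cfg <- do.call(paste, c(out[parents], sep = "\r"))
      for (u in unique(cfg)) {
        sel <- cfg == u
        asg <- setNames(as.list(strsplit(u, "\r", fixed = TRUE)[[1]]), parents)
        p <- vapply(states, function(s) {
          cpt_entry(bn, node, c(setNames(list(s), node), asg))
        }, numeric(1))
        draws[sel] <- sample(states, sum(sel), replace = TRUE, prob = p)
      }
    }
    out[[node]] <- draws
  }
  nms <- names(bn$dag$nodes)
  as.data.frame(lapply(setNames(nms, nms), function(nd) {
    factor(out[[nd]], levels = bn$dag$nodes[[nd]])
  }))
}
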
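# Independent oracles used across the test files. These deliberately avoid
# the package's own algorithms: LCSS by exhaustive recursion, inference by
# full joint enumeration, structure search by scoring every DAG.

# --- LCSS: exhaustive recursive longest monotone matching -----------------
# Points i of a and j of b may match when planar distance <= eps and
# |i - j| <= delta. Plain memoized recursion over (i, j).
lcss_bruteforce <- function(ax, ay, bx, by, eps, delta = Inf) {
  n <- length(ax); m <- length(bx)
  memo <- matrix(NA_integer_, n + 1, m + 1)
  rec <- function(i, j) {
    if (i > n || j > m) return(0L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- max(rec(i + 1L, j), rec(i, j + 1L))
    if (abs(i - j) <= delta &&
        (ax[i] - bx[j])^2 + (ay[i] - by[j])^2 <= eps^2) {
      best <- max(best, 1L + rec(i + 1L, j + 1L))
    }
    memo[i, j] <<- best
    best
  }
  rec(1L, 1L)
}

make_traj <- function(x, y, case_id = "c", role = "surgeon", t = NULL) {
  if (is.null(t)) t <- seq_along(x) - 1
  trajectory(case_id, role, t = t, x = x, y = y)
}

# --- Inference: posterior by full joint enumeration -----------------------
posterior_bruteforce <- function(bn, query, evidence = list()) {
  nodes <- names(bn$dag$nodes)
  grid <- expand.grid(bn$dag$nodes, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  grid <- grid[keep, , drop = FALSE]
  w <- vapply(seq_len(nrow(grid)), function(i) {
    joint_probability(bn, as.list(grid[i, , drop = FALSE]))
  }, numeric(1))
  agg <- tapply(w, factor(grid[[query]], levels = bn$dag$nodes[[query]]), sum)
  p <- as.numeric(agg)
  p[is.na(p)] <- 0
  setNames(p / sum(p), bn$dag$nodes[[query]])
}

# Random network over n_nodes nodes with n_states states each and random
# edges (acyclic by construction: edges only from earlier to later nodes in
# a shuffled order), Dirichlet-ish random CPTs.
random_bn <- function(n_nodes, n_states = 3, edge_prob = 0.4) {
  nm <- paste0("N", seq_len(n_nodes))
  states <- setNames(lapply(nm, function(.) paste0("s", seq_len(n_states))), nm)
  ord <- sample(nm)
  edges <- list()
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq(i + 1, n_nodes)) {
      if (runif(1) < edge_prob) edges[[length(edges) + 1]] <- c(ord[i], ord[j])
    }
  }
  dag <- dag_new(states, edges)
  cpts <- list()
  for (n in nm) {
    parents <- dag$parents[[n]]
    r <- n_states
    q <- prod(vapply(states[parents], length, 1L))
    mat <- matrix(rgamma(r * q, 1) + 0.05, nrow = r)
    mat <- sweep(mat, 2, colSums(mat), "/")
    dims <- unname(c(r, vapply(states[parents], length, 1L)))
    cpts[[n]] <- array(mat, dim = dims,
                       dimnames = c(setNames(list(states[[n]]), n),
                                    states[parents]))
  }
  structure(list(dag = dag, cpts = cpts), class = "or_bn")
}

# --- Structure search: exhaustive search over all DAGs (3 nodes) ----------
all_dags_3 <- function(states) {
  nm <- names(states)
  pairs <- t(combn(nm, 2))
  # each unordered pair: absent / -> / <-
  choices <- expand.grid(rep(list(0:2), nrow(pairs)))
  dags <- list()
  for (i in seq_len(nrow(choices))) {
    edges <- list()
    for (k in seq_len(nrow(pairs))) {
      ch <- choices[i, k]
      if (ch == 1) edges[[length(edges) + 1]] <- c(pairs[k, 1], pairs[k, 2])
      if (ch == 2) edges[[length(edges) + 1]] <- c(pairs[k, 2], pairs[k, 1])
    }
    d <- try(dag_new(states, edges), silent = TRUE)
    if (!inherits(d, "try-error")) dags[[length(dags) + 1]] <- d
  }
  dags
}

# v-structures (colliders a -> c <- b with a, b non-adjacent), for
# equivalence-class comparison of learned structures
v_structures <- function(dag) {
  out <- character(0)
  skel <- dag_skeleton(dag)
  for (n in names(dag$parents)) {
    ps <- dag$parents[[n]]
    if (length(ps) < 2) next
    for (pair in combn(ps, 2, simplify = FALSE)) {
      if (!paste(sort(pair), collapse = "--") %in% skel) {
        out <- c(out, paste0(pair[1], ">", n, "<", pair[2]))
      }
    }
  }
  sort(out)
}

# Dominant-state indices per parent configuration, redrawn until every
# parent has a clear *marginal* effect on the child (total variation
# >= 0.15 between the marginalized conditionals of any two parent levels).
# An unconstrained iid draw can leave an edge nearly unidentifiable, while
# additive/parity patterns hide edges from greedy single-edge search.
dominant_pattern <- function(parent_cards, r, p_dom = 0.8) {
  q <- prod(parent_cards)
  grid <- expand.grid(lapply(parent_cards, seq_len))
  repeat {
    dominant <- sample.int(r, q, replace = TRUE)
    cpt <- matrix((1 - p_dom) / (r - 1), nrow = r, ncol = q)
    cpt[cbind(dominant, seq_len(q))] <- p_dom
    ok <- TRUE
    for (k in seq_along(parent_cards)) {
      marg <- vapply(seq_len(parent_cards[k]), function(v) {
        rowMeans(cpt[, grid[[k]] == v, drop = FALSE])
      }, numeric(r))
      for (u in seq_len(ncol(marg) - 1)) {
        for (v in seq(u + 1, ncol(marg))) {
          if (sum(abs(marg[, u] - marg[, v])) / 2 < 0.15) ok <- FALSE
        }
      }
    }
    if (ok) return(dominant)
  }
}

# Ground-truth interaction structure used by recovery tests: the phase
# drives the surgeon-scrub interaction, which is also driven by the
# assistant-scrub channel; the remaining pairs influence the sterile pair
# indirectly through a chain. CPTs put p = 0.8 on a dominant state that
# changes with every parent.
truth_5node_bn <- function(seed = 1) {
  set.seed(seed)
  states <- list(
    phase = or_phases(),
    surg_scrub = c("Low", "Medium", "High"),
    asst_scrub = c("Low", "Medium", "High"),
    asst_surg = c("Low", "Medium", "High"),
    anes_asst = c("Low", "Medium", "High"))
  dag <- dag_new(states, list(
    c("phase", "surg_scrub"), c("asst_scrub", "surg_scrub"),
    c("asst_surg", "asst_scrub"), c("anes_asst", "asst_surg")))
  cpts <- list()
  for (n in names(states)) {
    r <- length(states[[n]])
    parents <- dag$parents[[n]]
    cards <- vapply(states[parents], length, 1L)
    q <- prod(cards)
    mat <- matrix(0.2 / (r - 1), nrow = r, ncol = q)
    dominant <- dominant_pattern(cards, r)
    for (j in seq_len(q)) mat[dominant[j], j] <- 0.8
    if (length(parents) == 0) mat <- matrix(rep(1 / r, r))
    dims <- unname(c(r, cards))
    cpts[[n]] <- array(mat, dim = dims,
                       dimnames = c(setNames(list(states[[n]]), n),
                                    states[parents]))
  }
  structure(list(dag = dag, cpts = cpts), class = "or_bn")
}

# --- Chance-level oracle --------------------------------------------------
# Mean holdout accuracy over label permutations: each repetition freshly
# permutes the phase labels (breaking any fixed-table association) and runs
# one stratified holdout, under which the expected accuracy for a balanced
# table is exactly 1/6.
chance_accuracies <- function(tab, n_reps, n_train, spec, seed) {
  vapply(seq_len(n_reps), function(r) {
    set.seed(seed + 7 * r)
    tab$phase <- sample(tab$phase)
    rep1 <- suppressMessages(repeated_holdout(
      tab, n_train = n_train, n_reps = 1, spec = spec,
      seed = seed + 7 * r + 3, split = "stratified"))
    rep1$accuracies
  }, numeric(1))
}

# Balanced 6-phase table with label-independent noise features.
balanced_noise_table <- function(n_per_phase = 13, seed = 1) {
  set.seed(seed)
  phases <- or_phases()
  n <- n_per_phase * 6
  tab <- data.frame(
    case_id = "c1", occurrence = 1,
    phase = factor(rep(phases, each = n_per_phase), levels = phases),
    surg_scrub_sim = runif(n), asst_surg_sim = runif(n),
    anes_asst_sim = runif(n), asst_scrub_sim = runif(n))
  class(tab) <- c("or_feature_table", "data.frame")
  tab
}
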
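test_that("joint probability factorizes and sums to 1 over all assignments", {
  # two independent binary nodes, uniform
  bn <- fit_cpts(dag_new(list(A = c("a0", "a1"), B = c("b0", "b1"))),
                 data.frame(A = c("a0", "a1", "a0", "a1"),
                            B = c("b0", "b0", "b1", "b1")))
  expect_equal(joint_probability(bn, list(A = "a0", B = "b1")), 0.25)
  expect_error(joint_probability(bn, list(A = "a0")), "missing node")

  # random 5-node nets: total probability is 1
  set.seed(42)
  for (i in 1:5) {
    bn <- random_bn(5, n_states = 2)
    grid <- expand.grid(bn$dag$nodes, stringsAsFactors = FALSE)
    tot <- sum(vapply(seq_len(nrow(grid)), function(r) {
      joint_probability(bn, as.list(grid[r, ]))
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("log-likelihood matches hand counting and is monotone in edges", {
  # 6-row two-node table, counts done by hand:
  # A: 4x a0, 2x a1 -> LL_A = 4 log(4/6) + 2 log(2/6)
  # B | empty graph: 3x b0, 3x b1 -> LL_B = 6 log(1/2)
  d <- data.frame(A = c("a0", "a0", "a0", "a0", "a1", "a1"),
                  B = c("b0", "b0", "b1", "b1", "b0", "b1"))
  states <- list(A = c("a0", "a1"), B = c("b0", "b1"))
  g0 <- dag_new(states)
  expect_equal(log_likelihood(g0, d),
               4 * log(4 / 6) + 2 * log(2 / 6) + 6 * log(1 / 2))
  # with A -> B: B counts split by A: (2,2) within a0, (1,1) within a1
  g1 <- dag_new(states, list(c("A", "B")))
  expect_equal(log_likelihood(g1, d),
               4 * log(4 / 6) + 2 * log(2 / 6) +
                 2 * log(2 / 4) + 2 * log(2 / 4) + 2 * log(1 / 2))

  # adding an edge never decreases the maximized likelihood
  set.seed(7)
  for (rep in 1:20) {
    nm <- c("X", "Y", "Z")
    d <- as.data.frame(setNames(lapply(nm, function(.) {
      sample(c("u", "v", "w"), 30, replace = TRUE)
    }), nm))
    states <- setNames(rep(list(c("u", "v", "w")), 3), nm)
    g <- dag_new(states)
    ll0 <- log_likelihood(g, d)
    from <- sample(nm, 1); to <- sample(setdiff(nm, from), 1)
    ll1 <- log_likelihood(dag_add_edge(g, from, to), d)
    expect_gte(ll1, ll0 - 1e-10)
  }
})

test_that("BIC penalty counts free parameters and decomposes by node", {
  set.seed(13)
  nm <- c("X", "Y", "Z")
  d <- as.data.frame(setNames(lapply(nm, function(.) {
    sample(c("u", "v"), 50, replace = TRUE)
  }), nm))
  states <- setNames(rep(list(c("u", "v")), 3), nm)
  g0 <- dag_new(states)
  expect_equal(bic_score(g0, d), log_likelihood(g0, d) - 3 * log(50) / 2)

  # decomposability: adding X -> Y changes only Y's term
  g1 <- dag_add_edge(g0, "X", "Y")
  delta_full <- bic_score(g1, d) - bic_score(g0, d)
  term <- function(g, node) {
    x <- factor(d[[node]], levels = states[[node]])
    orflow:::family_score(d, node, g$parents[[node]], states, "bic")
  }
  expect_equal(delta_full, term(g1, "Y") - term(g0, "Y"), tolerance = 1e-10)

  # complete graph scores below the generating sparse graph at N = 500
  truth <- truth_5node_bn(seed = 3)
  dat <- sample_bn(truth, 500, seed = 4)
  complete <- dag_new(truth$dag$nodes)
  ord <- names(truth$dag$nodes)
  for (i in seq_along(ord)[-1]) {
    for (j in seq_len(i - 1)) complete <- dag_add_edge(complete, ord[j], ord[i])
  }
  expect_lt(bic_score(complete, dat), bic_score(truth$dag, dat))
})

test_that("hill climbing agrees with exhaustive DAG search on 3-node data", {
  set.seed(11)
  states <- list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1"))
  for (rep in 1:10) {
    # random generating chain with strong dependence
    n <- 300
    a <- sample(c("0", "1"), n, replace = TRUE)
    b <- ifelse(runif(n) < 0.9, a, sample(c("0", "1"), n, replace = TRUE))
    c_ <- ifelse(runif(n) < 0.9, b, sample(c("0", "1"), n, replace = TRUE))
    d <- data.frame(A = factor(a, c("0", "1")), B = factor(b, c("0", "1")),
                    C = factor(c_, c("0", "1")))
    hc <- hill_climb(d, score = "bic")
    best <- max(vapply(all_dags_3(states), function(g) bic_score(g, d),
                       numeric(1)))
    expect_equal(hc$score, best, tolerance = 1e-9)
    # equivalence class of the chain A - B - C with no collider
    expect_setequal(dag_skeleton(hc$dag), c("A--B", "B--C"))
    expect_length(v_structures(hc$dag), 0)
  }
})

test_that("hill climbing search contract holds", {
  set.seed(5)
  # independent uniform columns: no improving move under BIC
  d <- data.frame(A = sample(c("0", "1"), 100, replace = TRUE),
                  B = sample(c("0", "1"), 100, replace = TRUE))
  hc <- hill_climb(d, score = "bic")
  expect_equal(nrow(dag_edges(hc$dag)), 0)
  expect_equal(hc$n_iter, 0)

  # accepted-move score sequence strictly increases; final >= empty score
  truth <- truth_5node_bn(seed = 8)
  dat <- sample_bn(truth, 200, seed = 9)
  hc <- hill_climb(dat, score = "bic")
  expect_true(all(diff(hc$trace) > 0))
  states <- lapply(dat, levels)
  expect_gte(hc$score, bic_score(dag_new(states), dat))

  # constraints: forbidden edges never appear, required edges always do
  hc2 <- hill_climb(dat, score = "bic",
                    forbidden = list(c("phase", "surg_scrub"),
                                     c("surg_scrub", "phase")),
                    required = list(c("anes_asst", "phase")))
  e <- apply(dag_edges(hc2$dag), 1, paste, collapse = ">")
  expect_false("phase>surg_scrub" %in% e)
  expect_false("surg_scrub>phase" %in% e)
  expect_true("anes_asst>phase" %in% e)

  # same data, same call -> identical result (determinism)
  hc3 <- hill_climb(dat, score = "bic")
  expect_identical(dag_edges(hc3$dag), dag_edges(hc$dag))
})

test_that("raw-likelihood scoring prefers denser graphs than BIC", {
  truth <- truth_5node_bn(seed = 21)
  dat <- sample_bn(truth, 200, seed = 22)
  n_bic <- nrow(dag_edges(hill_climb(dat, score = "bic")$dag))
  n_ml <- nrow(dag_edges(hill_climb(dat, score = "loglik")$dag))
  expect_gte(n_ml, n_bic)
})

test_that("CPT fitting is MLE at alpha 0 and shrinks to uniform as alpha grows", {
  d <- data.frame(A = c("s", "s", "s", "t", "t", "t"),
                  B = c("x", "x", "y", "y", "y", "y"))
  states <- list(A = c("s", "t"), B = c("x", "y"))
  bn <- fit_cpts(dag_new(states), d)
  expect_equal(as.numeric(bn$cpts$A), c(0.5, 0.5))

  bn2 <- fit_cpts(dag_new(states, list(c("A", "B"))), d)
  expect_equal(unname(bn2$cpts$B["x", "s"]), 2 / 3)
  # every CPT column sums to 1
  expect_equal(sum(bn2$cpts$A), 1, tolerance = 1e-9)
  expect_equal(unname(colSums(bn2$cpts$B)), c(1, 1), tolerance = 1e-9)

  big <- fit_cpts(dag_new(states), d, alpha = 1e9)
  expect_equal(as.numeric(big$cpts$B), c(0.5, 0.5), tolerance = 1e-6)

  # unseen parent configuration -> uniform row with warning at alpha 0
  d2 <- data.frame(A = c("s", "s"), B = c("x", "y"))
  expect_warning(bn3 <- fit_cpts(dag_new(states, list(c("A", "B"))), d2),
                 "unseen parent configuration")
  expect_equal(unname(bn3$cpts$B[, "t"]), c(0.5, 0.5))
})

test_that("fitted CPTs recover generating parameters at N = 5000", {
  # chain net with single parents, so every parent configuration receives
  # enough draws for the +/- 0.05 recovery band
  set.seed(31)
  states <- list(phase = or_phases(),
                 surg_scrub = c("Low", "Medium", "High"),
                 asst_scrub = c("Low", "Medium", "High"))
  dag <- dag_new(states, list(c("phase", "surg_scrub"),
                              c("surg_scrub", "asst_scrub")))
  cpts <- list()
  for (n in names(states)) {
    r <- length(states[[n]])
    parents <- dag$parents[[n]]
    q <- prod(vapply(states[parents], length, 1L))
    mat <- matrix(0.2 / (r - 1), nrow = r, ncol = q)
    for (j in seq_len(q)) mat[sample.int(r, 1), j] <- 0.8
    if (length(parents) == 0) mat <- matrix(rep(1 / r, r))
    cpts[[n]] <- array(mat, dim = unname(c(r, vapply(states[parents], length, 1L))),
                       dimnames = c(setNames(list(states[[n]]), n),
                                    states[parents]))
  }
  truth <- structure(list(dag = dag, cpts = cpts), class = "or_bn")
  dat <- sample_bn(truth, 5000, seed = 32)
  fit <- fit_cpts(truth$dag, dat, alpha = 1)
  for (n in names(truth$cpts)) {
    expect_true(all(abs(fit$cpts[[n]] - truth$cpts[[n]]) < 0.05),
                label = paste("CPT recovery for", n))
  }
})

test_that("variable elimination matches joint enumeration to 1e-10", {
  set.seed(99)
  for (rep in 1:20) {
    bn <- random_bn(sample(3:6, 1), n_states = 3)
    nodes <- names(bn$dag$nodes)
    query <- sample(nodes, 1)
    n_ev <- sample(0:(length(nodes) - 1), 1)
    ev_nodes <- sample(setdiff(nodes, query), n_ev)
    ev <- lapply(setNames(ev_nodes, ev_nodes), function(v) {
      sample(bn$dag$nodes[[v]], 1)
    })
    got <- posterior(bn, query, ev)
    want <- posterior_bruteforce(bn, query, ev)
    expect_equal(unclass(got), want, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("posterior handles edge cases per contract", {
  d <- data.frame(A = c("s", "s", "t"), B = c("x", "x", "y"))
  bn <- fit_cpts(dag_new(list(A = c("s", "t"), B = c("x", "y")),
                         list(c("A", "B"))), d)
  # no evidence -> prior marginal
  expect_equal(as.numeric(posterior(bn, "A")), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  # deterministic child observed -> posterior concentrates
  expect_equal(unname(posterior(bn, "A", list(B = "y"))["t"]), 1)
  expect_error(posterior(bn, "A", list(B = "nope")), "not a state")
  # impossible evidence: P(B = y | A = s) = 0 and A = s forced by query? use
  # a net where evidence has probability zero overall
  d0 <- data.frame(A = c("s", "s"), B = c("x", "x"))
  bn0 <- suppressWarnings(fit_cpts(dag_new(list(A = c("s", "t"),
                                                B = c("x", "y")),
                                           list(c("A", "B"))), d0))
  expect_error(posterior(bn0, "A", list(B = "y")), "probability 0")
})

test_that("classification takes the posterior argmax with fixed-order ties", {
  set.seed(123)
  for (rep in 1:20) {
    bn <- random_bn(4, n_states = 3)
    nodes <- names(bn$dag$nodes)
    query <- sample(nodes, 1)
    ev_nodes <- sample(setdiff(nodes, query), 2)
    ev <- lapply(setNames(ev_nodes, ev_nodes), function(v) {
      sample(bn$dag$nodes[[v]], 1)
    })
    got <- classify(bn, query, ev)
    want <- posterior_bruteforce(bn, query, ev)
    expect_equal(got$label, names(want)[which.max(want)])
  }
  # deterministic toy net: evidence pins the class, posterior 1
  d <- data.frame(phase = c("a", "b"), att = c("x", "y"))
  bn <- fit_cpts(dag_new(list(phase = c("a", "b"), att = c("x", "y")),
                         list(c("phase", "att"))), d)
  res <- classify(bn, "phase", list(att = "x"))
  expect_equal(res$label, "a")
  expect_equal(unname(res$posterior["a"]), 1)
})

test_that("naive Bayes is the star network with the closed-form posterior", {
  set.seed(55)
  d <- data.frame(T = sample(c("p", "q", "r"), 60, replace = TRUE),
                  A1 = sample(c("x", "y"), 60, replace = TRUE),
                  A2 = sample(c("x", "y"), 60, replace = TRUE))
  nb <- naive_bayes(d, target = "T", alpha = 1)
  e <- dag_edges(nb$dag)
  expect_equal(nrow(e), 2)
  expect_true(all(e[, "from"] == "T"))

  # posterior proportional to P(T) prod_i P(Ai | T)
  ev <- list(A1 = "x", A2 = "y")
  got <- posterior(nb, "T", ev)
  pT <- as.numeric(nb$cpts$T)
  w <- pT * nb$cpts$A1["x", ] * nb$cpts$A2["y", ]
  expect_equal(as.numeric(got), unname(w / sum(w)), tolerance = 1e-12)
})

test_that("network JSON round-trip is exact", {
  set.seed(77)
  bn <- random_bn(4, n_states = 3)
  path <- tempfile(fileext = ".json")
  bn_to_json(bn, path)
  back <- bn_from_json(path)
  expect_equal(back$dag$nodes, bn$dag$nodes)
  expect_identical(dag_edges(back$dag), dag_edges(bn$dag))
  for (n in names(bn$cpts)) {
    expect_equal(back$cpts[[n]], bn$cpts[[n]], tolerance = 0)
  }
})

test_that("structure recovery: hill climbing finds the 5-node skeleton", {
  recovered <- 0
  for (s in 1:20) {
    truth <- truth_5node_bn(seed = 100 + s)
    dat <- sample_bn(truth, 500, seed = 200 + s)
    hc <- hill_climb(dat, score = "bic")
    if (identical(dag_skeleton(hc$dag), dag_skeleton(truth$dag))) {
      recovered <- recovered + 1
    }
  }
  expect_gte(recovered / 20, 0.8)
})
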
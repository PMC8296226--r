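#' Classification accuracy
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Matching fraction in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth have different lengths", call. = FALSE)
  }
  if (length(predicted) == 0) stop("empty label vectors", call. = FALSE)
  mean(as.character(predicted) == as.character(truth))
}

#' Classifier specification for holdout evaluation
#'
#' @param kind `"bn"` (structure learned by [hill_climb()] per training
#'   split, or once, per `relearn_structure`) or `"nb"` ([naive_bayes()]).
#' @param score Structure score for `kind = "bn"` (`"bic"` default).
#' @param alpha Laplace pseudo-count for CPT fitting (default 1; with 40
#'   training rows over up to 18 parent configurations, unsmoothed tables
#'   produce zero posteriors on held-out level combinations).
#' @param relearn_structure If `TRUE` (default) the BN structure is
#'   relearned inside every training split; if `FALSE` it is learned once
#'   on the first split's training rows and only CPTs are refit thereafter.
#' @param augment_target If `TRUE` (default), `kind = "bn"` learns an
#'   augmented-naive structure: the target is required as a parent of every
#'   attribute and hill climbing adds attribute--attribute edges on top.
#'   Generative structure scores do not target the class posterior, and on
#'   small training splits unrestricted search can leave attributes outside
#'   the target's Markov blanket, silently discarding their evidence; the
#'   augmented family guarantees every measured interaction informs the
#'   phase posterior while still learning inter-attribute structure. Set to
#'   `FALSE` for fully unrestricted structure learning.
#' @return List of class `or_classifier_spec`.
#' @export
classifier_spec <- function(kind = c("bn", "nb"), score = "bic", alpha = 1,
                            relearn_structure = TRUE, augment_target = TRUE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, score = score, alpha = alpha,
                 relearn_structure = relearn_structure,
                 augment_target = augment_target),
            class = "or_classifier_spec")
}

# Columns of a feature table holding continuous similarities.
sim_columns <- function(table) grep("_sim$", names(table), value = TRUE)

# Fit discretizers on training rows only and return train/test level data
# frames plus test-row missingness (NA similarity = absent role).
split_discretize <- function(table, train_idx) {
  sims <- sim_columns(table)
  if (length(sims) == 0) stop("feature table has no *_sim columns", call. = FALSE)
  lev_names <- sub("_sim$", "_level", sims)
  train <- data.frame(phase = factor(table$phase[train_idx], levels = levels(table$phase)))
  test_idx <- setdiff(seq_len(nrow(table)), train_idx)
  test <- data.frame(phase = factor(table$phase[test_idx], levels = levels(table$phase)))
  miss <- matrix(FALSE, length(test_idx), length(sims),
                 dimnames = list(NULL, lev_names))
  for (k in seq_along(sims)) {
    disc <- suppressWarnings(discretize_fit(table[[sims[k]]][train_idx]))
    train[[lev_names[k]]] <- discretize_apply(disc, table[[sims[k]]][train_idx])
    test[[lev_names[k]]] <- discretize_apply(disc, table[[sims[k]]][test_idx])
    miss[, k] <- is.na(table[[sims[k]]][test_idx])
  }
  list(train = train, test = test, test_missing = miss, test_idx = test_idx)
}

classifier_required_edges <- function(spec, train, target = "phase") {
  if (!isTRUE(spec$augment_target)) return(list())
  lapply(setdiff(names(train), target), function(a) c(target, a))
}

fit_classifier <- function(spec, train, fixed_dag = NULL) {
  states <- lapply(train, levels)
  if (spec$kind == "nb") {
    naive_bayes(train, target = "phase", alpha = spec$alpha, states = states)
  } else {
    dag <- fixed_dag
    if (is.null(dag)) {
      dag <- hill_climb(train, score = spec$score, states = states,
                        required = classifier_required_edges(spec, train))$dag
    }
    fit_cpts(dag, train, alpha = spec$alpha)
  }
}

predict_rows <- function(bn, test, test_missing) {
  attrs <- setdiff(names(test), "phase")
  vapply(seq_len(nrow(test)), function(i) {
    ev <- list()
    for (a in attrs) {
      if (!test_missing[i, a]) ev[[a]] <- as.character(test[[a]][i])
    }
    classify(bn, "phase", ev)$label
  }, character(1))
}

#' Repeated random holdout evaluation
#'
#' The validation protocol for interaction-based phase classification:
#' `n_reps` times, draw `n_train` rows uniformly without replacement as the
#' training set and use the remainder for validation. Inside every
#' repetition the tertile discretization boundaries, the network structure
#' (in relearn mode) and the CPTs are fitted on the training rows only --
#' no information from the validation rows leaks into the model. Accuracy
#' is the fraction of validation rows whose classified phase matches the
#' truth; absent-role attributes of a validation row are omitted from the
#' evidence.
#'
#' With the defaults (`n_train = 40`, `n_reps = 1000`) on an 83-row
#' feature table each repetition validates on the remaining 43 rows.
#'
#' @param table An [build_feature_table()] result (continuous `*_sim`
#'   columns plus `phase`).
#' @param n_train Training rows per repetition (default 40).
#' @param n_reps Number of repetitions (default 1000).
#' @param spec An [classifier_spec()].
#' @param seed Integer master seed; the whole report is reproducible from
#'   it.
#' @param split `"uniform"` (default; rows drawn uniformly without
#'   replacement, the plain random-division protocol), `"stratified"`
#'   (training rows drawn per phase in proportion to the phase's row count,
#'   with any remainder assigned to randomly chosen phases), or
#'   `"by_case"` (whole cases assigned to training until `n_train` rows are
#'   reached or exceeded; segments of one case are not independent, so this
#'   is the pessimistic grouping).
#' @param max_retries A training split missing an entire phase label is
#'   redrawn (with a message) up to this many times per repetition before
#'   erroring (default 100).
#' @return Object of class `or_evaluation`: `accuracies` (length
#'   `n_reps`), `mean`, `min`, `max`, `n_train`, `n_test`, `n_reps`,
#'   `spec`, `seed`, and `splits` (list of training index vectors, for
#'   paired comparisons).
#' @export
repeated_holdout <- function(table, n_train = 40, n_reps = 1000,
                             spec = classifier_spec("bn"), seed = 1,
                             split = c("uniform", "stratified", "by_case"),
                             max_retries = 100) {
  split <- match.arg(split)
  n <- nrow(table)
  if (n_train >= n) stop("n_train must be smaller than the row count", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  phases_all <- unique(as.character(table$phase))
  draw_split <- function() {
    switch(split,
           uniform = sort(sample.int(n, n_train)),
           stratified = {
             ph <- as.character(table$phase)
             per <- floor(n_train * table(ph) / n)
             extra <- n_train - sum(per)
             if (extra > 0) {
               bump <- sample(names(per), extra)
               per[bump] <- per[bump] + 1
             }
             idx <- unlist(lapply(names(per), function(p) {
               sample(which(ph == p), per[[p]])
             }))
             sort(idx)
           },
           by_case = {
             cases <- sample(unique(table$case_id))
             idx <- integer(0)
             for (cid in cases) {
               if (length(idx) >= n_train) break
               idx <- c(idx, which(table$case_id == cid))
             }
             sort(idx)
           })
  }
  set.seed(seed)
  accs <- numeric(n_reps)
  splits <- vector("list", n_reps)
  fixed_dag <- NULL
  for (rep in seq_len(n_reps)) {
    tries <- 0
    repeat {
      idx <- draw_split()
      if (length(idx) < n &&
          setequal(unique(as.character(table$phase[idx])), phases_all)) break
      tries <- tries + 1
      if (tries == 1) {
        message("repetition ", rep, ": redrawing split missing a phase label")
      }
      if (tries > max_retries) {
        stop("could not draw a training split covering every phase after ",
             max_retries, " retries", call. = FALSE)
      }
    }
    splits[[rep]] <- idx
    parts <- split_discretize(table, idx)
    if (spec$kind == "bn" && !spec$relearn_structure && is.null(fixed_dag)) {
      fixed_dag <- hill_climb(
        parts$train, score = spec$score,
        states = lapply(parts$train, levels),
        required = classifier_required_edges(spec, parts$train))$dag
    }
    bn <- fit_classifier(spec, parts$train, fixed_dag = fixed_dag)
    pred <- predict_rows(bn, parts$test, parts$test_missing)
    accs[rep] <- accuracy(pred, parts$test$phase)
  }
  structure(list(accuracies = accs, mean = mean(accs), min = min(accs),
                 max = max(accs), n_train = n_train, n_test = n - n_train,
                 n_reps = n_reps, spec = spec, seed = seed, splits = splits),
            class = "or_evaluation")
}

#' @export
print.or_evaluation <- function(x, ...) {
  cat(sprintf(
    "<or_evaluation> %s, %d reps of %d/%d train/test\n  accuracy mean %.3f, range [%.3f, %.3f]\n",
    x$spec$kind, x$n_reps, x$n_train, x$n_test, x$mean, x$min, x$max))
  # coarse textual histogram of the accuracy distribution
  h <- graphics::hist(x$accuracies, breaks = seq(0, 1, 0.05), plot = FALSE)
  top <- max(h$counts)
  if (top > 0) {
    for (i in which(h$counts > 0)) {
      cat(sprintf("  %.2f-%.2f %s %d\n", h$breaks[i], h$breaks[i + 1],
                  strrep("#", ceiling(20 * h$counts[i] / top)), h$counts[i]))
    }
  }
  invisible(x)
}

#' Compare classifiers on identical splits
#'
#' Runs [repeated_holdout()] for each spec with the same seed, so every
#' repetition uses the same training/validation split for all classifiers,
#' and reports paired accuracies and mean differences.
#'
#' @param table Feature table as in [repeated_holdout()].
#' @param specs Named list of [classifier_spec()]s (default a structure-
#'   learned BN vs naive Bayes).
#' @param n_train,n_reps,seed As in [repeated_holdout()].
#' @return List of class `or_comparison`: `reports` (named list of
#'   `or_evaluation`), `paired` (data.frame of per-rep accuracies), and
#'   `mean_diff` (matrix of pairwise mean accuracy differences).
#' @export
compare_classifiers <- function(table,
                                specs = list(bn = classifier_spec("bn"),
                                             nb = classifier_spec("nb")),
                                n_train = 40, n_reps = 1000, seed = 1) {
  if (length(specs) < 2) stop("need at least two classifier specs", call. = FALSE)
  reports <- lapply(specs, function(sp) {
    repeated_holdout(table, n_train = n_train, n_reps = n_reps, spec = sp,
                     seed = seed)
  })
  # identical seeds draw identical split sequences
  paired <- as.data.frame(lapply(reports, function(r) r$accuracies))
  k <- length(specs)
  mean_diff <- matrix(0, k, k, dimnames = list(names(specs), names(specs)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    mean_diff[i, j] <- reports[[i]]$mean - reports[[j]]$mean
  }
  structure(list(reports = reports, paired = paired, mean_diff = mean_diff),
            class = "or_comparison")
}

#' @export
print.or_comparison <- function(x, ...) {
  cat("<or_comparison>\n")
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-4s mean %.3f  range [%.3f, %.3f]\n", nm, r$mean, r$min,
                r$max))
  }
  invisible(x)
}
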
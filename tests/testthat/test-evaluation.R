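# Synthetic feature tables built directly (no movement simulation), for
# fast, controlled evaluation tests.

# Deterministic, perfectly separable table. Each column takes only the
# values 0.1 ("low") and 0.9 ("high"), with high phases in the minority so
# tertile boundaries always fall on or above 0.1 and every low/high
# contrast survives discretization; the four columns' high-phase sets
# ({1,2}, {3,4}, {1,3}, {1,5}) distinguish every pair of the six phases.
separable_table <- function(n_per_phase = 12) {
  phases <- or_phases()
  high_sets <- list(surg_scrub_sim = c(1, 2), asst_surg_sim = c(3, 4),
                    anes_asst_sim = c(1, 3), asst_scrub_sim = c(1, 5))
  idx <- rep(seq_along(phases), each = n_per_phase)
  tab <- data.frame(
    case_id = "c1", occurrence = 1,
    phase = factor(phases[idx], levels = phases))
  for (col in names(high_sets)) {
    tab[[col]] <- ifelse(idx %in% high_sets[[col]], 0.9, 0.1)
  }
  class(tab) <- c("or_feature_table", "data.frame")
  tab
}

# Balanced table with label-independent noise features.
chance_table <- function(n_per_phase = 13, seed = 1) {
  set.seed(seed)
  phases <- or_phases()
  n <- n_per_phase * 6
  tab <- data.frame(
    case_id = "c1", occurrence = 1,
    phase = factor(sample(rep(phases, each = n_per_phase)), levels = phases),
    surg_scrub_sim = runif(n), asst_surg_sim = runif(n),
    anes_asst_sim = runif(n), asst_scrub_sim = runif(n))
  class(tab) <- c("or_feature_table", "data.frame")
  tab
}

test_that("accuracy is the matching fraction", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(accuracy(c("a", "b", "c", "d"), c("a", "b", "c", "x")), 0.75)
  expect_error(accuracy("a", c("a", "b")), "different lengths")
})

test_that("holdout on a separable table is always perfect", {
  # n_train leaves every phase several training rows, so the Laplace
  # pseudo-counts cannot outweigh a deterministic fingerprint
  tab <- separable_table()
  for (spec in list(classifier_spec("bn"), classifier_spec("nb"))) {
    rep <- repeated_holdout(tab, n_train = 60, n_reps = 10, spec = spec,
                            seed = 2)
    expect_equal(rep$accuracies, rep(1, 10))
    expect_equal(rep$n_test, nrow(tab) - 60)
  }
})

test_that("holdout splits are disjoint, sized and reproducible", {
  tab <- chance_table(n_per_phase = 14, seed = 5)  # 84 rows
  r1 <- repeated_holdout(tab, n_train = 40, n_reps = 5,
                         spec = classifier_spec("nb"), seed = 9)
  r2 <- repeated_holdout(tab, n_train = 40, n_reps = 5,
                         spec = classifier_spec("nb"), seed = 9)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_identical(r1$splits, r2$splits)
  for (idx in r1$splits) {
    expect_length(idx, 40)
    expect_false(any(duplicated(idx)))
  }
  r3 <- repeated_holdout(tab, n_train = 40, n_reps = 5,
                         spec = classifier_spec("nb"), seed = 10)
  expect_false(identical(r1$splits, r3$splits))
})

test_that("discretization boundaries come from training rows only", {
  tab <- chance_table(seed = 7)
  idx <- 1:40
  parts <- orflow:::split_discretize(tab, idx)
  want <- suppressWarnings(discretize_fit(tab$surg_scrub_sim[idx]))
  got_level <- discretize_apply(want, tab$surg_scrub_sim[-(1:40)])
  expect_equal(parts$test$surg_scrub_level, got_level)

  # perturbing validation rows leaves the trained boundaries untouched
  tab2 <- tab
  tab2$surg_scrub_sim[-(1:40)] <- tab2$surg_scrub_sim[-(1:40)] + 100
  parts2 <- orflow:::split_discretize(tab2, idx)
  expect_identical(parts$train, parts2$train)
  expect_true(all(parts2$test$surg_scrub_level == "High"))
})

test_that("absent-role attributes are dropped from the evidence, not imputed", {
  tab <- separable_table()
  tab$surg_scrub_sim[tab$phase == "Preparation"] <- NA  # absent role
  rep <- repeated_holdout(tab, n_train = 42, n_reps = 5,
                          spec = classifier_spec("nb"), seed = 3)
  # the remaining columns still separate every phase, so accuracy stays 1
  expect_equal(rep$accuracies, rep(1, 5))
})

test_that("chance-level calibration on permuted balanced labels", {
  tab <- balanced_noise_table(n_per_phase = 13, seed = 11)
  accs <- chance_accuracies(tab, n_reps = 200, n_train = 36,
                            spec = classifier_spec("nb"), seed = 12)
  mc_se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 6), 3 * mc_se)
})

test_that("stratified and by-case splits honor their grouping", {
  tab <- chance_table(n_per_phase = 13, seed = 13)
  r <- suppressMessages(repeated_holdout(tab, n_train = 36, n_reps = 3,
                                         spec = classifier_spec("nb"),
                                         seed = 14, split = "stratified"))
  for (idx in r$splits) {
    expect_equal(unname(table(tab$phase[idx])), rep(6L, 6), ignore_attr = TRUE)
  }

  tab$case_id <- rep(paste0("c", 1:13), each = 6)
  rb <- suppressMessages(repeated_holdout(tab, n_train = 36, n_reps = 3,
                                          spec = classifier_spec("nb"),
                                          seed = 15, split = "by_case"))
  for (idx in rb$splits) {
    train_cases <- unique(tab$case_id[idx])
    test_cases <- unique(tab$case_id[-idx])
    expect_length(intersect(train_cases, test_cases), 0)
  }
})

test_that("splits covering all phases are enforced by retry, then error", {
  phases <- or_phases()
  tab <- data.frame(
    case_id = "c1", occurrence = 1,
    phase = factor(c(rep("TR", 8), phases[phases != "TR"]), levels = phases),
    surg_scrub_sim = runif(13))
  class(tab) <- c("or_feature_table", "data.frame")
  set.seed(21)
  expect_message(
    rep <- repeated_holdout(tab, n_train = 12, n_reps = 3,
                            spec = classifier_spec("nb"), seed = 22),
    "redrawing split")
  for (idx in rep$splits) {
    expect_setequal(unique(as.character(tab$phase[idx])), phases)
  }
  # 3 training rows can never cover 6 phases
  expect_error(
    suppressMessages(repeated_holdout(tab, n_train = 3, n_reps = 1,
                                      spec = classifier_spec("nb"), seed = 23,
                                      max_retries = 20)),
    "could not draw")
})

test_that("classifier comparison pairs identical splits", {
  tab <- chance_table(n_per_phase = 10, seed = 31)
  cmp <- suppressMessages(compare_classifiers(
    tab, specs = list(bn = classifier_spec("bn"), bn2 = classifier_spec("bn")),
    n_train = 30, n_reps = 5, seed = 32))
  expect_equal(cmp$mean_diff["bn", "bn2"], 0)
  expect_identical(cmp$reports$bn$splits, cmp$reports$bn2$splits)
  expect_identical(cmp$paired$bn, cmp$paired$bn2)
})

test_that("BN exploits attribute dependence that naive Bayes cannot", {
  # phase drives A; B copies A's level with small noise: strong
  # attribute-attribute dependence given the class
  set.seed(41)
  phases <- or_phases()
  n_per <- 20
  centers <- setNames(seq(0.08, 0.92, length.out = 6), phases)
  phase <- rep(phases, each = n_per)
  a <- centers[phase] + runif(length(phase), -0.05, 0.05)
  flip <- runif(length(phase)) < 0.15
  b <- ifelse(flip, runif(length(phase)), a + runif(length(phase), -0.03, 0.03))
  tab <- data.frame(case_id = "c1", occurrence = 1,
                    phase = factor(phase, levels = phases),
                    surg_scrub_sim = a, asst_scrub_sim = b)
  class(tab) <- c("or_feature_table", "data.frame")
  cmp <- suppressMessages(compare_classifiers(tab, n_train = 80, n_reps = 30,
                                              seed = 42))
  expect_gte(cmp$reports$bn$mean, cmp$reports$nb$mean - 0.02)
})
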
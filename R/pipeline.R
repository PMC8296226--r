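#' Pipeline configuration
#'
#' Bundles the stage configurations for a full simulate -> features ->
#' learn -> evaluate run.
#'
#' @param sim An [or_sim_config()].
#' @param lcss An [lcss_params()].
#' @param pairs Named list of role pairs (default [default_pairs()]).
#' @param n_cases,target_segments Dataset size (defaults 10 cases, 83
#'   segments).
#' @param score Structure score (`"bic"` or `"loglik"`).
#' @param n_train,n_reps Holdout protocol (defaults 40 training rows, 1000
#'   repetitions).
#' @param seed Master seed for the whole pipeline.
#' @return List of class `or_pipeline_config`.
#' @export
pipeline_config <- function(sim = or_sim_config(), lcss = lcss_params(),
                            pairs = default_pairs(), n_cases = 10,
                            target_segments = 83, score = "bic",
                            n_train = 40, n_reps = 1000, seed = 7) {
  structure(list(sim = sim, lcss = lcss, pairs = pairs, n_cases = n_cases,
                 target_segments = target_segments, score = score,
                 n_train = n_train, n_reps = n_reps, seed = seed),
            class = "or_pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates a dataset, writes the track and phase CSVs, builds the
#' feature table, learns a full-data network (structure + CPTs), runs the
#' repeated-holdout comparison of the structure-learned network against
#' naive Bayes, and writes every artifact plus a resolved-config snapshot
#' into `out_dir`. Rerunning with the same config is bit-identical.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param log Function used for progress lines (default `message`;
#'   pass `function(...) {}` to silence).
#' @return Named list of artifact paths, invisibly; the evaluation
#'   comparison is returned in the `"comparison"` element.
#' @export
run_pipeline <- function(config, out_dir, log = message) {
  stopifnot(inherits(config, "or_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  log("stage simulate: ", config$n_cases, " case(s), seed ", config$seed)
  dataset <- stage("simulate", generate_dataset(
    config$sim, n_cases = config$n_cases, seed = config$seed,
    target_segments = config$target_segments))
  stage("simulate", write_dataset(dataset, out_dir))

  log("stage features: LCSS eps ", config$lcss$eps, " mm, delta ",
      config$lcss$delta)
  table <- stage("features", build_feature_table(
    dataset, params = config$lcss, selected_pairs = config$pairs,
    discretize = TRUE, resample_first = FALSE))
  features_csv <- file.path(out_dir, "features.csv")
  stage("features", write_feature_table(table, features_csv))

  log("stage learn: full-data network, score ", config$score)
  net <- stage("learn", {
    lev <- data.frame(phase = table$phase)
    for (col in grep("_level$", names(table), value = TRUE)) {
      lev[[col]] <- table[[col]]
    }
    fit <- hill_climb(lev, score = config$score)
    fit_cpts(fit$dag, lev, alpha = 1)
  })
  net_json <- file.path(out_dir, "network.json")
  stage("learn", bn_to_json(net, net_json))

  log("stage evaluate: ", config$n_reps, " reps of ", config$n_train, "/",
      nrow(table) - config$n_train)
  cmp <- stage("evaluate", compare_classifiers(
    table, n_train = config$n_train, n_reps = config$n_reps,
    seed = config$seed))
  report <- list(
    bn = unclass(cmp$reports$bn)[c("mean", "min", "max", "n_train", "n_test", "n_reps")],
    nb = unclass(cmp$reports$nb)[c("mean", "min", "max", "n_train", "n_test", "n_reps")],
    mean_diff_bn_minus_nb = cmp$mean_diff["bn", "nb"],
    seed = config$seed)
  report_json <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_json, auto_unbox = TRUE, digits = NA)
  acc_csv <- file.path(out_dir, "accuracies.csv")
  write.csv(cmp$paired, acc_csv, row.names = FALSE)

  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(resolved_config(config), cfg_json, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(tracks = file.path(out_dir, "tracks.csv"),
                 phases = file.path(out_dir, "phases.csv"),
                 ground_truth = file.path(out_dir, "ground_truth.json"),
                 features = features_csv, network = net_json,
                 report = report_json, accuracies = acc_csv,
                 config = cfg_json, comparison = cmp))
}

# Plain-list snapshot of a pipeline config for the provenance JSON.
resolved_config <- function(config) {
  list(
    sim = lapply(unclass(config$sim), function(x) {
      if (is.data.frame(x)) x else as.list(x)
    }),
    lcss = unclass(config$lcss),
    pairs = config$pairs,
    n_cases = config$n_cases, target_segments = config$target_segments,
    score = config$score, n_train = config$n_train, n_reps = config$n_reps,
    seed = config$seed)
}
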
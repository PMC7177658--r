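#' Configure a full recognition experiment
#'
#' Bundles the pieces of the end-to-end study: where the trajectories come
#' from (the built-in simulator or NGSIM-style CSV files), the risk
#' parameters, the dataset definitions (feature channels + threshold method,
#' mirroring the five benchmark datasets), the algorithm list, and the CV
#' geometry. Defaults reproduce the synthetic benchmark: 299 drivers with a
#' 14.4% aggressive minority and the five channel/threshold combinations.
#'
#' @param source `"synthetic"` or `"files"`.
#' @param trajectory_path,unit_system For `source = "files"`: CSV path and
#'   its unit system.
#' @param sim A [sim_config()] (synthetic source).
#' @param risk A [risk_params()].
#' @param datasets Named list; each element is
#'   `list(channels = ..., threshold = "kmeans"|"iqr"|"percentile",
#'   percentile = X)`.
#' @param algorithms Character vector drawn from [ALGORITHMS].
#' @param rounds,tree_depth Model size passed to every algorithm.
#' @param folds,repeats CV geometry.
#' @param grid Optional hyperparameter grid for [grid_search()].
#' @param min_duration,lane_ids Episode-extraction settings (file source).
#' @param seed Master seed; all stage seeds derive from it.
#' @param outdir Output directory, or `NULL` to skip writing artefacts.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(source = c("synthetic", "files"),
                              trajectory_path = NULL,
                              unit_system = "metric",
                              sim = sim_config(),
                              risk = risk_params(),
                              datasets = default_datasets(),
                              algorithms = c("adaboost", "xgboost",
                                             "smoteboost", "rusboost",
                                             "cusboost"),
                              rounds = 30, tree_depth = 2,
                              folds = 5, repeats = 5,
                              grid = NULL,
                              min_duration = 10, lane_ids = NULL,
                              seed = 1L, outdir = NULL) {
  source <- match.arg(source)
  bad <- setdiff(algorithms, ALGORITHMS)
  if (length(bad)) {
    stop_acr("unknown algorithm(s): ", paste(bad, collapse = ", "),
             class = "acr_config_error")
  }
  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    if (is.null(ds$channels) || is.null(ds$threshold) ||
        !ds$threshold %in% c("kmeans", "iqr", "percentile")) {
      stop_acr("dataset '", nm, "' must name channels and a threshold method",
               class = "acr_config_error")
    }
  }
  structure(list(source = source, trajectory_path = trajectory_path,
                 unit_system = unit_system, sim = sim, risk = risk,
                 datasets = datasets, algorithms = algorithms,
                 rounds = rounds, tree_depth = tree_depth,
                 folds = folds, repeats = repeats, grid = grid,
                 min_duration = min_duration, lane_ids = lane_ids,
                 seed = as.integer(seed), outdir = outdir),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @export
default_datasets <- function() {
  list(
    dataset1 = list(channels = c("speed", "acceleration"), threshold = "kmeans"),
    dataset2 = list(channels = "gap", threshold = "kmeans"),
    dataset3 = list(channels = c("gap", "speed", "acceleration"),
                    threshold = "kmeans"),
    dataset4 = list(channels = c("gap", "speed", "acceleration"),
                    threshold = "iqr"),
    dataset5 = list(channels = c("gap", "speed", "acceleration"),
                    threshold = "percentile", percentile = 94))
}

#' Load an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]; `sim` and
#' `risk` sub-maps are passed to [sim_config()] / [risk_params()].
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file is read.
#' @return An `experiment_config`.
#' @export
load_experiment_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  args <- list(...)
  for (nm in names(args)) raw[[nm]] <- args[[nm]]
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$risk)) raw$risk <- do.call(risk_params, raw$risk)
  if (!is.null(raw$datasets)) {
    raw$datasets <- lapply(raw$datasets, function(d) {
      d$channels <- unlist(d$channels)
      d
    })
  }
  do.call(experiment_config, raw)
}

# Cheap deterministic content hash for run manifests (hex string).
config_hash <- function(config) {
  s <- utf8ToInt(paste(deparse(config[setdiff(names(config), "outdir")]),
                       collapse = ""))
  h <- 17
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full aggressive-driver recognition experiment
#'
#' Executes the pipeline end to end: obtain episodes (simulate, or read and
#' extract from files), compute per-driver ACR, derive each dataset's
#' threshold and labels, build DFT feature matrices, cross-validate every
#' algorithm, and assemble one summary table per dataset
#' (algorithm x precision/recall/F1/AUPRC). Deterministic from the master
#' seed. When `outdir` is set, labels, features, per-fold metrics, summary
#' tables and a run manifest are written as CSV/YAML.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress progress messages (stderr)?
#' @return Object of class `experiment_report`: `tables` (named list of
#'   summary data frames), `thresholds`, `labels`, `acr`,
#'   `leader_follower_r`, `truth_auc` (when ground truth exists), `config`.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_acr("stage '", name, "' failed: ", conditionMessage(e),
               class = "acr_pipeline_error")
    })
  }

  truth <- NULL
  if (config$source == "synthetic") {
    say("simulating platoon of ", config$sim$n_drivers, " drivers (seed ",
        config$sim$seed, ")")
    platoon <- stage("simulate", {
      profiles <- sample_population(config$sim)
      simulate_platoon(profiles, config$sim)
    })
    episodes <- platoon$episodes
    truth <- platoon$truth
  } else {
    say("reading trajectories from ", config$trajectory_path)
    episodes <- stage("extract", {
      rec <- read_trajectory_table(config$trajectory_path,
                                   unit_system = config$unit_system)
      extract_episodes(rec, min_duration = config$min_duration,
                       lane_ids = config$lane_ids)
    })
  }
  say(length(episodes), " car-following episodes")

  acr <- stage("risk", acr_table(episodes, config$risk,
                                 aggregate_followers = TRUE))
  lf <- tryCatch(leader_follower_correlation(
    data.frame(driver_id = acr$follower_id, acr = acr$acr), episodes),
    error = function(e) NULL)
  truth_auc <- if (!is.null(truth)) {
    m <- match(acr$follower_id, truth$driver_id)
    rank_auc(acr$acr, truth$is_aggressive[m])
  } else NA_real_

  thresholds <- list(); labels <- list(); tables <- list()
  for (nm in names(config$datasets)) {
    ds <- config$datasets[[nm]]
    thr <- stage("threshold", switch(ds$threshold,
      kmeans = kmeans_threshold(acr$acr),
      iqr = iqr_threshold(acr$acr),
      percentile = percentile_threshold(acr$acr, ds$percentile %||% 94)))
    lab <- stage("label", label_drivers(acr, thr, truth = truth))
    say(sprintf("%s: %s threshold %.4f s -> %.1f%% aggressive (%.1f:1), channels %s",
                nm, ds$threshold, thr$threshold,
                100 * attr(lab, "minority_fraction"),
                attr(lab, "imbalance_ratio"),
                paste(ds$channels, collapse = "+")))
    fm <- stage("featurize", build_feature_matrix(episodes, lab,
                                                  channels = ds$channels))
    res <- lapply(config$algorithms, function(alg) {
      say("  evaluating ", alg)
      spec <- model_spec(alg, rounds = config$rounds,
                         tree_depth = config$tree_depth)
      rep <- stage(paste0("evaluate:", alg),
                   repeated_stratified_cv(fm, spec, folds = config$folds,
                                          repeats = config$repeats,
                                          seed = child_seed(config$seed,
                                                            match(nm, names(config$datasets))),
                                          grid = config$grid))
      c(algorithm = alg, as.list(rep$summary))
    })
    tab <- do.call(rbind, lapply(res, as.data.frame))
    thresholds[[nm]] <- thr; labels[[nm]] <- lab; tables[[nm]] <- tab
  }

  report <- structure(list(tables = tables, thresholds = thresholds,
                           labels = labels, acr = acr,
                           leader_follower_r = lf, truth_auc = truth_auc,
                           config = config, hash = config_hash(config)),
                      class = "experiment_report")
  if (!is.null(config$outdir)) write_experiment(report, config$outdir)
  report
}

# Area under the ROC of a score against a binary truth (rank statistic).
rank_auc <- function(score, truth) {
  truth <- as.logical(truth)
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

write_experiment <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$acr, file.path(outdir, "acr_table.csv"),
                   row.names = FALSE)
  for (nm in names(report$tables)) {
    utils::write.csv(report$tables[[nm]],
                     file.path(outdir, paste0("summary_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report$labels[[nm]]),
                     file.path(outdir, paste0("labels_", nm, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    hash = report$hash,
    seed = report$config$seed,
    thresholds = lapply(report$thresholds, `[[`, "threshold"),
    imbalance_ratio = lapply(report$labels, attr, "imbalance_ratio"),
    leader_follower_r = report$leader_follower_r$r,
    truth_auc = report$truth_auc)
  yaml::write_yaml(manifest, file.path(outdir, "run_manifest.yaml"))
  invisible(outdir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d dataset(s), seed %d, config %s\n",
              length(x$tables), x$config$seed, x$hash))
  for (nm in names(x$tables)) {
    cat("\n", nm, " (threshold ", sprintf("%.4f", x$thresholds[[nm]]$threshold),
        " s, ", sprintf("%.1f", attr(x$labels[[nm]], "imbalance_ratio")),
        ":1):\n", sep = "")
    print(x$tables[[nm]], digits = 3, row.names = FALSE)
  }
  invisible(x)
}
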
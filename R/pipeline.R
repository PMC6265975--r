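# End-to-end runner: synth/load -> annotate -> segment -> features ->
# select + evaluate, with report artifacts. Every artifact embeds the seed
# and a hash of the resolved configuration so a run can be replayed.

#' Default pipeline configuration
#'
#' @return nested list understood by [run_pipeline()]; any subset can be
#'   overridden via a YAML file or the `override` argument.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "eegstress_run",
    data_dir = NULL,            # NULL -> generate a synthetic cohort
    methods = c("all", "pca", "ga"),
    n_segments = 16L,
    synth = list(n_participants = 3L, trials_per_participant = 12L,
                 channel_names = c("Fp1", "Fp2", "F3", "F4",
                                   "C3", "C4", "O1", "O2"),
                 samples_per_trial = 2048L, fs = 128),
    ga = list(population_size = 24L, n_generations = 40L),
    knn = list(n_neighbors = 5L),
    pca_variance_threshold = 0.95
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a run configuration from YAML
#' @param path YAML file; keys override [default_run_config()].
#' @return resolved configuration list.
#' @export
read_run_config <- function(path) {
  merge_config(default_run_config(), yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  # order-stable digest of the resolved config; no external digest package
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_along(utf8ToInt(as.character(s))) %% 997)) %%
            .Machine$integer.max)
}

#' Run the full stress-classification pipeline
#'
#' Stages: obtain trials and ratings (from `data_dir` or the synthetic
#' generator), annotate and select participants, segment, extract the
#' feature bank, then evaluate every requested method under k-fold
#' validation. Writes `labels.csv`, `exclusions.json`, `features.csv`,
#' `per_participant.csv` (participant x method accuracies),
#' `summary.csv` (method means) and `report.json` into `out_dir`.
#'
#' @param cfg configuration list (see [default_run_config()]) or a YAML
#'   path.
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- merge_config(default_run_config(), cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(cfg$data_dir)) {
    cohort <- generate_cohort(do.call(synth_config,
                                      c(cfg$synth, list(seed = cfg$seed))))
    trials <- cohort$trials
    ratings <- cohort$ratings
  } else {
    layout <- deap_channel_layout()
    mf <- file.path(cfg$data_dir, "manifest.json")
    if (file.exists(mf)) {
      layout <- jsonlite::read_json(mf, simplifyVector = TRUE)$channel_names
    }
    trials <- read_trials(cfg$data_dir, layout = layout)
    ratings <- read_ratings(file.path(cfg$data_dir, "ratings.csv"))
  }

  ann <- annotate_ratings(ratings)
  utils::write.csv(ann[, c("participant_id", "trial_id", "label")],
                   file.path(cfg$out_dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  parts <- select_participants(ann)
  jsonlite::write_json(parts, file.path(cfg$out_dir, "exclusions.json"),
                       auto_unbox = FALSE)
  trials <- Filter(function(t) t$participant_id %in% parts$included, trials)

  segs <- segment_cohort(trials, ann, cfg$n_segments)
  fm <- extract_features(segs)
  write_feature_matrix(fm, file.path(cfg$out_dir, "features.csv"))

  report <- run_experiment(
    fm, methods = cfg$methods, k_folds = 3L, seed = cfg$seed,
    knn_cfg = do.call(knn_config, cfg$knn),
    ga_cfg = do.call(ga_config, cfg$ga),
    pca_variance_threshold = cfg$pca_variance_threshold)

  wide <- stats::reshape(report$per_participant, idvar = "participant_id",
                         timevar = "method", direction = "wide")
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  utils::write.csv(wide, file.path(cfg$out_dir, "per_participant.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(method = names(report$mean_accuracy),
               mean_accuracy = as.numeric(report$mean_accuracy)),
    file.path(cfg$out_dir, "summary.csv"), row.names = FALSE, quote = FALSE)

  out <- list(seed = cfg$seed, config_hash = config_hash(cfg),
              included = parts$included, excluded = parts$excluded,
              n_segments_total = nrow(fm$values),
              n_features = ncol(fm$values),
              per_participant = report$per_participant,
              mean_accuracy = as.list(report$mean_accuracy))
  jsonlite::write_json(out, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
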
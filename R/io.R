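# Containers and file formats: EEG trials, ratings tables, feature matrices.
#
# Trial matrices are stored channels x samples. Two on-disk layouts are
# supported: one headerless CSV per trial (rows = channels), and a packed
# little-endian binary container per participant for speed. Sample indexing
# is 0-based and all sample intervals are half-open.

#' Default 32-electrode channel layout
#'
#' Electrode labels in the Geneva ordering used by the DEAP preprocessed
#' matrices: Fp1 is channel 1 and Fp2 is channel 17 (1-based). The layout is
#' an argument everywhere it is consumed, so other montages can be supplied.
#'
#' @return character vector of 32 electrode labels (10-20 system).
#' @export
deap_channel_layout <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' Construct an EEG trial
#'
#' @param data numeric matrix, channels x samples (microvolt scale).
#' @param participant_id character scalar.
#' @param trial_id integer scalar.
#' @param channel_names unique electrode labels, one per row of `data`.
#' @param sampling_rate_hz positive sampling rate.
#' @return object of class `eeg_trial`.
#' @export
trial <- function(data, participant_id, trial_id, channel_names,
                  sampling_rate_hz = 128) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L) {
    abort("trial data must be a numeric matrix with >= 1 channel row",
          "eegstress_format_error")
  }
  if (length(channel_names) != nrow(data)) {
    abort(sprintf("layout has %d channels but matrix has %d rows",
                  length(channel_names), nrow(data)),
          "eegstress_layout_error")
  }
  if (anyDuplicated(channel_names)) {
    abort("channel names must be unique", "eegstress_layout_error")
  }
  if (!is_scalar_number(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("sampling_rate_hz must be a positive number", "eegstress_format_error")
  }
  rownames(data) <- channel_names
  structure(list(participant_id = as.character(participant_id),
                 trial_id = as.integer(trial_id),
                 data = data,
                 channel_names = as.character(channel_names),
                 sampling_rate_hz = as.numeric(sampling_rate_hz)),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> participant %s trial %d: %d channels x %d samples @ %g Hz\n",
              x$participant_id, x$trial_id, nrow(x$data), ncol(x$data),
              x$sampling_rate_hz))
  invisible(x)
}

trial_filename <- function(participant_id, trial_id) {
  sprintf("%s_trial%02d.csv", participant_id, trial_id)
}

parse_trial_filename <- function(fn) {
  m <- regmatches(fn, regexec("^(.+)_trial([0-9]+)\\.csv$", fn))[[1]]
  if (length(m) != 3L) return(NULL)
  list(participant_id = m[2], trial_id = as.integer(m[3]))
}

#' Read EEG trials from a directory
#'
#' Reads every `<participant>_trial<NN>.csv` (headerless CSV, rows = channels)
#' and every `<participant>.eegbin` packed container in `path`. Channel names
#' are attached from `layout`; a file whose row count differs from the layout
#' is rejected, never truncated.
#'
#' @param path directory containing trial files.
#' @param layout character vector of electrode labels, see
#'   [deap_channel_layout()].
#' @param sampling_rate_hz sampling rate recorded on each trial.
#' @return list of [trial()] objects (empty, with a warning, if the directory
#'   holds no trial files).
#' @export
read_trials <- function(path, layout = deap_channel_layout(),
                        sampling_rate_hz = 128) {
  if (!dir.exists(path)) {
    abort(sprintf("trial directory not found: %s", path), "eegstress_io_error")
  }
  csvs <- sort(list.files(path, pattern = "_trial[0-9]+\\.csv$"))
  bins <- sort(list.files(path, pattern = "\\.eegbin$"))
  if (length(csvs) == 0L && length(bins) == 0L) {
    warning("no trial files found in ", path)
    return(list())
  }
  trials <- list()
  for (fn in csvs) {
    meta <- parse_trial_filename(fn)
    mat <- tryCatch(
      as.matrix(utils::read.csv(file.path(path, fn), header = FALSE)),
      warning = function(w) abort(sprintf("malformed trial file %s: %s",
                                          fn, conditionMessage(w)),
                                  "eegstress_format_error"))
    if (!is.numeric(mat) || anyNA(mat)) {
      abort(sprintf("malformed trial file %s: non-numeric or ragged rows", fn),
            "eegstress_format_error")
    }
    if (nrow(mat) != length(layout)) {
      abort(sprintf("%s: %d rows but layout has %d channels",
                    fn, nrow(mat), length(layout)),
            "eegstress_layout_error")
    }
    trials[[length(trials) + 1L]] <-
      trial(mat, meta$participant_id, meta$trial_id, layout, sampling_rate_hz)
  }
  for (fn in bins) {
    pid <- sub("\\.eegbin$", "", fn)
    trials <- c(trials, read_trials_bin(file.path(path, fn), pid, layout,
                                        sampling_rate_hz))
  }
  trials
}

# Packed binary container: int32 magic 0x45454731 ("EEG1"), int32 n_trials,
# n_channels, n_samples, then n_trials int32 trial ids, then doubles in trial
# order, each trial stored column-major (channels fastest).
write_trials_bin <- function(trials, path) {
  stopifnot(length(trials) > 0L)
  nc <- nrow(trials[[1]]$data); ns <- ncol(trials[[1]]$data)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(0x45454731L, length(trials), nc, ns), con, size = 4L,
           endian = "little")
  writeBin(vapply(trials, function(t) t$trial_id, integer(1)), con,
           size = 4L, endian = "little")
  for (t in trials) {
    stopifnot(nrow(t$data) == nc, ncol(t$data) == ns)
    writeBin(as.vector(t$data), con, size = 8L, endian = "little")
  }
  invisible(path)
}

read_trials_bin <- function(path, participant_id, layout,
                            sampling_rate_hz = 128) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, integer(), n = 4L, size = 4L, endian = "little")
  if (length(hdr) != 4L || hdr[1] != 0x45454731L) {
    abort(sprintf("%s: not a packed trial container", path),
          "eegstress_format_error")
  }
  if (hdr[3] != length(layout)) {
    abort(sprintf("%s: %d channels but layout has %d", path, hdr[3],
                  length(layout)),
          "eegstress_layout_error")
  }
  ids <- readBin(con, integer(), n = hdr[2], size = 4L, endian = "little")
  lapply(seq_len(hdr[2]), function(i) {
    mat <- matrix(readBin(con, double(), n = hdr[3] * hdr[4], size = 8L,
                          endian = "little"),
                  nrow = hdr[3])
    trial(mat, participant_id, ids[i], layout, sampling_rate_hz)
  })
}

#' Read an arousal/valence ratings table
#'
#' @param path CSV with header `participant_id,trial_id,arousal,valence`.
#'   Ratings are self-assessment scores on 1-9 scales.
#' @return validated data.frame, class `ratings_table`.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ratings_table(df)
}

#' Validate a ratings table
#'
#' @param df data.frame with columns participant_id, trial_id, arousal,
#'   valence; keys must be unique and ratings within \[1, 9\].
#' @return the validated data.frame with class `ratings_table` prepended.
#' @export
ratings_table <- function(df) {
  need <- c("participant_id", "trial_id", "arousal", "valence")
  if (!all(need %in% names(df))) {
    abort(paste("ratings table must have columns", paste(need, collapse = ", ")),
          "eegstress_format_error")
  }
  if (any(df$arousal < 1 | df$arousal > 9 | df$valence < 1 | df$valence > 9,
          na.rm = FALSE) || anyNA(df$arousal) || anyNA(df$valence)) {
    abort("ratings must lie in [1, 9]", "eegstress_validation_error")
  }
  if (anyDuplicated(df[, c("participant_id", "trial_id")])) {
    abort("duplicate (participant_id, trial_id) key", "eegstress_validation_error")
  }
  df$participant_id <- as.character(df$participant_id)
  df$trial_id <- as.integer(df$trial_id)
  class(df) <- c("ratings_table", "data.frame")
  df
}

#' Write a ratings table
#' @param ratings a `ratings_table`.
#' @param path output CSV path.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(as.data.frame(ratings)[, c("participant_id", "trial_id",
                                              "arousal", "valence")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

feature_families <- c("statistical", "bandpower", "hoc", "hjorth", "asymmetry")

#' Construct a feature matrix
#'
#' Rows are labeled segments, columns are named features tagged with one of
#' the five feature families.
#'
#' @param values numeric matrix, segments x features; must be finite.
#' @param feature_names unique column names.
#' @param feature_types one of statistical, bandpower, hoc, hjorth, asymmetry
#'   per column.
#' @param segment_keys data.frame with participant_id, trial_id,
#'   segment_index (0-based) per row.
#' @param labels optional character vector in \{calm, stress\} per row.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_names, feature_types, segment_keys,
                           labels = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != length(feature_names) ||
      length(feature_names) != length(feature_types)) {
    abort("feature names/types must align with value columns",
          "eegstress_shape_error")
  }
  if (anyDuplicated(feature_names)) {
    abort("feature names must be unique", "eegstress_format_error")
  }
  if (!all(feature_types %in% feature_families)) {
    abort("unknown feature type tag", "eegstress_format_error")
  }
  if (nrow(values) > 0 && !all(is.finite(values))) {
    abort("feature values must be finite", "eegstress_validation_error")
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(values), all(labels %in% c("calm", "stress")))
  }
  stopifnot(nrow(segment_keys) == nrow(values))
  colnames(values) <- feature_names
  structure(list(values = values,
                 feature_names = as.character(feature_names),
                 feature_types = as.character(feature_types),
                 segment_keys = as.data.frame(segment_keys),
                 labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$feature_types)),
                            as.integer(table(x$feature_types))),
                    collapse = ", ")))
  invisible(x)
}

#' Write a feature matrix to CSV
#'
#' Layout: a types header line (`#types,...`), an optional label line is not
#' needed because labels travel as an ordinary column; then a standard CSV
#' with key columns participant_id, trial_id, segment_index, label and one
#' column per feature at full double precision.
#'
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @export
write_feature_matrix <- function(fm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#types,", paste(fm$feature_types, collapse = ",")), con)
  labels <- if (is.null(fm$labels)) rep(NA_character_, nrow(fm$values)) else fm$labels
  df <- cbind(fm$segment_keys[, c("participant_id", "trial_id", "segment_index")],
              label = labels,
              as.data.frame(fm$values, check.names = FALSE))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path input path.
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path, n = 1L)
  if (length(lines) == 0L || !startsWith(lines[1], "#types,")) {
    abort(sprintf("%s: missing #types header line", path),
          "eegstress_format_error")
  }
  types <- strsplit(sub("^#types,", "", lines[1]), ",", fixed = TRUE)[[1]]
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE,
                        stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  keycols <- c("participant_id", "trial_id", "segment_index", "label")
  if (!all(keycols %in% names(df)[1:4])) {
    abort(sprintf("%s: malformed feature matrix header", path),
          "eegstress_format_error")
  }
  featcols <- setdiff(names(df), keycols)
  if (length(featcols) != length(types)) {
    abort(sprintf("%s: %d type tags for %d feature columns", path,
                  length(types), length(featcols)),
          "eegstress_format_error")
  }
  labels <- df$label
  if (all(is.na(labels))) labels <- NULL else labels <- as.character(labels)
  vals <- as.matrix(df[, featcols, drop = FALSE])
  if (nrow(vals) == 0L) {
    # preserve numeric mode on the empty round trip
    storage.mode(vals) <- "double"
  }
  feature_matrix(vals, featcols, types,
                 df[, c("participant_id", "trial_id", "segment_index"),
                    drop = FALSE],
                 labels)
}
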
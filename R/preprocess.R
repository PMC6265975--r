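# Annotation and segmentation.
#
# A trial is labeled from its arousal/valence self-assessment: calm when
# arousal < 4 and 4 < valence < 6, stress when arousal > 5 and valence < 3.
# All inequalities are strict, so boundary ratings stay unlabeled; the two
# regions are disjoint (arousal < 4 vs > 5). Participants that lack either
# class are excluded from classification.

#' Label a trial calm/stress from its ratings
#'
#' @param arousal,valence self-assessment scores in \[1, 9\].
#' @return `"calm"`, `"stress"`, or `"unlabeled"`.
#' @export
label_trial <- function(arousal, valence) {
  stopifnot(arousal >= 1, arousal <= 9, valence >= 1, valence <= 9)
  if (arousal < 4 && valence > 4 && valence < 6) return("calm")
  if (arousal > 5 && valence < 3) return("stress")
  "unlabeled"
}

#' Annotate a ratings table
#'
#' @param ratings a `ratings_table`.
#' @return the table with a `label` column appended.
#' @export
annotate_ratings <- function(ratings) {
  ratings$label <- mapply(label_trial, ratings$arousal, ratings$valence)
  ratings
}

#' Select participants exhibiting both classes
#'
#' A participant enters the experiment only with at least one calm and at
#' least one stress trial; others cannot supply both classes to a classifier.
#'
#' @param annotated ratings table with a `label` column
#'   (see [annotate_ratings()]).
#' @return list with `included` and `excluded` participant id vectors.
#' @export
select_participants <- function(annotated) {
  stopifnot("label" %in% names(annotated))
  tab <- table(annotated$participant_id, factor(annotated$label,
                                                levels = c("calm", "stress", "unlabeled")))
  ok <- tab[, "calm"] >= 1 & tab[, "stress"] >= 1
  included <- rownames(tab)[ok]
  excluded <- rownames(tab)[!ok]
  if (length(excluded)) {
    message("excluding participants without both classes: ",
            paste(excluded, collapse = ", "))
  }
  list(included = included, excluded = excluded)
}

#' Split a labeled trial into equal contiguous segments
#'
#' An 8064-sample trial at 128 Hz yields 16 windows of 504 samples (~4 s)
#' each, left to right. When the trial length is not divisible the tail
#' remainder is dropped with a warning; segments are never resized.
#'
#' @param tr an [trial()] object.
#' @param label `"calm"` or `"stress"` (one rating per trial, inherited by
#'   every segment).
#' @param n_segments number of windows (default 16).
#' @return list of `labeled_segment` objects, each holding a channels x w
#'   matrix (`w = floor(n_samples / n_segments)`), the label, and provenance
#'   (participant, trial, 0-based segment index).
#' @export
segment_trial <- function(tr, label, n_segments = 16L) {
  stopifnot(inherits(tr, "eeg_trial"), n_segments >= 1L)
  if (!label %in% c("calm", "stress")) {
    abort("trial must be labeled calm or stress before segmentation",
          "eegstress_precondition_error")
  }
  ns <- ncol(tr$data)
  if (ns < n_segments) {
    abort("trial shorter than the number of segments",
          "eegstress_precondition_error")
  }
  w <- ns %/% n_segments
  rem <- ns - w * n_segments
  if (rem > 0L) {
    warning(sprintf("trial %s/%d: dropping %d trailing samples (%d %% %d)",
                    tr$participant_id, tr$trial_id, rem, ns, n_segments))
  }
  lapply(seq_len(n_segments) - 1L, function(i) {
    structure(list(data = tr$data[, (i * w + 1L):((i + 1L) * w), drop = FALSE],
                   label = label,
                   participant_id = tr$participant_id,
                   trial_id = tr$trial_id,
                   segment_index = i,
                   channel_names = tr$channel_names,
                   sampling_rate_hz = tr$sampling_rate_hz),
              class = "labeled_segment")
  })
}

#' Segment every labeled trial of a cohort
#'
#' @param trials list of [trial()] objects.
#' @param annotated annotated ratings table; trials labeled `unlabeled` are
#'   skipped.
#' @param n_segments windows per trial.
#' @return flat list of `labeled_segment`s.
#' @export
segment_cohort <- function(trials, annotated, n_segments = 16L) {
  key <- paste(annotated$participant_id, annotated$trial_id)
  out <- list()
  for (tr in trials) {
    i <- match(paste(tr$participant_id, tr$trial_id), key)
    if (is.na(i) || annotated$label[i] == "unlabeled") next
    out <- c(out, segment_trial(tr, annotated$label[i], n_segments))
  }
  out
}
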
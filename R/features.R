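# Per-segment feature bank: five families widely used in EEG affect work.
#
# On a 32-channel segment with the default configuration (7 bands, HOC order
# 5) the bank has 673 named columns: 6*32 statistical, 7*32 band power,
# 5*32 higher-order crossings, 3*32 Hjorth, and 1 frontal alpha asymmetry.

#' Six time-domain statistical features of one channel
#'
#' Mean; population (1/N) standard deviation; mean absolute first difference
#' (1/(N-1)); the same normalized by the standard deviation; mean absolute
#' second difference `|x(n+2) - x(n)|` (1/(N-2)); and its normalized form.
#' On a constant channel the standard deviation is 0 and both normalized
#' differences are defined as 0.
#'
#' @param x numeric vector, length >= 3.
#' @return named numeric vector of 6 values.
#' @export
statistical_features <- function(x) {
  n <- length(x)
  if (n < 3L) abort("need at least 3 samples", "eegstress_precondition_error")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  d1 <- sum(abs(diff(x))) / (n - 1)
  d2 <- sum(abs(x[3:n] - x[1:(n - 2)])) / (n - 2)
  c(mean = mu,
    std = sdev,
    first_diff = d1,
    norm_first_diff = if (sdev == 0) 0 else d1 / sdev,
    second_diff = d2,
    norm_second_diff = if (sdev == 0) 0 else d2 / sdev)
}

#' Higher-order crossings of one channel
#'
#' The signal is demeaned once, then repeatedly backward-differenced; `D[k]`
#' counts the sign changes (zero crossings) of the (k-1)-times differenced
#' demeaned signal. Differencing acts as a high-pass filter, so the sequence
#' summarizes the oscillatory structure cheaply. Zero samples inherit the
#' previous nonzero sign; an identically zero sequence has 0 crossings.
#'
#' @param x numeric vector, length >= M + 1.
#' @param M maximum crossing order (default 5).
#' @return integer vector `D1..DM`.
#' @export
hoc_features <- function(x, M = 5L) {
  if (M < 1L) abort("M must be >= 1", "eegstress_precondition_error")
  if (length(x) < M + 1L) {
    abort("signal too short for the requested HOC order",
          "eegstress_precondition_error")
  }
  y <- x - mean(x)
  out <- integer(M)
  for (k in seq_len(M)) {
    out[k] <- count_sign_changes(y)
    y <- diff(y)
  }
  names(out) <- paste0("D", seq_len(M))
  out
}

count_sign_changes <- function(y) {
  s <- sign(y)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Hjorth parameters of one channel
#'
#' Activity (variance of the demeaned signal), mobility (square root of the
#' ratio of first-difference variance to signal variance; a mean-frequency
#' proxy) and complexity (mobility of the derivative over mobility of the
#' signal; 1 for a pure sinusoid). Degenerate conventions: a constant signal
#' yields (0, 0, 0); a zero-variance derivative yields complexity 0.
#'
#' @param x numeric vector, length >= 3.
#' @return named numeric vector (activity, mobility, complexity).
#' @export
hjorth <- function(x) {
  n <- length(x)
  if (n < 3L) abort("need at least 3 samples", "eegstress_precondition_error")
  x <- x - mean(x)
  s1 <- sum(x^2) / n
  dx <- diff(x)
  s2 <- sum(dx^2) / (n - 1)
  ddx <- diff(dx)
  s3 <- sum(ddx^2) / (n - 2)
  if (s1 == 0) return(c(activity = 0, mobility = 0, complexity = 0))
  mob <- sqrt(s2 / s1)
  comp <- if (s2 == 0) 0 else sqrt(s3 / s2) / mob
  c(activity = s1, mobility = mob, complexity = comp)
}

#' Frontal alpha asymmetry
#'
#' Alpha-band power is computed on the right (Fp2) and left (Fp1) prefrontal
#' channels with [band_power()]; the feature is `|ln R| - |ln L|`. Resting
#' alpha lateralization over the prefrontal cortex tracks affective state,
#' which is why this single scalar joins the per-channel families.
#'
#' @param fp1,fp2 left/right prefrontal channels, equal length.
#' @param fs sampling rate in Hz.
#' @param wc a [welch_config()].
#' @param alpha_band numeric `(low, high)` in Hz; default the classic 8-13 Hz
#'   alpha band.
#' @return scalar asymmetry value.
#' @export
frontal_asymmetry_alpha <- function(fp1, fp2, fs, wc = welch_config(),
                                    alpha_band = c(8, 13)) {
  stopifnot(length(fp1) == length(fp2))
  sch <- band_scheme(matrix(alpha_band, ncol = 2L))
  L <- band_power(fp1, fs, sch, wc)
  R <- band_power(fp2, fs, sch, wc)
  if (L <= 0 || R <= 0) {
    abort("zero alpha power on a prefrontal channel: log power undefined",
          "eegstress_degenerate_error")
  }
  abs(log(R)) - abs(log(L))
}

#' Feature-extraction configuration
#'
#' @param bands a [band_scheme()].
#' @param wc a [welch_config()].
#' @param hoc_M maximum higher-order-crossing order.
#' @param alpha_band alpha band in Hz for the asymmetry feature.
#' @param left,right electrode labels of the prefrontal pair.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(bands = band_scheme(), wc = welch_config(),
                           hoc_M = 5L, alpha_band = c(8, 13),
                           left = "Fp1", right = "Fp2") {
  structure(list(bands = bands, wc = wc, hoc_M = as.integer(hoc_M),
                 alpha_band = alpha_band, left = left, right = right),
            class = "feature_config")
}

band_names <- function(bands) {
  sprintf("band%d_%g-%g", seq_len(nrow(bands)), bands[, 1], bands[, 2])
}

#' Names and family tags of the feature bank
#'
#' @param channel_names electrode labels of the montage.
#' @param config a [feature_config()].
#' @return data.frame with `name` and `type` in extraction order
#'   (statistical for every channel, then band power, HOC, Hjorth, and the
#'   single asymmetry column).
#' @export
feature_schema <- function(channel_names, config = feature_config()) {
  stat_comp <- c("mean", "std", "first_diff", "norm_first_diff",
                 "second_diff", "norm_second_diff")
  bp_comp <- band_names(config$bands)
  hoc_comp <- paste0("D", seq_len(config$hoc_M))
  hj_comp <- c("activity", "mobility", "complexity")
  fam <- function(family, comps) {
    data.frame(
      name = as.vector(vapply(channel_names, function(ch)
        paste(family, ch, comps, sep = "/"),
        character(length(comps)))),
      type = family, stringsAsFactors = FALSE)
  }
  rbind(fam("statistical", stat_comp),
        fam("bandpower", bp_comp),
        fam("hoc", hoc_comp),
        fam("hjorth", hj_comp),
        data.frame(name = sprintf("asymmetry/%s-%s/faa",
                                  config$right, config$left),
                   type = "asymmetry", stringsAsFactors = FALSE))
}

#' Extract the full feature bank from one labeled segment
#'
#' @param seg a `labeled_segment` (see [segment_trial()]).
#' @param config a [feature_config()]; the montage must contain the
#'   configured prefrontal pair.
#' @return named numeric feature vector following [feature_schema()].
#' @export
extract_all <- function(seg, config = feature_config()) {
  stopifnot(inherits(seg, "labeled_segment"))
  chn <- seg$channel_names
  if (!all(c(config$left, config$right) %in% chn)) {
    abort(sprintf("montage lacks the prefrontal pair %s/%s",
                  config$left, config$right),
          "eegstress_config_error")
  }
  fs <- seg$sampling_rate_hz
  stat <- as.vector(apply(seg$data, 1, statistical_features))
  bp <- as.vector(apply(seg$data, 1, band_power, fs = fs,
                        scheme = config$bands, wc = config$wc))
  hc <- as.vector(apply(seg$data, 1, function(ch) hoc_features(ch, config$hoc_M)))
  hj <- as.vector(apply(seg$data, 1, hjorth))
  faa <- frontal_asymmetry_alpha(seg$data[config$left, ],
                                 seg$data[config$right, ],
                                 fs, config$wc, config$alpha_band)
  v <- c(stat, bp, hc, hj, faa)
  schema <- feature_schema(chn, config)
  names(v) <- schema$name
  v
}

#' Extract features for a list of segments into a feature matrix
#'
#' @param segments list of `labeled_segment`s sharing one montage.
#' @param config a [feature_config()].
#' @return a [feature_matrix()] with one row per segment and provenance keys.
#' @export
extract_features <- function(segments, config = feature_config()) {
  stopifnot(length(segments) > 0L)
  schema <- feature_schema(segments[[1]]$channel_names, config)
  vals <- t(vapply(segments, extract_all, numeric(nrow(schema)),
                   config = config))
  keys <- data.frame(
    participant_id = vapply(segments, `[[`, character(1), "participant_id"),
    trial_id = vapply(segments, `[[`, integer(1), "trial_id"),
    segment_index = vapply(segments, `[[`, integer(1), "segment_index"),
    stringsAsFactors = FALSE)
  feature_matrix(vals, schema$name, schema$type, keys,
                 labels = vapply(segments, `[[`, character(1), "label"))
}
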
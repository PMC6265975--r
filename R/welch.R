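# Welch power spectral density.
#
# Averaged periodograms of overlapping, tapered, per-segment demeaned
# windows; one-sided density scaling (power / Hz), interior bins doubled.
# Defaults (1 s window, 50% overlap, Hann taper) follow common EEG practice
# and give ~7 averaged periodograms on a 504-sample segment at 128 Hz.

#' Welch configuration
#'
#' @param window_length_samples taper length in samples (default 128 = 1 s at
#'   128 Hz).
#' @param overlap_fraction fraction of the window shared by consecutive
#'   segments, in \[0, 1).
#' @param window_shape taper name; `"hann"` or `"rect"`.
#' @return list of class `welch_config`.
#' @export
welch_config <- function(window_length_samples = 128L, overlap_fraction = 0.5,
                         window_shape = "hann") {
  stopifnot(window_length_samples >= 2L,
            overlap_fraction >= 0, overlap_fraction < 1,
            window_shape %in% c("hann", "rect"))
  structure(list(window_length_samples = as.integer(window_length_samples),
                 overlap_fraction = overlap_fraction,
                 window_shape = window_shape),
            class = "welch_config")
}

#' Welch PSD estimate
#'
#' @param x numeric vector (one channel of one segment).
#' @param fs sampling rate in Hz.
#' @param wc a [welch_config()]; the window must not exceed `length(x)`.
#' @return list with `freq` (Hz) and `psd` (power per Hz), one-sided.
#' @export
welch_psd <- function(x, fs, wc = welch_config()) {
  stopifnot(fs > 0)
  n <- length(x)
  L <- wc$window_length_samples
  if (L > n) {
    abort("Welch window longer than the signal", "eegstress_precondition_error")
  }
  step <- max(1L, as.integer(floor(L * (1 - wc$overlap_fraction))))
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- if (wc$window_shape == "hann") {
    # periodic Hann
    0.5 * (1 - cos(2 * pi * (seq_len(L) - 1L) / L))
  } else {
    rep(1, L)
  }
  u <- sum(w^2)
  nfreq <- L %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC and (for even L) Nyquist
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (L %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / L, psd = psd * dbl)
}

#' Band scheme used for band-power features
#'
#' The default seven contiguous bands span 4-60 Hz: 4-7.2, 7.2-10.4,
#' 10.4-13.8, 13.8-17, 17-20, 20-23 and 23-60 Hz. Band edges are half-open
#' \[low, high) so touching bands partition the axis without double counting.
#'
#' @param bands numeric matrix or list of `(low_hz, high_hz)` pairs.
#' @return matrix with columns `low`, `high`, class `band_scheme`.
#' @export
band_scheme <- function(bands = default_bands()) {
  if (is.list(bands)) bands <- do.call(rbind, bands)
  bands <- matrix(as.numeric(bands), ncol = 2L,
                  dimnames = list(NULL, c("low", "high")))
  if (nrow(bands) == 0L || any(bands[, 1] >= bands[, 2])) {
    abort("each band needs low < high and the scheme must be non-empty",
          "eegstress_validation_error")
  }
  structure(bands, class = c("band_scheme", "matrix"))
}

#' @rdname band_scheme
#' @export
default_bands <- function() {
  rbind(c(4, 7.2), c(7.2, 10.4), c(10.4, 13.8), c(13.8, 17),
        c(17, 20), c(20, 23), c(23, 60))
}

#' Band power per frequency band
#'
#' Sums the Welch PSD bins whose frequency lies in `[low, high)` for each
#' band. A band lying entirely above the Nyquist frequency is still reported
#' (as the sum over the empty/available bin set) with a warning.
#'
#' @param x one channel of one segment.
#' @param fs sampling rate in Hz.
#' @param scheme a [band_scheme()].
#' @param wc a [welch_config()].
#' @return numeric vector, one value per band.
#' @export
band_power <- function(x, fs, scheme = band_scheme(), wc = welch_config()) {
  est <- welch_psd(x, fs, wc)
  nyq <- fs / 2
  vapply(seq_len(nrow(scheme)), function(i) {
    lo <- scheme[i, 1]; hi <- scheme[i, 2]
    if (lo >= nyq) {
      warning(sprintf("band %g-%g Hz lies entirely above Nyquist (%g Hz)",
                      lo, hi, nyq))
    }
    sum(est$psd[est$freq >= lo & est$freq < hi])
  }, numeric(1))
}
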
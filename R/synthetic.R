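# Synthetic EEG cohort generator.
#
# Each channel is a sum of narrowband theta/alpha/beta oscillators with
# random frequencies and phases plus band-limited pink-ish (1/f amplitude)
# noise, all confined to the 4-45 Hz band to emulate bandpass-filtered
# recordings. Stress trials scale beta power up and alpha power down on a
# planted channel subset and shift the Fp2/Fp1 alpha-power ratio, so the
# class signal lives exactly in the feature families the pipeline extracts
# and recovery tests are interpretable. Ratings are drawn strictly inside
# the calm/stress annotation regions so the annotation stage recovers the
# generator's labels exactly.

#' Synthetic cohort configuration
#'
#' Defaults mirror the geometry of the public 32-participant emotion
#' dataset the pipeline targets: 32 channels, 8064 samples (63 s) at 128 Hz,
#' 40 trials per participant.
#'
#' @param n_participants participants to generate.
#' @param trials_per_participant labeled trials per participant.
#' @param n_channels channels; the layout is the first `n_channels` labels
#'   of `layout`.
#' @param samples_per_trial samples per trial.
#' @param fs sampling rate in Hz.
#' @param calm_fraction fraction of calm trials (rounded; both classes must
#'   end up non-empty).
#' @param effect_size multiplicative band-power shift for stress trials:
#'   beta power x (1 + effect_size), alpha power / (1 + effect_size) on the
#'   planted channels. 0 plants no band-power signal.
#' @param planted_channels electrode labels carrying the effect.
#' @param asymmetry_shift log alpha-power shift applied to Fp2 on stress
#'   trials (alpha power x `exp(asymmetry_shift)`).
#' @param layout full montage the channels are drawn from.
#' @param channel_names explicit montage (must contain Fp1 and Fp2 so the
#'   asymmetry feature is computable); overrides `n_channels`/`layout`.
#' @param seed integer seed; a cohort is a pure function of its config.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 32L, trials_per_participant = 40L,
                         n_channels = 32L, samples_per_trial = 8064L,
                         fs = 128, calm_fraction = 0.5,
                         effect_size = 0.5,
                         planted_channels = c("Fp1", "Fp2", "F3", "F4"),
                         asymmetry_shift = 0.5,
                         layout = deap_channel_layout(),
                         channel_names = NULL, seed = 1L) {
  chn <- if (is.null(channel_names)) layout[seq_len(n_channels)] else channel_names
  n_channels <- length(chn)
  stopifnot(n_participants >= 1L, trials_per_participant >= 2L,
            n_channels >= 2L,
            samples_per_trial >= 32L, fs > 0, effect_size >= 0,
            calm_fraction > 0, calm_fraction < 1)
  if (!all(planted_channels %in% chn)) {
    abort("planted_channels must be a subset of the active layout",
          "eegstress_config_error")
  }
  n_calm <- round(trials_per_participant * calm_fraction)
  if (n_calm < 1L || n_calm >= trials_per_participant) {
    abort("calm_fraction yields an empty class; the participant would be excluded",
          "eegstress_config_error")
  }
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_participant = as.integer(trials_per_participant),
                 n_channels = as.integer(n_channels),
                 samples_per_trial = as.integer(samples_per_trial),
                 fs = fs, calm_fraction = calm_fraction,
                 effect_size = effect_size,
                 planted_channels = planted_channels,
                 asymmetry_shift = asymmetry_shift,
                 channel_names = chn, seed = as.integer(seed)),
            class = "synth_config")
}

# Band-limited noise via frequency-domain synthesis: spectral amplitude
# shape(f) inside [lo, hi] Hz, independent random phases, zero outside; the
# result is a stationary Gaussian-like series rescaled to sd_target. Random
# phases on every call keep trials and segments free of deterministic
# frequency fingerprints a nearest-neighbour classifier could key on.
shaped_noise <- function(n, fs, lo, hi, shape, sd_target) {
  nf <- n %/% 2L
  f <- (1:nf) * fs / n
  amp <- ifelse(f >= lo & f <= hi, shape(f), 0)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- spec
  if (n %% 2L == 0L) {
    full[nf + 1L] <- complex(real = amp[nf] * cos(phase[nf]))
    full[seq(n, nf + 2L)] <- Conj(full[2:nf])
  } else {
    full[seq(n, nf + 2L)] <- Conj(full[2:(nf + 1L)])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x * (sd_target / s)
}

pink_noise_bandlimited <- function(n, fs, lo = 4, hi = 45, sd_target = 1) {
  shaped_noise(n, fs, lo, hi, function(f) 1 / sqrt(f), sd_target)
}

# narrowband stochastic oscillator: flat spectrum inside the band; rms
# matches a sinusoid of the given amplitude so band power scales with
# amplitude^2
oscillator <- function(n, fs, band, amplitude) {
  shaped_noise(n, fs, band[1], band[2], function(f) 1, amplitude / sqrt(2))
}

synth_channel <- function(n, fs, a_theta, a_alpha, a_beta, noise_sd) {
  oscillator(n, fs, c(4, 8), a_theta) +
    oscillator(n, fs, c(8, 13), a_alpha) +
    oscillator(n, fs, c(13, 30), a_beta) +
    pink_noise_bandlimited(n, fs, sd_target = noise_sd)
}

# microvolt-scale resting amplitudes: alpha dominant, moderate theta,
# weaker beta, broadband background
base_amplitudes <- list(theta = 4, alpha = 6, beta = 3, noise_sd = 4)

#' Generate a synthetic cohort
#'
#' @param cfg a [synth_config()].
#' @return list with `trials` (list of [trial()]), `ratings` (a
#'   `ratings_table`), and `manifest`: per-trial true labels plus
#'   `planted_features`, the feature names (in [feature_schema()] naming)
#'   whose generating parameters differ between classes.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  n_calm <- round(cfg$trials_per_participant * cfg$calm_fraction)
  amp <- base_amplitudes
  trials <- list()
  rat <- list()
  truth <- list()
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("p%02d", p)
    lab <- sample(c(rep("calm", n_calm),
                    rep("stress", cfg$trials_per_participant - n_calm)))
    for (t in seq_len(cfg$trials_per_participant)) {
      stress <- lab[t] == "stress"
      mat <- matrix(0, nrow = cfg$n_channels, ncol = cfg$samples_per_trial)
      for (c in seq_len(cfg$n_channels)) {
        ch <- cfg$channel_names[c]
        planted <- stress && ch %in% cfg$planted_channels
        a_alpha <- amp$alpha
        a_beta <- amp$beta
        if (planted) {
          a_beta <- a_beta * sqrt(1 + cfg$effect_size)
          a_alpha <- a_alpha / sqrt(1 + cfg$effect_size)
        }
        if (stress && ch == "Fp2") {
          a_alpha <- a_alpha * exp(cfg$asymmetry_shift / 2)
        }
        mat[c, ] <- synth_channel(cfg$samples_per_trial, cfg$fs,
                                  amp$theta, a_alpha, a_beta, amp$noise_sd)
      }
      trials[[length(trials) + 1L]] <-
        trial(mat, pid, t, cfg$channel_names, cfg$fs)
      # ratings drawn strictly inside the annotation regions
      rat[[length(rat) + 1L]] <- if (stress) {
        data.frame(participant_id = pid, trial_id = t,
                   arousal = stats::runif(1, 5.5, 8.5),
                   valence = stats::runif(1, 1.2, 2.8))
      } else {
        data.frame(participant_id = pid, trial_id = t,
                   arousal = stats::runif(1, 1.5, 3.5),
                   valence = stats::runif(1, 4.2, 5.8))
      }
      truth[[length(truth) + 1L]] <- data.frame(
        participant_id = pid, trial_id = t, label = lab[t],
        stringsAsFactors = FALSE)
    }
  }
  list(trials = trials,
       ratings = ratings_table(do.call(rbind, rat)),
       manifest = list(
         config = unclass(cfg),
         truth = do.call(rbind, truth),
         planted_features = planted_feature_names(cfg)))
}

#' Feature names carrying the planted class effect
#'
#' Band-power columns of planted channels for bands intersecting the alpha
#' (8-13 Hz) or beta (13-30 Hz) ranges, plus the asymmetry column when an
#' asymmetry shift is planted.
#'
#' @param cfg a [synth_config()].
#' @param config a [feature_config()] defining the naming scheme.
#' @return character vector of feature names.
#' @export
planted_feature_names <- function(cfg, config = feature_config()) {
  schema <- feature_schema(cfg$channel_names, config)
  bands <- config$bands
  overlaps <- function(lo, hi, a, b) lo < b & hi > a
  informative_band <- overlaps(bands[, 1], bands[, 2], 8, 13) |
    overlaps(bands[, 1], bands[, 2], 13, 30)
  keep <- character(0)
  if (cfg$effect_size > 0) {
    bn <- band_names(bands)[informative_band]
    for (ch in cfg$planted_channels) {
      keep <- c(keep, paste("bandpower", ch, bn, sep = "/"))
    }
  }
  if (cfg$asymmetry_shift != 0) {
    keep <- c(keep, schema$name[schema$type == "asymmetry"])
    alpha_bn <- band_names(bands)[overlaps(bands[, 1], bands[, 2], 8, 13)]
    keep <- c(keep, paste("bandpower", "Fp2", alpha_bn, sep = "/"))
  }
  intersect(schema$name, unique(keep))
}

#' Export a cohort in the package's on-disk formats
#'
#' Writes one headerless CSV per trial, the ratings CSV, and a JSON
#' manifest, all readable back with [read_trials()] / [read_ratings()].
#'
#' @param cohort result of [generate_cohort()].
#' @param path output directory (created if missing).
#' @param binary if `TRUE`, write packed per-participant binary containers
#'   instead of per-trial CSVs.
#' @return `path`, invisibly.
#' @export
export_cohort <- function(cohort, path, binary = FALSE) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE)) {
    abort(sprintf("cannot create output directory %s", path),
          "eegstress_io_error")
  }
  if (binary) {
    pids <- unique(vapply(cohort$trials, `[[`, character(1), "participant_id"))
    for (pid in pids) {
      mine <- Filter(function(t) t$participant_id == pid, cohort$trials)
      write_trials_bin(mine, file.path(path, paste0(pid, ".eegbin")))
    }
  } else {
    for (tr in cohort$trials) {
      utils::write.table(tr$data,
                         file.path(path, trial_filename(tr$participant_id,
                                                        tr$trial_id)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  write_ratings(cohort$ratings, file.path(path, "ratings.csv"))
  jsonlite::write_json(
    list(truth = cohort$manifest$truth,
         planted_features = cohort$manifest$planted_features,
         config = cohort$manifest$config[
           setdiff(names(cohort$manifest$config), "channel_names")],
         channel_names = cohort$manifest$config$channel_names),
    file.path(path, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
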
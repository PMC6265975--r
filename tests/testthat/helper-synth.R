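# Shared fixtures, all generated in code.

# 8-electrode montage containing the prefrontal pair; used to keep test
# cohorts small while exercising every feature family.
test_montage <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "O1", "O2")

tiny_cohort <- function(seed = 1L, effect = 0.5, shift = 0.5, trials = 8L,
                        samples = 2048L, participants = 1L) {
  generate_cohort(synth_config(
    n_participants = participants, trials_per_participant = trials,
    channel_names = test_montage, samples_per_trial = samples,
    effect_size = effect, asymmetry_shift = shift,
    planted_channels = c("Fp1", "Fp2", "F3", "F4"), seed = seed))
}

cohort_features <- function(cohort, n_segments = 16L) {
  ann <- annotate_ratings(cohort$ratings)
  extract_features(segment_cohort(cohort$trials, ann, n_segments))
}

# independent brute-force separability oracles (plain loops, no shared code
# with the implementation)
oracle_euclid <- function(x, y) sqrt(sum((x - y)^2))

oracle_inter <- function(classes) {
  n <- length(classes)
  acc <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- 0
    for (a in seq_len(nrow(classes[[i]]))) {
      for (b in seq_len(nrow(classes[[j]]))) {
        s <- s + oracle_euclid(classes[[i]][a, ], classes[[j]][b, ])
      }
    }
    acc <- acc + s / (nrow(classes[[i]]) * nrow(classes[[j]]))
    np <- np + 1
  }
  acc / np
}

oracle_intra <- function(classes) {
  vals <- sapply(classes, function(m) {
    s <- 0
    for (a in seq_len(nrow(m))) for (b in seq_len(nrow(m))) {
      s <- s + oracle_euclid(m[a, ], m[b, ])
    }
    s / nrow(m)^2
  })
  mean(vals)
}

oracle_rating <- function(x, labels, mask) {
  x <- x[, as.logical(mask), drop = FALSE]
  classes <- lapply(sort(unique(labels)), function(l)
    x[labels == l, , drop = FALSE])
  intra <- oracle_intra(classes)
  if (intra == 0) return(1e12)
  oracle_inter(classes) / intra
}

# brute-force k-NN oracle implementing the documented tie-break
oracle_knn <- function(train_x, train_y, test_x, k) {
  apply(test_x, 1, function(p) {
    d <- apply(train_x, 1, function(q) sqrt(sum((p - q)^2)))
    nn <- order(d)[1:k]
    tab <- table(train_y[nn])
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1) {
      w <- sapply(cand, function(l)
        sum(1 / pmax(d[nn][train_y[nn] == l], .Machine$double.eps)))
      cand <- sort(cand[w == max(w)])[1]
    }
    cand
  })
}
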
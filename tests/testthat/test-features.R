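test_that("statistical features match hand-computed values", {
  # x = (1,2,3,4): population sd sqrt(1.25); mean |first diff| 1;
  # mean |x(n+2)-x(n)| 2; normalized forms divide by the sd
  f <- statistical_features(c(1, 2, 3, 4))
  expect_equal(unname(f), c(2.5, sqrt(1.25), 1, 1 / sqrt(1.25), 2, 2 / sqrt(1.25)),
               tolerance = 1e-12)
  expect_named(f, c("mean", "std", "first_diff", "norm_first_diff",
                    "second_diff", "norm_second_diff"))
})

test_that("statistical features: constant signal and shift invariance", {
  expect_equal(unname(statistical_features(rep(0, 10))), rep(0, 6))
  # sd = 0 convention: normalized differences are 0, not NaN
  expect_equal(unname(statistical_features(rep(3.7, 10))),
               c(3.7, 0, 0, 0, 0, 0))
  set.seed(1)
  x <- rnorm(50)
  a <- statistical_features(x); b <- statistical_features(x + 5)
  expect_equal(a[-1], b[-1], tolerance = 1e-12)
  expect_equal(b[["mean"]], a[["mean"]] + 5)
  expect_error(statistical_features(c(1, 2)),
               class = "eegstress_precondition_error")
})

test_that("Welch band power localizes a sinusoid and is additive over bands", {
  fs <- 128; n <- 504
  x <- sin(2 * pi * 10 * (0:(n - 1)) / fs)
  bp <- band_power(x, fs)
  expect_identical(which.max(bp), 2L)  # 10 Hz falls in 7.2-10.4 Hz

  # disjoint half-open bands partition the axis: their sum equals the
  # direct PSD bin sum over [4, 60)
  set.seed(2)
  w <- rnorm(n)
  bp_w <- band_power(w, fs)
  est <- welch_psd(w, fs)
  direct <- sum(est$psd[est$freq >= 4 & est$freq < 60])
  expect_equal(sum(bp_w), direct, tolerance = 0.01 * direct)

  # refining a band into two sub-bands conserves power exactly
  whole <- band_power(w, fs, band_scheme(matrix(c(8, 13), 1)))
  halves <- band_power(w, fs, band_scheme(rbind(c(8, 10), c(10, 13))))
  expect_equal(sum(halves), whole, tolerance = 1e-12)

  expect_equal(band_power(rep(0, n), fs), rep(0, 7))
  expect_warning(band_power(w, fs, band_scheme(matrix(c(70, 80), 1))),
                 "above Nyquist")
})

test_that("Welch PSD agrees with a direct single-window periodogram", {
  # rectangular taper, no overlap possible on an exact-length signal:
  # Welch collapses to the one-sided periodogram, computed independently
  fs <- 128; n <- 128
  set.seed(3)
  x <- rnorm(n)
  est <- welch_psd(x, fs, welch_config(n, 0, "rect"))
  xd <- x - mean(x)
  per <- Mod(fft(xd))^2 / (fs * n)
  per <- per[1:(n / 2 + 1)]
  per[2:(n / 2)] <- 2 * per[2:(n / 2)]
  expect_equal(est$psd, per, tolerance = 1e-12)
  # Parseval: integrated PSD equals the demeaned variance
  expect_equal(sum(est$psd) * fs / n, sum(xd^2) / n, tolerance = 1e-10)
})

test_that("higher-order crossings match a brute-force sign-change count", {
  expect_identical(unname(hoc_features(rep(2, 20))), rep(0L, 5))
  expect_identical(hoc_features(rep(c(1, -1), 5))[["D1"]], 9L)
  expect_identical(hoc_features(1:50)[["D1"]], 1L)

  brute <- function(x, M) {
    y <- x - mean(x)
    sapply(seq_len(M), function(k) {
      z <- y
      if (k > 1) for (i in 2:k) z <- z[-1] - z[-length(z)]
      s <- sign(z); s <- s[s != 0]
      if (length(s) < 2) 0L else sum(diff(s) != 0)
    })
  }
  set.seed(5)
  for (i in 1:25) {
    x <- switch(1 + i %% 3,
                rnorm(40),
                round(rnorm(40)),            # exercises exact zeros
                sin(2 * pi * runif(1, 1, 20) * (1:60) / 128))
    expect_identical(unname(hoc_features(x, 5L)), as.integer(brute(x, 5)))
  }
  expect_error(hoc_features(1:3, M = 0L), class = "eegstress_precondition_error")
  expect_error(hoc_features(1:4, M = 5L), class = "eegstress_precondition_error")
})

test_that("crossing counts rise with order on broadband noise", {
  # differencing high-passes, so successive orders cross zero more often
  set.seed(99)
  d <- hoc_features(rnorm(1000), 5L)
  expect_true(all(diff(d) > 0))
  expect_lt(d[["D1"]], d[["D5"]])
})

test_that("Hjorth parameters match sinusoid closed forms and scale correctly", {
  expect_equal(unname(hjorth(rep(1, 10))), c(0, 0, 0))
  fs <- 128
  for (f in c(5, 10, 20)) {
    h <- hjorth(sin(2 * pi * f * (0:9999) / fs))
    expect_equal(h[["mobility"]], 2 * sin(pi * f / fs), tolerance = 0.02)
    expect_equal(h[["complexity"]], 1, tolerance = 0.02)
  }
  set.seed(6)
  x <- rnorm(300)
  a <- hjorth(x); b <- hjorth(3 * x)
  expect_equal(b[["activity"]], 9 * a[["activity"]], tolerance = 1e-12)
  expect_equal(b[["mobility"]], a[["mobility"]], tolerance = 1e-12)
  expect_equal(b[["complexity"]], a[["complexity"]], tolerance = 1e-12)
})

test_that("frontal alpha asymmetry is zero for identical channels and antisymmetric", {
  fs <- 128; n <- 512
  set.seed(7)
  base <- sin(2 * pi * 10 * (0:(n - 1)) / fs) + 0.1 * rnorm(n)
  expect_equal(frontal_asymmetry_alpha(base, base, fs), 0)

  # amplitudes chosen so both alpha powers exceed 1: |ln| is then monotone
  # and swapping the channels negates the value
  p <- band_power(base, fs, band_scheme(matrix(c(8, 13), 1)))
  fp1 <- base * sqrt(exp(1) / p)
  fp2 <- base * sqrt(exp(2) / p)
  expect_equal(frontal_asymmetry_alpha(fp1, fp2, fs), 1, tolerance = 1e-9)
  expect_equal(frontal_asymmetry_alpha(fp2, fp1, fs),
               -frontal_asymmetry_alpha(fp1, fp2, fs), tolerance = 1e-12)
  expect_error(frontal_asymmetry_alpha(rep(0, n), base, fs),
               class = "eegstress_degenerate_error")
})

test_that("the full bank has the documented family counts and naming scheme", {
  schema <- feature_schema(deap_channel_layout())
  counts <- table(schema$type)
  expect_identical(as.integer(counts[c("statistical", "bandpower", "hoc",
                                       "hjorth", "asymmetry")]),
                   c(192L, 224L, 160L, 96L, 1L))
  expect_identical(nrow(schema), 673L)
  expect_false(anyDuplicated(schema$name) > 0)
  expect_identical(schema$name[1], "statistical/Fp1/mean")
  expect_identical(schema$name[673], "asymmetry/Fp2-Fp1/faa")

  # reduced montages scale as 21 features per channel plus one asymmetry
  s8 <- feature_schema(test_montage)
  expect_identical(nrow(s8), 8L * 21L + 1L)
})

test_that("extraction is finite on degenerate and synthetic segments", {
  co <- tiny_cohort(seed = 8L, trials = 2L, samples = 2048L)
  seg <- segment_trial(co$trials[[1]], "calm")[[1]]
  fv <- extract_all(seg)
  expect_length(fv, 169L)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_schema(test_montage)$name)

  # constant channels exercise every degenerate convention except the
  # asymmetry log (kept nonzero via the prefrontal pair)
  seg$data[3:8, ] <- 5
  fv2 <- extract_all(seg)
  expect_true(all(is.finite(fv2)))
  expect_equal(unname(fv2[["hjorth/F3/activity"]]), 0)

  bad <- seg
  bad$channel_names <- paste0("X", 1:8)
  rownames(bad$data) <- bad$channel_names
  expect_error(extract_all(bad), class = "eegstress_config_error")
})

test_that("extract_features assembles provenance-keyed labeled rows", {
  co <- tiny_cohort(seed = 10L, trials = 4L, samples = 2048L)
  fm <- cohort_features(co, n_segments = 4L)
  expect_s3_class(fm, "feature_matrix")
  expect_identical(nrow(fm$values), 16L)
  expect_identical(ncol(fm$values), 169L)
  expect_setequal(unique(fm$labels), c("calm", "stress"))
  expect_identical(fm$segment_keys$segment_index, rep(0:3, 4))
})
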
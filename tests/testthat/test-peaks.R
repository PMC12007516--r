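# Synthetic median spectrum with injected tones over a flat floor.
synth_spectrum <- function(tones, levels = 10^(20 / 20), floor_level = 1,
                           df = 1 / 3, fmax = 250) {
  freqs <- seq(0, fmax, by = df)
  asd <- rep(floor_level, length(freqs))
  levels <- rep(levels, length.out = length(tones))
  for (i in seq_along(tones)) {
    k <- which.min(abs(freqs - tones[i]))
    asd[k] <- asd[k] + levels[i]
  }
  structure(list(freqs = freqs, asd = asd, n_channels = 1,
                 channel_asd = NULL),
            class = "median_spectrum")
}

test_that("detect_peaks finds injected tones at bin accuracy", {
  flat <- synth_spectrum(numeric(0))
  expect_equal(nrow(detect_peaks(flat)), 0L)

  one <- detect_peaks(synth_spectrum(123))
  expect_equal(nrow(one), 1L)
  expect_lte(abs(one$freq - 123), 1 / 3)
  expect_gt(one$prominence_db, 6)

  # scale equivariance: prominences unchanged under positive scaling
  sp <- synth_spectrum(c(40, 123), levels = c(5, 50))
  p1 <- detect_peaks(sp)
  sp$asd <- sp$asd * 1e4
  p2 <- detect_peaks(sp)
  expect_equal(p1$prominence_db, p2$prominence_db, tolerance = 1e-9)
  expect_equal(p1$freq, p2$freq)

  coarse <- structure(list(freqs = seq(0, 100, by = 1), asd = rep(1, 101),
                           n_channels = 1, channel_asd = NULL),
                      class = "median_spectrum")
  expect_error(detect_peaks(coarse), "resolution")
})

test_that("detect_peaks on a simulated streaming condition finds 123 Hz only", {
  sim <- sim_cached("ctf", "sensight_streaming")
  pk <- exclude_line_peaks(detect_peaks(welch_asd(sim$rec)))
  below50 <- pk$freq[pk$freq < 50]
  expect_length(below50, 0)
  expect_true(any(abs(pk$freq - 123) <= 1 / 3))
})

test_that("estimate_comb recovers fundamentals with the documented tie-break", {
  mk <- function(f) structure(
    data.frame(freq = f, prominence_db = 20, width_hz = 1 / 3,
               n_channels = NA_integer_),
    class = c("peak_table", "data.frame"), resolution = 1 / 3)

  e1 <- estimate_comb(mk(c(14.3, 28.6, 42.9, 57.2)), c(5, 30))
  expect_equal(e1$fundamental, 14.3)
  expect_equal(e1$matched_harmonics, 4L)

  # 2 Hz comb between 4 and 48: 2 explains all 23, larger f0 on ties
  e2 <- estimate_comb(mk(seq(4, 48, by = 2)), c(1, 5))
  expect_equal(e2$fundamental, 2)
  expect_equal(e2$matched_harmonics, 23L)
  expect_equal(e2$coverage, 1)

  e3 <- estimate_comb(mk(50), c(10, 60))
  expect_equal(e3$fundamental, 50)
  expect_equal(e3$matched_harmonics, 1L)

  empty <- structure(data.frame(freq = numeric(), prominence_db = numeric(),
                                width_hz = numeric(),
                                n_channels = integer()),
                     class = c("peak_table", "data.frame"))
  expect_error(estimate_comb(empty, c(1, 5)), "empty")
})

test_that("estimate_comb inverts synthetic combs over the candidate grid", {
  # exhaustive over fundamentals 1-20 Hz at 0.1 steps, >= 3 harmonics,
  # peaks quantised to the 1/3 Hz spectral grid
  mk <- function(f) structure(
    data.frame(freq = f, prominence_db = 20, width_hz = 1 / 3,
               n_channels = NA_integer_),
    class = c("peak_table", "data.frame"), resolution = 1 / 3)
  for (f0 in seq(2, 20, by = 0.3)) {
    harmonics <- f0 * seq_len(max(3, floor(60 / f0)))
    quantised <- round(harmonics * 3) / 3
    est <- estimate_comb(mk(quantised), c(1, 21))
    expect_equal(est$fundamental, f0, tolerance = 0.11,
                 info = paste("f0 =", f0))
  }
})

test_that("predict_intermod matches the arithmetic and the FFT oracle", {
  got <- predict_intermod(145, 923, fs = 6000, n_max = 14, m_max = 2)
  expect_true(all(c(39, 53, 92, 106) %in% got))
  expect_identical(predict_intermod(145, 923, 6000, n_max = 5, m_max = 0),
                   numeric(0))

  # brute-force oracle: FFT peak set of a quadratic+cubic distortion of a
  # two-tone stack, on a random grid of tone pairs; 10 s duration puts the
  # 0.1 Hz-quantised tones exactly on FFT bins
  fs <- 4000
  t <- (0:(fs * 10 - 1)) / fs
  set.seed(7)
  for (trial in 1:50) {
    f1 <- round(runif(1, 80, 250), 1)
    f2 <- round(runif(1, 700, 1200), 1)
    x <- cos(2 * pi * f1 * t) + cos(2 * pi * f2 * t)
    y <- 0.3 * x^2 + 0.1 * x^3
    n <- length(y)
    a <- Mod(fft(y)) / n
    f <- (0:(n - 1)) * fs / n
    # products reachable at quadratic/cubic order: n + m <= 3
    pred <- union(predict_intermod(f1, f2, fs, n_max = 2, m_max = 1,
                                   f_ceiling = 400),
                  predict_intermod(f1, f2, fs, n_max = 1, m_max = 2,
                                   f_ceiling = 400))
    for (fp in pred) {
      idx <- abs(f - fp) < 0.5
      expect_gt(max(a[idx]), 0.01, label = sprintf(
        "oracle amplitude at %.1f Hz (f1=%.1f, f2=%.1f)", fp, f1, f2))
    }
  }
})

test_that("classification recovers single-factor conditions from their spectra", {
  cases <- list(
    list(profile = "ctf", cond = "sensight_streaming",
         expect = "sensight_telemetry"),
    list(profile = "ctf", cond = "legacy_open",
         expect = "legacy_telemetry_open"),
    list(profile = "ctf", cond = "legacy_streaming",
         expect = "legacy_streaming"),
    list(profile = "ctf", cond = "communicator_near",
         expect = "communicator"),
    list(profile = "opm", cond = "bipolar", expect = "stim_bipolar"),
    list(profile = "megin", cond = "bipolar", expect = "stim_bipolar"),
    list(profile = "ctf", cond = "monopolar", expect = "stim_monopolar")
  )
  for (cs in cases) {
    sim <- sim_cached(cs$profile, cs$cond)
    mask <- if (cs$cond == "monopolar")
      reject_bad_segments(sim$rec) else NULL
    sp <- suppressWarnings(welch_asd(sim$rec, mask = mask))
    pk <- detect_peaks(sp)
    res <- classify_condition(pk, signature_library(make_profile(cs$profile)))
    active <- res$source[res$active]
    expect_true(cs$expect %in% active,
                info = paste(cs$profile, cs$cond, "->",
                             paste(active, collapse = ",")))
    wrong <- setdiff(res$source[grepl("telemetry|streaming|communicator",
                                      res$source)], cs$expect)
    if (grepl("telemetry|communicator|streaming", cs$expect))
      expect_false(any(wrong %in% active),
                   info = paste(cs$profile, cs$cond))
  }
})

test_that("legacy streaming produces a dense sub-50 Hz comb", {
  sim <- sim_cached("ctf", "legacy_streaming")
  pk <- exclude_line_peaks(detect_peaks(welch_asd(sim$rec)))
  expect_gte(sum(pk$freq < 50), 10)
})

test_that("end-to-end: every planned tone is detected within one bin", {
  for (case in list(c("ctf", "sensight_streaming"),
                    c("megin", "bipolar"),
                    c("opm", "bipolar"))) {
    sim <- sim_cached(case[1], case[2])
    plan <- sim$rec$truth$artefact_freqs
    plan <- plan[!is.na(plan$freq) & plan$freq <= 200, ]
    if (case[1] == "megin" && "megin_subharmonic" %in% plan$source) {
      sub <- sim$rec$truth$subharmonic_channels
      sp <- welch_asd(sim$rec)
      pk_sub <- detect_peaks(median_spectrum(sp, sub))
      f_sub <- plan$freq[plan$source == "megin_subharmonic"]
      expect_true(any(abs(pk_sub$freq - f_sub) <= 1 / 3 + 0.2),
                  info = "subharmonic on affected channels")
      plan <- plan[plan$source != "megin_subharmonic", ]
    }
    pk <- detect_peaks(welch_asd(sim$rec))
    for (i in seq_len(nrow(plan)))
      expect_true(any(abs(pk$freq - plan$freq[i]) <= 1 / 3 + 0.05),
                  info = paste(case[1], case[2], plan$source[i],
                               plan$freq[i]))
  }
})
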
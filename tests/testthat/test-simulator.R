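test_that("pulse_train is charge balanced with its fundamental at f_stim", {
  stim <- stim_settings(amplitude = 5, pulse_width = 60, frequency = 145,
                        mode = "bipolar")
  fs <- 19200
  w <- pulse_train(stim, fs, duration = 2)
  expect_equal(length(w), 2 * fs)
  # charge balance: mean over the full train within 1e-12 of peak amplitude
  expect_lt(abs(mean(w)), 1e-12 * max(abs(w)))
  # FFT oracle: strongest bin below 200 Hz within one bin of 145 Hz
  n <- length(w)
  a <- Mod(fft(w))[2:(n %/% 2)]
  f <- (1:(n %/% 2 - 1)) * fs / n
  expect_lt(abs(f[f < 200][which.max(a[f < 200])] - 145), fs / n + 1e-9)

  expect_equal(pulse_train(stim_settings(amplitude = 0, mode = "off"),
                           fs, 0.5), numeric(fs / 2))
  expect_error(pulse_train(stim, fs = 5000, duration = 1), "raise the samp")
})

test_that("shaped_noise matches its ASD spec and closed forms", {
  fs <- 1000
  # flat white case: closed-form one-sided ASD sigma*sqrt(2/fs)
  L <- 7
  x <- shaped_noise(list(freq = c(0.1, fs / 2), level = c(L, L)), fs,
                    n_samples = 240 * fs, seed = 2)
  rec <- toy_recording(x, fs)
  sp <- welch_asd(rec, segment_length = 3)
  band <- sp$freqs >= 20 & sp$freqs <= 45
  expect_equal(median(sp$asd[1, band]), L, tolerance = 0.1)
  # implied variance: integral of squared ASD over (0, fs/2]
  expect_equal(var(x), L^2 * fs / 2, tolerance = 0.1)

  # the OPM curve reaches its specified level at 10 Hz within 15%
  opm <- make_profile("opm")
  y <- shaped_noise(opm$noise_floor_spec$mag, opm$fs, 40 * opm$fs, seed = 3)
  spo <- welch_asd(toy_recording(y, opm$fs))
  expect_equal(unname(spo$asd[1, which.min(abs(spo$freqs - 10))]), 540,
               tolerance = 0.15)

  expect_identical(shaped_noise(list(freq = 1, level = 1), fs, 0), numeric(0))
  expect_error(shaped_noise(list(freq = 1, level = 0), fs, 10), "positive")
  # seeded reproducibility
  expect_identical(shaped_noise(list(freq = c(1, 500), level = c(2, 2)),
                                fs, 100, seed = 5),
                   shaped_noise(list(freq = c(1, 500), level = c(2, 2)),
                                fs, 100, seed = 5))
})

test_that("OPM nonlinearity mixes tones at |n f1 - m f2| and is identity at zero", {
  prof <- make_profile("opm")
  fs <- prof$fs
  t <- (0:(fs * 8 - 1)) / fs
  x <- 3000 * cos(2 * pi * 870 * t) + 1500 * cos(2 * pi * 610 * t)

  prof0 <- prof
  prof0$opm_nonlinearity <- c(alpha = 0, beta = 0)
  expect_equal(apply_opm_nonlinearity(x, prof0), x, tolerance = 1e-12)

  y <- apply_opm_nonlinearity(x, prof)
  n <- length(y)
  a <- Mod(fft(y)) / n
  f <- (0:(n - 1)) * fs / n
  peak_at <- function(freq) max(a[abs(f - freq) < 0.4])
  floor_near <- function(freq) median(a[abs(f - freq) < 8 & abs(f - freq) > 2])
  # quadratic product of the 870 Hz tone with the 923 Hz modulation: 53 Hz
  expect_gt(peak_at(53), 20 * floor_near(53))
  # and of the 610 Hz tone: 313 Hz
  expect_gt(peak_at(313), 20 * floor_near(313))
})

test_that("predicted intermod products appear for the stimulation pulse train", {
  # brute-force FFT oracle on a simulated OPM bipolar channel
  sim <- sim_cached("opm", "bipolar")
  sp <- welch_asd(sim$rec)
  pk <- detect_peaks(sp)
  quad <- predict_intermod(145, 923, 6000, n_max = 8, m_max = 1,
                           f_ceiling = 200)
  for (f0 in quad)
    expect_true(any(abs(pk$freq - f0) <= 0.4), info = paste("product", f0))
})

test_that("simulate_condition composes conditions per the factor model", {
  prof <- make_profile("ctf")
  # quiescent adds nothing over empty room on this system (same noise seed)
  s_er <- sim_cached("ctf", "empty_room")
  s_q <- sim_cached("ctf", "quiescent")
  a_er <- median_spectrum(welch_asd(s_er$rec))
  a_q <- median_spectrum(welch_asd(s_q$rec))
  band <- a_er$freqs >= 20 & a_er$freqs <= 45
  expect_lt(max(abs(a_q$asd[band] / a_er$asd[band] - 1)), 0.05)

  # sensight streaming: the single non-line peak below 200 Hz is 123 Hz
  s_ss <- sim_cached("ctf", "sensight_streaming")
  pk <- exclude_line_peaks(detect_peaks(welch_asd(s_ss$rec)))
  low <- pk$freq[pk$freq < 200]
  expect_equal(low, 123, tolerance = 1 / 3)

  # monopolar: at least one channel with a step > 20x diff-MAD
  s_mono <- sim_cached("ctf", "monopolar")
  ratios <- apply(s_mono$rec$data, 1, function(x) {
    d <- diff(x); max(abs(d)) / mad(d, constant = 1.4826)
  })
  expect_gt(max(ratios), 20)
  expect_gt(length(unlist(s_mono$rec$truth$jump_times)), 0)
})

test_that("movement artefact is confined below 20 Hz", {
  sim <- sim_cached("ctf", "movement")
  base <- sim_cached("ctf", "quiescent")
  a_m <- median_spectrum(welch_asd(sim$rec))
  a_q <- median_spectrum(welch_asd(base$rec))
  low <- a_m$freqs >= 2 & a_m$freqs <= 4
  high <- a_m$freqs >= 25 & a_m$freqs <= 45
  expect_gt(median(a_m$asd[low] / a_q$asd[low]), 2)    # clear lift below 20
  expect_lt(max(a_m$asd[high] / a_q$asd[high]), 1.1)   # none above
})

test_that("simulation is bit-reproducible for identical seeds", {
  a <- simulate_condition(make_profile("opm"), condition_spec("bipolar"),
                          duration = 8, seed = 21, n_channels = 3)
  b <- simulate_condition(make_profile("opm"), condition_spec("bipolar"),
                          duration = 8, seed = 21, n_channels = 3)
  expect_identical(a$rec$data, b$rec$data)
  expect_identical(a$lfp$data, b$lfp$data)
  c <- simulate_condition(make_profile("opm"), condition_spec("bipolar"),
                          duration = 8, seed = 22, n_channels = 3)
  expect_false(identical(a$rec$data, c$rec$data))
})

test_that("toggling one artefact source leaves other sub-streams unchanged", {
  # sub-stream seeding: the noise realisation is identical whether or not
  # telemetry is active
  a <- simulate_condition(make_profile("ctf"), condition_spec("empty_room"),
                          duration = 6, seed = 31, n_channels = 2)
  b <- simulate_condition(make_profile("ctf"),
                          condition_spec("sensight_streaming"),
                          duration = 6, seed = 31, n_channels = 2)
  # difference is exactly the telemetry tones: a pure set of sinusoids
  d <- b$rec$data[1, ] - a$rec$data[1, ]
  n <- length(d)
  a_fft <- Mod(fft(d)) / n
  f <- (0:(n - 1)) * 19200 / n
  f <- pmin(f, 19200 - f)               # fold the mirrored bins
  in_tones <- abs(f - 123) < 0.5 | abs(f - 246) < 0.5 | abs(f - 369) < 0.5
  expect_gt(sum(a_fft[in_tones]^2), 0.999 * sum(a_fft^2))
})

test_that("inject_clock_drift records and applies the affine map", {
  cond <- condition_spec("quiescent", clock = list(offset = 0, rate = 1))
  lfp <- perceptmeg:::build_lfp_stream(cond, duration = 30, seed = 4)
  same <- inject_clock_drift(lfp, 0, 1)
  expect_identical(same$data, lfp$data)

  drifted <- inject_clock_drift(lfp, 1.25, 1 + 5e-5)
  expect_equal(drifted$clock, list(offset = 1.25, rate = 1 + 5e-5))
  expect_error(inject_clock_drift(lfp, 0, 1.01), "rate")

  # round trip through the alignment resampler: residual < 1 LFP sample
  map <- structure(list(offset = 1.25, rate = 1 + 5e-5, residuals = 0,
                        n_events = 2), class = "clock_map")
  back <- resample_to_meg_clock(drifted, map, target_fs = lfp$fs)
  n <- min(ncol(back), ncol(lfp$data)) - 2 * lfp$fs
  i <- (lfp$fs + 1):n
  # residual lag via cross-correlation of a mid-section
  cc <- sapply(-2:2, function(lag)
    cor(back[1, i], lfp$data[1, i + lag]))
  expect_equal(which.max(cc), 3L)   # zero lag
  expect_gt(max(cc), 0.99)
})

test_that("LFP stream carries stimulation artefact and optional ECG", {
  cond <- condition_spec("toggling", lfp_ecg = TRUE,
                         clock = list(offset = 0, rate = 1))
  lfp <- perceptmeg:::build_lfp_stream(cond, duration = 40, seed = 5,
                                       tog = NULL)
  sp <- welch_asd(new_recording(lfp$data, lfp$fs, toy_meta(2, units = "uV")))
  ms <- median_spectrum(sp)
  # 145 Hz stim artefact aliased to 105 Hz at the 250 Hz LFP rate
  i105 <- which.min(abs(ms$freqs - 105))
  base <- median(ms$asd[ms$freqs > 60 & ms$freqs < 100])
  expect_gt(ms$asd[i105], 5 * base)
})
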
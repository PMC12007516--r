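#' Charge-balanced biphasic stimulation pulse train
#'
#' Symmetric biphasic rectangular pulse train with immediate passive recharge:
#' each period contains a positive phase of `pulse_width` us followed directly
#' by an equal negative phase, so every period integrates to zero and the
#' fundamental sits at the pulse rate.
#'
#' @param stim A [stim_settings()] object.
#' @param fs Sampling rate, Hz (must exceed twice the pulse rate and resolve
#'   one phase with at least one sample).
#' @param duration Duration, s.
#' The rectangular train is rendered at an internally oversampled rate where
#' each phase spans at least 8 samples, anti-alias low-pass filtered at
#' 0.45 fs and decimated — the waveform as seen through an acquisition
#' front end. Without this, a 60 us pulse (barely more than one sample even
#' at 19.2 kHz) would alias high harmonics onto arbitrary frequencies.
#'
#' @return Numeric waveform in arbitrary source units (scaled by `amplitude`).
#' @examples
#' w <- pulse_train(stim_settings(mode = "bipolar"), fs = 19200, duration = 1)
#' mean(w)
#' @export
pulse_train <- function(stim, fs, duration) {
  stopifnot(inherits(stim, "stim_settings"), duration > 0)
  if (fs <= 2 * stim$frequency)
    stop("fs must exceed twice the stimulation frequency")
  n <- round(duration * fs)
  if (stim$amplitude == 0) return(numeric(n))
  pw_samp <- stim$pulse_width * 1e-6 * fs
  if (pw_samp < 1)
    stop("pulse width is narrower than one sample at fs = ", fs,
         " Hz; raise the sampling rate to at least ",
         ceiling(1 / (stim$pulse_width * 1e-6)), " Hz")
  up <- max(1L, ceiling(8 / pw_samp))
  fs_i <- fs * up
  n_i <- n * up
  t <- (0:(n_i - 1)) / fs_i
  phase <- (t * stim$frequency) %% 1          # position within period [0,1)
  pw_frac <- stim$pulse_width * 1e-6 * stim$frequency
  out <- numeric(n_i)
  out[phase < pw_frac] <- stim$amplitude
  out[phase >= pw_frac & phase < 2 * pw_frac] <- -stim$amplitude
  if (up > 1L) {
    out <- fft_lowpass(out, fs_i, 0.45 * fs)
    out <- out[seq(1, n_i, by = up)]
  }
  # exact charge balance (sampling can unbalance the phases)
  out - mean(out)
}

#' Gaussian noise with a prescribed amplitude spectral density
#'
#' Generates zero-mean Gaussian noise whose one-sided amplitude spectral
#' density follows a piecewise log-log curve, by shaping white noise in the
#' Fourier domain. The variance of the output equals the integral of the
#' squared ASD over (0, fs/2] (up to stochastic fluctuation).
#'
#' @param spec List with `freq` and `level` (see [noise_floor_level()]).
#' @param fs Sampling rate, Hz.
#' @param n_samples Number of samples.
#' @param seed Optional integer; if given the generator is seeded locally.
#' @return Numeric waveform.
#' @examples
#' x <- shaped_noise(list(freq = c(1, 100), level = c(10, 10)), 1000, 4096,
#'                   seed = 1)
#' @export
shaped_noise <- function(spec, fs, n_samples, seed = NULL) {
  if (any(spec$level <= 0)) stop("noise ASD levels must be positive")
  n_samples <- as.integer(n_samples)
  if (n_samples == 0L) return(numeric(0))
  gen <- function() {
    x <- stats::rnorm(n_samples)
    # white unit-variance noise has one-sided ASD sqrt(2/fs)
    fft_apply_gain(x, fs, function(f)
      noise_floor_level(spec, pmax(f, 1e-3)) / sqrt(2 / fs))
  }
  if (is.null(seed)) gen() else with_sub_seed(seed, "shaped_noise", gen())
}

#' Polynomial sensor nonlinearity with internal modulation tone
#'
#' Emulates the response of an optically pumped magnetometer whose internal
#' modulation tone (923 Hz for this profile) mixes with strong interferers:
#' the modulation tone is added to the input, a quadratic/cubic
#' polynomial `y = x' + alpha x'^2 + beta x'^3` is applied, and the
#' modulation tone is notched back out. Intermodulation products at
#' `|n f_stim - m f_mod|` appear for strong pulse-train inputs.
#'
#' @param x Waveform sampled at `profile$fs`.
#' @param profile A `system_profile` with `opm_modulation_freq` and
#'   `opm_nonlinearity` (`alpha`, `beta`).
#' The polynomial is evaluated at a 3x internally oversampled rate and the
#' result is low-pass filtered back to the original Nyquist band before
#' decimation, so cubic distortion of band-limited inputs cannot alias into
#' the physiological range; products below `fs/2` therefore appear at their
#' true `|n f_stim - m f_mod|` frequencies.
#'
#' @param modulation_amp Amplitude of the internal modulation tone in sensor
#'   units (default 1e5 fT = 0.1 nT).
#' @return Transformed waveform (identity when `alpha = beta = 0`).
#' @export
apply_opm_nonlinearity <- function(x, profile, modulation_amp = 1e5) {
  al <- profile$opm_nonlinearity[["alpha"]]
  be <- profile$opm_nonlinearity[["beta"]]
  if (al == 0 && be == 0) return(x)
  fmod <- profile$opm_modulation_freq
  if (is.null(fmod)) stop("profile has no modulation frequency")
  fs <- profile$fs
  n <- length(x)
  up <- 3L
  xu <- fft_upsample(x, up)
  t <- (0:(n * up - 1)) / (fs * up)
  xp <- xu + modulation_amp * cos(2 * pi * fmod * t)
  y <- xp + al * xp^2 + be * xp^3
  y <- fft_lowpass(y, fs * up, fs / 2 * 0.999)
  y <- y[seq(1, n * up, by = up)]
  y <- fft_notch(y, fs, fmod, half_width = 2)
  y - mean(y)
}

# Exact FFT zero-padding upsampler for band-limited signals.
#' @noRd
fft_upsample <- function(x, up) {
  n <- length(x)
  X <- stats::fft(x)
  half <- n %/% 2
  Xu <- complex(real = numeric(n * up))
  Xu[1:(half + 1)] <- X[1:(half + 1)]
  n_neg <- n - half - 1L
  if (n_neg > 0) Xu[(n * up - n_neg + 1):(n * up)] <- X[(half + 2):n]
  Re(stats::fft(Xu, inverse = TRUE)) / n
}

#' Simulate a phantom recording for one operating condition
#'
#' Additively composes, per channel: shaped system noise, mains lines and
#' intrinsic sensor peaks, telemetry tones or combs, communicator comb,
#' breathing-like implant movement, and the stimulation field projected
#' through a current dipole at the lead position (with system-specific
#' extras: CTF sidelobes and extra tones, MEGIN subharmonic on a channel
#' subset, SQUID step jumps on cryogenic channels under monopolar
#' stimulation, and the OPM modulation nonlinearity applied last). A bipolar
#' LFP stream on a drifting clock is returned alongside, carrying the
#' (aliased) stimulation artefact and optional ECG contamination or a
#' physiological oscillation coherent with a simulated cortical source.
#'
#' Each artefact source draws from an independent sub-stream of `seed`, so
#' toggling one source never changes another's realisation.
#'
#' @param profile A [make_profile()] object.
#' @param cond A [condition_spec()] object.
#' @param duration Duration, s (>= 30 s recommended for spectral targets;
#'   120 s for the reference analyses).
#' @param seed Integer root seed.
#' @param n_channels Number of channels to simulate (desk-scale subset of the
#'   full array, sampled evenly; MEGIN keeps the 2:1 gradiometer:magnetometer
#'   ratio). Default 18.
#' @return List with elements `rec` (a `meg_recording` with a filled `truth`
#'   block) and `lfp` (an `lfp_stream`).
#' @export
simulate_condition <- function(profile, cond, duration = 120, seed = 1,
                               n_channels = 18L) {
  stopifnot(inherits(profile, "system_profile"),
            inherits(cond, "condition_spec"))
  validate_condition(cond)
  fs <- profile$fs
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  meta <- select_channels(profile, n_channels)
  n_ch <- nrow(meta)
  data <- matrix(0, n_ch, n)
  truth <- list(condition = cond$name, seed = seed,
                artefact_freqs = data.frame(source = character(),
                                            freq = numeric()),
                stim_on = numeric(), stim_off = numeric(),
                jump_times = vector("list", n_ch),
                subharmonic_channels = character(),
                clock = cond$clock, source = NULL)

  floor_of <- function(type, f) noise_floor_level(profile$noise_floor_spec[[type]], f)
  # A tone of amplitude A yields a Welch-Hann ASD peak of about A*sqrt(T/3);
  # amplitudes are calibrated for the default 3 s analysis, where the factor
  # is 1 and "rel_db above floor" maps directly to amplitude.
  tone_amp <- function(type, f, rel_db) floor_of(type, f) * 10^(rel_db / 20)

  # --- system noise -------------------------------------------------------
  for (ch in seq_len(n_ch)) {
    data[ch, ] <- shaped_noise(profile$noise_floor_spec[[meta$type[ch]]], fs,
                               n, seed = sub_seed(seed, paste0("noise", ch)))
  }

  # --- mains lines (common phase, per-channel gain) -----------------------
  with_sub_seed(seed, "lines", {
    for (f in profile$line_freqs) {
      ph <- stats::runif(1, 0, 2 * pi)
      gains <- stats::runif(n_ch, 0.5, 1)
      wave <- cos(2 * pi * f * t + ph)
      for (ch in seq_len(n_ch))
        data[ch, ] <- data[ch, ] +
          gains[ch] * tone_amp(meta$type[ch], f, 28) * wave
    }
  })

  # --- intrinsic sensor peaks --------------------------------------------
  with_sub_seed(seed, "intrinsic", {
    for (type in names(profile$intrinsic_peaks)) {
      pk <- profile$intrinsic_peaks[[type]]
      if (is.null(pk)) next
      idx <- which(meta$type == type)
      for (i in seq_len(nrow(pk))) {
        for (ch in idx) {
          ph <- stats::runif(1, 0, 2 * pi)
          g <- stats::runif(1, 0.6, 1)
          data[ch, ] <- data[ch, ] +
            g * tone_amp(type, pk$freq[i], pk$rel_db[i]) *
              cos(2 * pi * pk$freq[i] * t + ph)
        }
      }
    }
  })

  add_tones <- function(data, plan, topo_norm) {
    # topo_norm: per-channel gain in [0,1] per type (max 1 within each type)
    with_sub_seed(seed, "tones", {
      for (i in seq_len(nrow(plan))) {
        ph <- stats::runif(1, 0, 2 * pi)
        wave <- cos(2 * pi * plan$freq[i] * t + ph)
        for (ch in seq_len(n_ch))
          data[ch, ] <- data[ch, ] + topo_norm[ch] *
            tone_amp(meta$type[ch], plan$freq[i], plan$rel_db[i]) * wave
      }
      data
    })
  }

  ipg_pos <- c(0, 0, -0.33)            # implant ~33 cm below the array centre
  lead_pos <- c(0.025, 0.01, 0.045)    # lead tip inside the conductor sphere
  topo_ipg <- normalized_dipole_topography(meta, ipg_pos, free_space = TRUE)
  topo_lead <- normalized_dipole_topography(meta, lead_pos)
  # telemetry/communicator tones are calibrated against the median spectrum,
  # so their topography is normalised to unit median gain per sensor type
  topo_tele <- topo_ipg
  for (ty in unique(meta$type)) {
    i <- meta$type == ty
    topo_tele[i] <- topo_ipg[i] / stats::median(abs(topo_ipg[i]))
  }

  if (cond$ipg_present) {
    plan <- condition_tone_plan(profile, cond)
    plan_tele <- plan[plan$source %in% c("sensight_telemetry",
                                         "legacy_telemetry_open",
                                         "legacy_streaming_comb",
                                         "communicator", "ctf_misc"), ,
                      drop = FALSE]
    if (nrow(plan_tele))
      data <- add_tones(data, plan_tele, topo_tele)
    truth$artefact_freqs <- rbind(truth$artefact_freqs,
                                  plan[, c("source", "freq")])
  }

  # --- movement artefact --------------------------------------------------
  # breathing-like implant motion: amplitude-modulated at 0.25 Hz, ASD flat
  # 46 dB above the local floor up to 1 Hz then rolling off as 1/f^2, no
  # power above 20 Hz
  if (cond$movement) {
    mv <- with_sub_seed(seed, "movement", {
      base <- shaped_noise(list(freq = c(0.1, 1, 20, fs / 2),
                                level = c(1, 1, 1 / 400, 1e-9)), fs, n)
      base <- fft_lowpass(base, fs, 20)
      am <- 0.5 * (1 + sin(2 * pi * 0.25 * t))
      base * am
    })
    for (ch in seq_len(n_ch)) {
      amp <- 10^(46 / 20) * floor_of(meta$type[ch], 5)
      data[ch, ] <- data[ch, ] + topo_ipg[ch] * amp * mv
    }
    truth$artefact_freqs <- rbind(truth$artefact_freqs,
                                  data.frame(source = "movement", freq = NA))
  }

  # --- stimulation --------------------------------------------------------
  stim <- cond$stim
  stim_active <- cond$ipg_present && stim$mode != "off" && stim$amplitude > 0
  stim_tone_only <- cond$ipg_present && stim$mode == "monopolar" &&
    stim$amplitude == 0 && cond$streaming
  tog <- toggle_mask(cond$toggle, t, duration)
  truth$stim_on <- tog$on
  truth$stim_off <- tog$off

  if (stim_active || stim_tone_only) {
    f_stim <- stim$frequency
    rel_db_fund <- if (stim$mode == "monopolar" && stim$amplitude > 0) 55
                   else if (stim_tone_only) 30 else 46
    if (stim_active) {
      pt <- bandlimited_pulse_train(stim, fs, duration)
    } else {
      pt <- cos(2 * pi * f_stim * t)
    }
    pt <- pt * tog$mask
    for (ch in seq_len(n_ch)) {
      amp <- tone_amp(meta$type[ch], f_stim, rel_db_fund)
      data[ch, ] <- data[ch, ] + topo_lead[ch] * amp * pt
    }
    truth$artefact_freqs <- rbind(truth$artefact_freqs,
                                  data.frame(source = "stim", freq = f_stim))
    # system-specific deterministic extras
    plan <- condition_tone_plan(profile, cond)
    plan_st <- plan[plan$source %in% c("stim_sidelobes", "ctf_bipolar_extras"),
                    , drop = FALSE]
    if (nrow(plan_st)) {
      with_sub_seed(seed, "stim_extras", {
        for (i in seq_len(nrow(plan_st))) {
          ph <- stats::runif(1, 0, 2 * pi)
          wave <- cos(2 * pi * plan_st$freq[i] * t + ph) * tog$mask
          for (ch in seq_len(n_ch))
            data[ch, ] <- data[ch, ] + topo_lead[ch] *
              tone_amp(meta$type[ch], plan_st$freq[i], plan_st$rel_db[i]) * wave
        }
      })
    }
    # MEGIN: slightly broadened subharmonic on a gradiometer subset
    if (stim$mode == "bipolar" && profile$name == "megin") {
      f_sub <- f_stim * cond$subharmonic$factor
      grads <- which(meta$type == "planar_grad")
      n_aff <- max(1L, round(length(grads) * cond$subharmonic$channel_fraction))
      aff <- grads[seq_len(n_aff)]
      with_sub_seed(seed, "subharmonic", {
        z <- fft_lowpass(stats::rnorm(n), fs, 0.4)
        am <- 1 + 0.5 * z / stats::sd(z)
        ph <- stats::runif(1, 0, 2 * pi)
        wave <- am * cos(2 * pi * f_sub * t + ph)
        for (ch in aff)
          data[ch, ] <- data[ch, ] +
            tone_amp(meta$type[ch], f_sub, 28) * wave
        # fainter trace on magnetometers
        for (ch in which(meta$type == "mag"))
          data[ch, ] <- data[ch, ] +
            0.3 * tone_amp("mag", f_sub, 28) * wave
      })
      truth$subharmonic_channels <- meta$name[aff]
    }
    # monopolar: broadband lift + SQUID jumps on cryogenic channels only
    # (OPMs recover after over-ranging and keep artefact-free spectral
    # portions at the empty-room level)
    if (stim$mode == "monopolar" && stim$amplitude > 0 &&
        profile$squid_jump_susceptible) {
      with_sub_seed(seed, "broadband", {
        for (ch in seq_len(n_ch)) {
          lift <- shaped_noise(profile$noise_floor_spec[[meta$type[ch]]], fs, n)
          data[ch, ] <- data[ch, ] + 9 * lift * tog$mask_slow
        }
      })
      with_sub_seed(seed, "jumps", {
        for (ch in seq_len(n_ch)) {
          n_jump <- stats::rpois(1, 0.05 * duration)
          if (n_jump == 0) next
          times <- sort(stats::runif(n_jump, 0, duration))
          sizes <- stats::runif(n_jump, 50, 500) *
            sample(c(-1, 1), n_jump, replace = TRUE) * stats::sd(data[ch, ])
          step <- numeric(n)
          for (j in seq_len(n_jump))
            step[t >= times[j]] <- step[t >= times[j]] + sizes[j]
          data[ch, ] <- data[ch, ] + step
          truth$jump_times[[ch]] <- times
        }
      })
    }
  }

  # --- coherent cortical source (optional) --------------------------------
  src_signal <- NULL
  if (!is.null(cond$source)) {
    src <- cond$source
    src_signal <- with_sub_seed(seed, "cortical_source", {
      s <- fft_bandpass(stats::rnorm(n), fs,
                        src$freq - src$bandwidth / 2,
                        src$freq + src$bandwidth / 2)
      s / stats::sd(s)
    })
    topo_src <- normalized_dipole_topography(meta, src$location)
    for (ch in seq_len(n_ch)) {
      amp <- tone_amp(meta$type[ch], src$freq, src$amp_db %||% 15)
      data[ch, ] <- data[ch, ] + topo_src[ch] * amp * src_signal
    }
    truth$source <- src
  }

  # --- OPM nonlinearity last (non-additive by design) ---------------------
  if (profile$name == "opm" &&
      any(profile$opm_nonlinearity != 0) && (stim_active || stim_tone_only)) {
    for (ch in seq_len(n_ch))
      data[ch, ] <- apply_opm_nonlinearity(data[ch, ], profile)
  }

  rec <- new_recording(data, fs, meta,
                       provenance = list(condition = cond$name, seed = seed,
                                         profile = profile$name),
                       truth = truth)
  lfp <- build_lfp_stream(cond, duration, seed, src_signal, tog)
  list(rec = rec, lfp = lfp)
}

# Band-limited stimulation artefact, synthesised from the analytic Fourier
# series of the biphasic pulse train, |c_k| = (4A/(pi k)) sin^2(pi k f pw),
# normalised so the fundamental has unit amplitude. Used inside the
# simulator: at the 5-6 kHz profiles a 60 us pulse is narrower than one
# sample, so time-domain synthesis is impossible, and band-limiting keeps
# the OPM nonlinearity alias-free. Harmonic phases are scrambled with a
# deterministic golden-ratio sequence: sensor and electronics dispersion
# decorrelates harmonic phases in practice, which leaves every spectral line
# untouched but removes the pulse-like crest (whose sample-to-sample
# differences would otherwise trip the jump detector in every segment).
#' @noRd
bandlimited_pulse_train <- function(stim, fs, duration, k_max = 20L) {
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  f <- stim$frequency
  pw <- stim$pulse_width * 1e-6
  ks <- seq_len(min(k_max, floor((fs / 2 - 1) / f)))
  ck <- (4 / (pi * ks)) * sin(pi * ks * f * pw)^2
  ck <- ck / ck[1]
  phases <- 2 * pi * ((ks * (sqrt(5) - 1) / 2) %% 1)
  phases[1] <- 0
  out <- numeric(n)
  for (k in ks) out <- out + ck[k] * cos(2 * pi * k * f * t + phases[k])
  out
}

#' @noRd
toggle_mask <- function(toggle, t, duration) {
  if (is.null(toggle))
    return(list(mask = 1, mask_slow = 1, on = 0, off = duration))
  on <- toggle$start_s + (0:(toggle$n_cycles - 1)) * (toggle$on_s + toggle$off_s)
  off <- on + toggle$on_s
  mask <- numeric(length(t))
  for (j in seq_along(on)) mask[t >= on[j] & t < off[j]] <- 1
  list(mask = mask, mask_slow = mask, on = on, off = off)
}

# Evenly subsampled channel subset of the full array.
#' @noRd
select_channels <- function(profile, n_channels) {
  geo <- profile$geometry
  if (is.null(n_channels) || n_channels >= nrow(geo)) return(geo)
  if (profile$name == "megin") {
    n_mag <- max(1L, round(n_channels / 3))
    n_grad <- n_channels - n_mag
    mags <- geo[geo$type == "mag", ]
    grads <- geo[geo$type == "planar_grad", ]
    pick <- function(d, k) d[unique(round(seq(1, nrow(d), length.out = k))), ]
    out <- rbind(pick(grads, n_grad), pick(mags, n_mag))
  } else {
    out <- geo[unique(round(seq(1, nrow(geo), length.out = n_channels))), ]
  }
  rownames(out) <- NULL
  out
}

# Dipole-field topography normalised to max |gain| = 1 within each sensor
# type, so per-type amplitude calibration stays meaningful. Sources inside
# the conductor sphere use the Sarvas field; distant sources (the implant in
# the chest) use a free-space magnetic dipole.
#' @noRd
normalized_dipole_topography <- function(meta, pos, free_space = FALSE) {
  n_ch <- nrow(meta)
  g <- numeric(n_ch)
  moment <- c(0.7, 0.7, 0.14)          # mostly tangential
  for (ch in seq_len(n_ch)) {
    p <- as.numeric(meta[ch, c("px", "py", "pz")])
    o <- as.numeric(meta[ch, c("ox", "oy", "oz")])
    B <- if (free_space) dipole_field_free(p, pos, moment)
         else sarvas_field(p, pos, moment)
    val <- switch(meta$type[ch],
      axial_grad = {
        B2 <- if (free_space) dipole_field_free(p + 0.05 * o, pos, moment)
              else sarvas_field(p + 0.05 * o, pos, moment)
        sum((B - B2) * o)
      },
      planar_grad = {
        pd <- as.numeric(meta[ch, c("dx", "dy", "dz")])
        Bp <- if (free_space) dipole_field_free(p + 0.0084 * pd, pos, moment)
              else sarvas_field(p + 0.0084 * pd, pos, moment)
        Bm <- if (free_space) dipole_field_free(p - 0.0084 * pd, pos, moment)
              else sarvas_field(p - 0.0084 * pd, pos, moment)
        sum((Bp - Bm) * o) / 16.8
      },
      sum(B * o)
    )
    g[ch] <- val
  }
  for (type in unique(meta$type)) {
    idx <- meta$type == type
    m <- max(abs(g[idx]))
    if (m > 0) g[idx] <- g[idx] / m
    # keep every channel responsive enough for detection targets
    low <- idx & abs(g) < 0.3
    g[low] <- sign(g[low] + 1e-12) * 0.3
  }
  g
}

# Free-space magnetic point dipole (for the distant ferromagnetic implant).
#' @noRd
dipole_field_free <- function(r, r0, m) {
  d <- r - r0
  dist <- sqrt(sum(d^2))
  rh <- d / dist
  1e-7 * (3 * sum(m * rh) * rh - m) / dist^3 * 1e15
}

#' Resample an LFP stream onto a drifting clock
#'
#' Applies the affine clock model `t_lfp = offset + rate * t_meg`: the
#' returned stream's nominal sample times correspond to MEG times
#' `(t_nom - offset) / rate`, so an event at MEG time T appears in the LFP at
#' nominal time `offset + rate * T`. The ground-truth map is recorded in the
#' stream's `clock` field.
#'
#' @param lfp An `lfp_stream` on the MEG time base.
#' @param offset Clock offset, s.
#' @param rate Clock rate ratio (|rate - 1| < 1e-3).
#' @return A new `lfp_stream`.
#' @export
inject_clock_drift <- function(lfp, offset, rate) {
  stopifnot(inherits(lfp, "lfp_stream"))
  if (abs(rate - 1) >= 1e-3) stop("|rate - 1| must be < 1e-3")
  if (offset == 0 && rate == 1) {
    lfp$clock <- list(offset = 0, rate = 1)
    return(lfp)
  }
  n <- ncol(lfp$data)
  t_nom <- (0:(n - 1)) / lfp$fs
  t_src <- (t_nom - offset) / rate
  out <- lfp
  for (ch in 1:2)
    out$data[ch, ] <- sinc_interp(lfp$data[ch, ], lfp$fs, t_src)
  out$clock <- list(offset = offset, rate = rate)
  out
}

# LFP stream generated on the MEG clock, then shifted onto its own clock.
#' @noRd
build_lfp_stream <- function(cond, duration, seed, src_signal = NULL,
                             tog = NULL, fs_lfp = 250, fs_meg = NULL) {
  n <- round(duration * fs_lfp)
  t <- (0:(n - 1)) / fs_lfp
  data <- matrix(0, 2, n)
  with_sub_seed(seed, "lfp_noise", {
    for (ch in 1:2)
      data[ch, ] <- 4 * stats::rnorm(n) +
        8 * fft_bandpass(stats::rnorm(n), fs_lfp, 3, 45)
  })
  stim <- cond$stim
  if (stim$mode %in% c("monopolar", "bipolar") &&
      (stim$amplitude > 0 || cond$streaming)) {
    mask <- if (is.null(tog) || length(tog$mask) == 1) 1 else {
      m <- numeric(n)
      for (j in seq_along(tog$on)) m[t >= tog$on[j] & t < tog$off[j]] <- 1
      m
    }
    with_sub_seed(seed, "lfp_stim", {
      # pulse-train harmonics folded below the LFP Nyquist
      for (k in 1:6) {
        fk <- alias_freq(k * stim$frequency, fs_lfp)
        if (fk < 1) next
        amp <- 60 / k * max(stim$amplitude, 0.5) / 5
        ph <- stats::runif(1, 0, 2 * pi)
        wave <- amp * cos(2 * pi * fk * t + ph) * mask
        data[1, ] <- data[1, ] + wave
        data[2, ] <- data[2, ] + wave
      }
    })
  }
  if (isTRUE(cond$lfp_ecg)) {
    ecg <- ecg_waveform(fs_lfp, duration, hr = 68, seed = sub_seed(seed, "ecg"))
    data[1, ] <- data[1, ] + 25 * ecg
    data[2, ] <- data[2, ] + 18 * ecg
  }
  if (!is.null(cond$source) && !is.null(src_signal)) {
    src <- cond$source
    gam <- src$coherence
    shared <- with_sub_seed(seed, "lfp_shared", {
      # band-limited projection of the cortical source onto the LFP clock
      idx <- pmin(length(src_signal),
                  pmax(1, round(t * (length(src_signal) / duration)) + 1))
      s <- src_signal[idx]
      fft_bandpass(s, fs_lfp, src$freq - src$bandwidth / 2,
                   src$freq + src$bandwidth / 2)
    })
    indep <- with_sub_seed(seed, "lfp_indep", {
      fft_bandpass(stats::rnorm(n), fs_lfp, src$freq - src$bandwidth / 2,
                   src$freq + src$bandwidth / 2)
    })
    osc <- sqrt(gam) * shared / stats::sd(shared) +
      sqrt(1 - gam) * indep / stats::sd(indep)
    data[2, ] <- data[2, ] + 10 * osc
  }
  lfp <- new_lfp_stream(data, fs = fs_lfp,
                        truth = list(stim_on = if (!is.null(tog)) tog$on,
                                     stim_off = if (!is.null(tog)) tog$off))
  clk <- cond$clock %||% list(offset = 0, rate = 1)
  inject_clock_drift(lfp, clk$offset, clk$rate)
}

#' Synthetic ECG-like waveform
#'
#' Train of QRS-like biphasic transients with slight beat-to-beat jitter;
#' used to emulate cardiac contamination of the LFP stream and as a surface
#' ECG template for alignment tests.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Duration, s.
#' @param hr Heart rate, beats per minute.
#' @param seed Optional integer seed for jitter.
#' @return Numeric waveform (unit peak).
#' @export
ecg_waveform <- function(fs, duration, hr = 70, seed = NULL) {
  gen <- function() {
    n <- round(duration * fs)
    t <- (0:(n - 1)) / fs
    period <- 60 / hr
    beats <- seq(0.3, duration - 0.3, by = period)
    beats <- beats + stats::rnorm(length(beats), 0, 0.02)
    x <- numeric(n)
    for (b in beats) {
      d <- t - b
      x <- x + exp(-(d / 0.012)^2) - 0.35 * exp(-((d - 0.03) / 0.02)^2) -
        0.2 * exp(-((d + 0.025) / 0.02)^2) +
        0.15 * exp(-((d - 0.25) / 0.06)^2)   # T wave
    }
    x / max(abs(x))
  }
  if (is.null(seed)) gen() else with_sub_seed(seed, "ecg", gen())
}
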
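#' Jump-robust transform for severely contaminated channels
#'
#' Log-magnitude of the first difference, `y[i] = log(|x[i+1] - x[i]| + eps)`,
#' which compresses SQUID flux jumps and large stimulation transients into a
#' common range so stimulation on/off boundaries become visible. `eps` is
#' tied to the robust scale of the input (1e-12 x MAD), making the transform
#' invariant to the channel's units.
#'
#' @param x Numeric waveform (length >= 2).
#' @return Numeric waveform of length `length(x) - 1`.
#' @export
jump_robust_transform <- function(x) {
  if (length(x) < 2) stop("input must have at least 2 samples")
  d <- abs(diff(x))
  scale <- robust_sd(x)
  if (scale == 0) scale <- 1
  log(d + 1e-12 * scale)
}

#' Detect stimulation on/off edges
#'
#' Extracts the envelope of the signal in a narrow band around the
#' stimulation frequency (+/- 5 Hz), smooths it over 100 ms, and finds
#' crossings of the midpoint between the 10th and 90th envelope percentiles
#' with hysteresis. Channels carrying step discontinuities (detected from the
#' diff-MAD) are passed through [jump_robust_transform()] first. Frequencies
#' at or above the Nyquist are folded to their alias (relevant for the
#' telemetered LFP, where a 145 Hz artefact appears at 105 Hz).
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate, Hz.
#' @param f_stim Stimulation frequency, Hz.
#' @return Object of class `edge_list`: data frame with `time` (s),
#'   `polarity` (`"on"`/`"off"`), `confidence` (envelope dynamic range, dB).
#'   Empty when no toggling is present; errors when the envelope dynamic
#'   range is below 6 dB.
#' @export
detect_stim_edges <- function(x, fs, f_stim) {
  f_eff <- if (f_stim >= fs / 2) alias_freq(f_stim, fs) else f_stim
  # isolated extreme first differences (flux jumps) send the channel through
  # the robust log-transform; a toggled stimulation artefact alone produces
  # large but *frequent* diffs and stays on the band-envelope path
  d <- abs(diff(x))
  q999 <- stats::quantile(d, 0.999, names = FALSE)
  if (q999 > 0 && max(d) > 10 * q999) {
    # envelope = smoothed log |diff| level; dynamic range measured in the
    # underlying diff-magnitude ratio
    env <- moving_average(jump_robust_transform(x), round(0.1 * fs))
    q <- stats::quantile(env, c(0.1, 0.9), names = FALSE)
    dyn_db <- 20 * (q[2] - q[1]) / log(10)
  } else {
    xb <- fft_bandpass(x, fs, max(f_eff - 5, 1), min(f_eff + 5, fs / 2 - 1))
    env <- moving_average(analytic_envelope(xb), round(0.1 * fs))
    q <- stats::quantile(env, c(0.1, 0.9), names = FALSE)
    if (q[1] <= 0) q[1] <- .Machine$double.eps
    dyn_db <- 20 * log10(q[2] / q[1])
  }
  # toggling shows a bimodal envelope: few samples dwell mid-range
  r <- q[2] - q[1]
  mid_frac <- mean(env > q[1] + r / 3 & env < q[2] - r / 3)
  if (dyn_db < 6 || mid_frac > 0.25) {
    return(structure(data.frame(time = numeric(), polarity = character(),
                                confidence = numeric()),
                     class = c("edge_list", "data.frame"),
                     note = "no toggling detected (envelope dynamic range < 6 dB or unimodal envelope)"))
  }
  mid <- (q[1] + q[2]) / 2
  hyst <- 0.25 * (q[2] - q[1])
  state <- env[1] > mid
  times <- numeric(0)
  pol <- character(0)
  i <- 2L
  n <- length(env)
  while (i <= n) {
    if (!state && env[i] > mid + hyst) {
      state <- TRUE
      j <- i; while (j > 1 && env[j - 1] > mid) j <- j - 1
      times <- c(times, (j - 1) / fs); pol <- c(pol, "on")
    } else if (state && env[i] < mid - hyst) {
      state <- FALSE
      j <- i; while (j > 1 && env[j - 1] < mid) j <- j - 1
      times <- c(times, (j - 1) / fs); pol <- c(pol, "off")
    }
    i <- i + 1L
  }
  structure(data.frame(time = times, polarity = pol,
                       confidence = rep(dyn_db, length(times))),
            class = c("edge_list", "data.frame"))
}

#' Fit an affine clock map from paired event lists
#'
#' Least-squares fit of `t_lfp = offset + rate * t_meg` over events paired by
#' rank order and polarity (assumes no missed or spurious edges after
#' confidence filtering). With exactly two events the fit interpolates them
#' exactly. At least two markers, one near each end of the recording, are
#' needed to separate offset from drift.
#'
#' @param meg_events,lfp_events `edge_list` objects (or data frames with
#'   `time` and `polarity`) with equal event counts >= 2.
#' @return Object of class `clock_map`: list with `offset` (s), `rate`,
#'   `residuals` (s, per event), `n_events`.
#' @export
fit_clock_map <- function(meg_events, lfp_events) {
  tm <- meg_events$time
  tl <- lfp_events$time
  if (length(tm) != length(tl)) {
    stop("event counts differ (MEG ", length(tm), ", LFP ", length(tl),
         "); unpaired events at ",
         paste(round(utils::tail(if (length(tm) > length(tl)) tm else tl,
                                 abs(length(tm) - length(tl))), 3),
               collapse = ", "), " s")
  }
  if (length(tm) < 2) stop("need at least 2 paired events to fit a clock map")
  if (!is.null(meg_events$polarity) && !is.null(lfp_events$polarity) &&
      !all(meg_events$polarity == lfp_events$polarity))
    stop("event polarities do not match after rank pairing")
  fit <- stats::lm.fit(cbind(1, tm), tl)
  map <- structure(list(offset = unname(fit$coefficients[1]),
                        rate = unname(fit$coefficients[2]),
                        residuals = unname(fit$residuals),
                        n_events = length(tm)),
                   class = "clock_map")
  if (abs(map$rate - 1) >= 1e-3)
    warning("fitted clock rate ", format(map$rate),
            " is implausibly far from 1")
  map
}

#' @export
print.clock_map <- function(x, ...) {
  cat(sprintf("<clock_map> t_lfp = %.6f + %.9f * t_meg (%d events, RMS residual %.2g s)\n",
              x$offset, x$rate, x$n_events, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Resample an LFP stream onto the MEG clock
#'
#' Band-limited (windowed-sinc) interpolation of the LFP onto the MEG time
#' grid using a fitted [fit_clock_map()]: the sample at MEG time `t` is read
#' from the LFP at nominal time `offset + rate * t`. An anti-alias low-pass
#' is applied first when `target_fs < lfp$fs`.
#'
#' @param lfp An `lfp_stream` (or a single numeric waveform with attribute-free
#'   interpretation at `lfp_fs`).
#' @param map A `clock_map`.
#' @param target_fs Output sampling rate on the MEG clock, Hz.
#' @param duration Output duration, s (default: full overlap).
#' @return Matrix 2 x samples (or vector for vector input) on the MEG clock.
#' @export
resample_to_meg_clock <- function(lfp, map, target_fs, duration = NULL) {
  stopifnot(inherits(lfp, "lfp_stream"), inherits(map, "clock_map"))
  if (abs(map$rate - 1) >= 1e-3) stop("clock map rate outside invariant bounds")
  lfp_dur <- ncol(lfp$data) / lfp$fs
  if (is.null(duration)) duration <- (lfp_dur - map$offset) / map$rate
  t_meg <- seq(0, duration, by = 1 / target_fs)
  t_meg <- t_meg[t_meg < duration]
  t_lfp <- map$offset + map$rate * t_meg
  if (min(t_lfp) < -1 || max(t_lfp) > lfp_dur + 1)
    stop("clock map extrapolates more than 1 s beyond the LFP support")
  dat <- lfp$data
  if (target_fs < lfp$fs) {
    for (ch in 1:2)
      dat[ch, ] <- fft_lowpass(dat[ch, ], lfp$fs, 0.45 * target_fs)
  }
  out <- matrix(0, 2, length(t_meg))
  for (ch in 1:2) out[ch, ] <- sinc_interp(dat[ch, ], lfp$fs, t_lfp)
  rownames(out) <- rownames(lfp$data)
  out
}

#' Align two signals by cross-correlation (ECG method)
#'
#' Lag of the peak of the normalised cross-correlation between an
#' ECG-contaminated LFP and a surface ECG recorded on the MEG clock, both at
#' a common sampling rate. Useful when stimulation toggling is unavailable;
#' works only when the cardiac artefact is strong enough, so a confidence
#' ratio (main peak over next-highest peak outside its 250 ms neighbourhood)
#' is reported and a warning is raised below 1.2.
#'
#' @param lfp Numeric waveform.
#' @param ecg Numeric waveform at the same sampling rate.
#' @param fs Common sampling rate, Hz.
#' @param max_lag Maximum lag searched, s (default 30).
#' @return List with `lag` (s; positive when `lfp` lags `ecg`), `confidence`.
#' @export
ecg_xcorr_lag <- function(lfp, ecg, fs, max_lag = 30) {
  n_overlap <- min(length(lfp), length(ecg))
  if (n_overlap / fs < 10) stop("signals must overlap by at least 10 s")
  a <- lfp - mean(lfp)
  b <- ecg - mean(ecg)
  n <- length(a) + length(b) - 1L
  nfft <- stats::nextn(n, c(2, 3, 5))
  A <- stats::fft(c(a, numeric(nfft - length(a))))
  B <- stats::fft(c(b, numeric(nfft - length(b))))
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / nfft
  # lag k: a[t] ~ b[t - k]; wrap negative lags from the tail
  lags <- c(0:(nfft %/% 2), -((nfft - nfft %/% 2 - 1):1)) / fs
  ok <- abs(lags) <= max_lag
  cc <- cc[ok]; lags <- lags[ok]
  norm <- sqrt(sum(a^2) * sum(b^2))
  cc <- cc / norm
  i_pk <- which.max(cc)
  excl <- abs(lags - lags[i_pk]) < 0.25
  runner <- max(cc[!excl])
  confidence <- if (runner > 0) cc[i_pk] / runner else Inf
  if (confidence < 1.2)
    warning("alignment unreliable: cross-correlation confidence ",
            round(confidence, 2), " < 1.2")
  list(lag = lags[i_pk], confidence = confidence)
}

#' Detect mechanical tap transients
#'
#' Broadband-envelope variant of the stimulation edge detector for alignment
#' by tapping on the implant: transients exceeding `threshold_k` times the
#' robust envelope scale are reported. Reliable only for impacts well above
#' the noise floor (>= 10x noise SD); weaker taps are not claimed.
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate, Hz.
#' @param threshold_k Detection threshold in robust envelope SDs (default 8).
#' @return Numeric vector of transient times, s.
#' @export
detect_taps <- function(x, fs, threshold_k = 8) {
  env <- moving_average(abs(x - stats::median(x)), round(0.02 * fs))
  thr <- stats::median(env) + threshold_k * robust_sd(env)
  above <- env > thr
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onsets <- starts[r$values]
  # merge events closer than 100 ms
  keep <- c(TRUE, diff(onsets) > 0.1 * fs)
  (onsets[keep] - 1) / fs
}
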
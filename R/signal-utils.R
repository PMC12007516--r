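# Internal DSP primitives shared across modules. All filtering is done with
# zero-phase FFT masks: recordings here are long, stationary segments where
# circular edge effects are negligible compared to artefact amplitudes.

#' @keywords internal
#' @noRd
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

# Apply a gain function of |frequency| in the Fourier domain.
#' @noRd
fft_apply_gain <- function(x, fs, gain_fun) {
  n <- length(x)
  if (n == 0L) return(x)
  g <- gain_fun(abs(fft_freqs(n, fs)))
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

#' @noRd
fft_bandpass <- function(x, fs, lo, hi) {
  fft_apply_gain(x, fs, function(f) as.numeric(f >= lo & f <= hi))
}

#' @noRd
fft_notch <- function(x, fs, f0, half_width = 2) {
  fft_apply_gain(x, fs, function(f) as.numeric(abs(f - f0) > half_width))
}

#' @noRd
fft_lowpass <- function(x, fs, cutoff) {
  fft_apply_gain(x, fs, function(f) as.numeric(f <= cutoff))
}

# Magnitude of the analytic signal (FFT Hilbert transform).
#' @noRd
analytic_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Centered moving average with edge shrinkage (window truncated at the ends).
#' @noRd
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L || length(x) < 2L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- k %/% 2
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Running median with odd window, endpoints handled by stats::runmed.
#' @noRd
running_median <- function(x, k) {
  k <- as.integer(k)
  if (k %% 2 == 0L) k <- k + 1L
  k <- min(k, if (length(x) %% 2 == 0L) length(x) - 1L else length(x))
  if (k < 3L) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# Running quantile over a centred window (truncated at the ends).
#' @noRd
running_quantile <- function(x, k, prob = 0.25) {
  k <- max(3L, as.integer(k))
  n <- length(x)
  half <- k %/% 2
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    stats::quantile(w, prob, names = FALSE, type = 7)
  }, numeric(1))
}

# Windowed-sinc interpolation of x (sampled at fs, first sample at t = 0)
# onto arbitrary times t_new (seconds). Values outside the support decay to 0.
# Exact at integer sample points because sinc(0)=1, sinc(k)=0.
#' @noRd
sinc_interp <- function(x, fs, t_new, half_taps = 12L) {
  n <- length(x)
  pos <- t_new * fs                     # fractional sample index (0-based)
  base <- floor(pos)
  frac <- pos - base
  out <- numeric(length(t_new))
  # exact hit fast path keeps identity maps bit-clean
  hit <- frac < 1e-12 & base >= 0 & base < n
  out[hit] <- x[base[hit] + 1]
  todo <- which(!hit)
  if (length(todo)) {
    for (j in seq(-half_taps + 1L, half_taps)) {
      idx <- base[todo] + j
      d <- pos[todo] - idx
      w <- sinc(d) * hann_tap(d / half_taps)
      ok <- idx >= 0 & idx < n
      out[todo[ok]] <- out[todo[ok]] + x[idx[ok] + 1] * w[ok]
    }
  }
  out
}

#' @noRd
sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))

#' @noRd
hann_tap <- function(u) ifelse(abs(u) >= 1, 0, 0.5 * (1 + cos(pi * u)))

#' @noRd
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))  # periodic-free symmetric-ish
}

# Robust scale (MAD, normal-consistent).
#' @noRd
robust_sd <- function(x) stats::mad(x, constant = 1.4826)

# Deterministic 31-bit sub-seed per (root seed, label); keeps artefact sources
# on independent reproducible streams so toggling one leaves others untouched.
#' @noRd
sub_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' @noRd
with_sub_seed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(sub_seed(seed, label))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  })
  force(expr)
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Fold a frequency into (0, fs/2] by aliasing.
#' @noRd
alias_freq <- function(f, fs) {
  f <- abs(f) %% fs
  ifelse(f > fs / 2, fs - f, f)
}
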
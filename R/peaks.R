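#' Detect narrowband spectral peaks
#'
#' A peak is a local maximum of the (median) ASD exceeding a running baseline
#' by at least `min_prominence` dB. Adjacent supra-threshold bins are merged
#' into a single peak whose frequency is reported at the maximum bin and
#' whose width is measured at half prominence. The baseline is a running
#' lower quartile rather than a median: in a dense harmonic comb the taper
#' mainlobes occupy a large fraction of bins and would drag a median
#' baseline up to the peak shoulders, masking the comb itself.
#'
#' @param spec A `median_spectrum` or `spectrum_set` (the median across all
#'   channels is used, and per-peak channel support is counted).
#' @param baseline_window Running-baseline window, Hz (default 5).
#' @param min_prominence Minimum prominence over baseline, dB (default 6).
#' @param fmax Ignore bins above this frequency (default 250 Hz; the
#'   characterisation focuses on 0-200 Hz).
#' @return Object of class `peak_table`: data frame with columns `freq` (Hz),
#'   `prominence_db`, `width_hz`, `n_channels` (channels supporting the peak
#'   at half the detection prominence; `NA` when a bare curve was supplied).
#' @export
detect_peaks <- function(spec, baseline_window = 5, min_prominence = 6,
                         fmax = 250) {
  if (inherits(spec, "spectrum_set")) spec <- median_spectrum(spec)
  stopifnot(inherits(spec, "median_spectrum"))
  df <- spec$freqs[2] - spec$freqs[1]
  if (df > 0.5)
    stop("spectral resolution ", df, " Hz is too coarse for peak detection; ",
         "use segments of at least 2 s")
  sel <- spec$freqs > 0 & spec$freqs <= fmax
  f <- spec$freqs[sel]
  a <- spec$asd[sel]
  a_db <- 20 * log10(pmax(a, .Machine$double.xmin))
  k <- max(3L, round(baseline_window / df))
  base_db <- running_quantile(a_db, k, prob = 0.25)
  prom <- a_db - base_db
  above <- prom >= min_prominence
  out <- data.frame(freq = numeric(), prominence_db = numeric(),
                    width_hz = numeric(), n_channels = integer())
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      bins <- starts[i]:ends[i]
      pk <- bins[which.max(a_db[bins])]
      # require a true local maximum within the cluster
      lo <- max(1L, pk - 1L); hi <- min(length(a_db), pk + 1L)
      if (a_db[pk] < max(a_db[lo:hi])) next
      half <- base_db[pk] + prom[pk] / 2
      wl <- pk; while (wl > 1L && a_db[wl - 1L] > half) wl <- wl - 1L
      wr <- pk; while (wr < length(a_db) && a_db[wr + 1L] > half) wr <- wr + 1L
      n_sup <- NA_integer_
      if (!is.null(spec$channel_asd) && nrow(spec$channel_asd) > 1) {
        ch_db <- 20 * log10(pmax(spec$channel_asd[, which(sel)[pk]],
                                 .Machine$double.xmin))
        ch_base <- 20 * log10(pmax(10^(base_db[pk] / 20) *
          spec$channel_asd[, which(sel)[pk]] / pmax(a[pk], .Machine$double.xmin),
          .Machine$double.xmin))
        n_sup <- sum(ch_db - ch_base >= min_prominence / 2, na.rm = TRUE)
      }
      out <- rbind(out, data.frame(freq = f[pk], prominence_db = prom[pk],
                                   width_hz = (wr - wl + 1L) * df,
                                   n_channels = n_sup))
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("peak_table", "data.frame"),
            resolution = df)
}

#' Remove mains-line bins from a peak table
#'
#' Drops peaks within `tol` of any multiple of the given line frequencies
#' (default both 50 Hz and 60 Hz families), the standard pre-filter before
#' comb estimation and condition classification.
#'
#' @param peaks A `peak_table`.
#' @param line_freqs Base line frequencies, Hz.
#' @param fmax Highest harmonic considered.
#' @param tol Matching tolerance, Hz (default one resolution bin).
#' @return Filtered `peak_table`.
#' @export
exclude_line_peaks <- function(peaks, line_freqs = c(50, 60), fmax = 250,
                               tol = NULL) {
  if (is.null(tol)) tol <- attr(peaks, "resolution") %||% 0.5
  if (nrow(peaks) == 0) return(peaks)
  lines <- unique(unlist(lapply(line_freqs, function(f)
    seq(f, fmax, by = f))))
  bad <- vapply(peaks$freq, function(f) any(abs(f - lines) <= tol + 1e-9),
                logical(1))
  out <- peaks[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(peaks), resolution = attr(peaks, "resolution"))
}

#' Estimate a harmonic-comb fundamental from detected peaks
#'
#' Grid search over candidate fundamentals: each candidate is scored by the
#' number of peaks lying within `tolerance` of one of its integer multiples.
#' Ties are broken towards the larger fundamental (otherwise near-unit
#' fundamentals trivially explain everything).
#'
#' @param peaks A `peak_table` (>= 1 row).
#' @param f0_range Length-2 numeric, candidate fundamental interval, Hz.
#' @param tolerance Matching tolerance, Hz (default 0.2); the candidate grid
#'   step is `tolerance / 2`.
#' @return Object of class `comb_estimate`: list with `fundamental`,
#'   `matched_harmonics`, `coverage` (fraction of peaks explained).
#' @examples
#' pt <- structure(data.frame(freq = c(14.3, 28.6, 42.9, 57.2),
#'                            prominence_db = 20, width_hz = 0.3,
#'                            n_channels = NA),
#'                 class = c("peak_table", "data.frame"))
#' estimate_comb(pt, c(5, 30))
#' @export
estimate_comb <- function(peaks, f0_range, tolerance = 0.2) {
  if (nrow(peaks) == 0) stop("peak table is empty")
  f <- sort(peaks$freq)
  cand <- seq(f0_range[1], f0_range[2], by = tolerance / 2)
  stats_for <- function(f0) {
    k <- pmax(1, round(f / f0))
    dev <- abs(f - k * f0)
    hit <- dev <= tolerance + 1e-9
    c(sum(hit), sum(dev[hit]))
  }
  s <- vapply(cand, stats_for, numeric(2))
  best <- max(s[1, ])
  top <- which(s[1, ] == best)
  # secondary criterion: smallest total deviation; then larger fundamental
  top <- top[s[2, top] <= min(s[2, top]) + 1e-9]
  f0 <- max(cand[top])
  structure(list(fundamental = f0, matched_harmonics = as.integer(best),
                 coverage = best / length(f)),
            class = "comb_estimate")
}

#' @export
print.comb_estimate <- function(x, ...) {
  cat(sprintf("<comb_estimate> fundamental %.2f Hz (%d harmonics, %.0f%% of peaks)\n",
              x$fundamental, x$matched_harmonics, 100 * x$coverage))
  invisible(x)
}

#' Predict intermodulation product frequencies
#'
#' Difference-type intermodulation products `|n f_stim - m f_mod|` of a
#' stimulation pulse train and a sensor modulation tone under a polynomial
#' nonlinearity, aliased into `(0, fs/2]`, deduplicated at 0.1 Hz and sorted.
#' Sum products are omitted: they fall above the 200 Hz characterisation
#' ceiling.
#'
#' @param f_stim Stimulation frequency, Hz.
#' @param f_mod Modulation frequency, Hz.
#' @param fs Sampling rate, Hz (for aliasing).
#' @param n_max Maximum stimulation harmonic order.
#' @param m_max Maximum modulation harmonic order.
#' @param f_ceiling Only products at or below this frequency are returned.
#' @return Sorted numeric vector of product frequencies, Hz.
#' @examples
#' predict_intermod(145, 923, fs = 6000, n_max = 14, m_max = 2)
#' @export
predict_intermod <- function(f_stim, f_mod, fs, n_max = 14, m_max = 2,
                             f_ceiling = 200) {
  stopifnot(f_stim > 0, f_mod > 0)
  if (m_max < 1 || n_max < 1) return(numeric(0))
  prods <- c(outer(seq_len(n_max) * f_stim, seq_len(m_max) * f_mod, "-"))
  f <- alias_freq(prods, fs)
  f <- f[f > 1e-9 & f <= f_ceiling]
  sort(unique(round(f, 1)))
}

#' Expected spectral signatures of the artefact sources
#'
#' Library of expected peak sets per artefact source, used by
#' [classify_condition()]. Each signature lists the deterministic peak
#' frequencies that source injects for a given system profile.
#'
#' @param profile A `system_profile`.
#' @param fmax Consider peaks up to this frequency (default 200 Hz).
#' @return Named list of numeric frequency vectors, class
#'   `signature_library`.
#' @export
signature_library <- function(profile, fmax = 200) {
  mk_cond <- function(name) condition_spec(name)
  f_stim <- 145
  legacy_str <- condition_tone_plan(profile, mk_cond("legacy_streaming"))
  # the dense streaming comb decays as 1/n; only its sub-50 Hz members stay
  # reliably detectable, and that range is where the comb is densest
  legacy_str <- legacy_str[legacy_str$source != "legacy_streaming_comb" |
                             legacy_str$freq < 50, ]
  lib <- list(
    sensight_telemetry = condition_tone_plan(profile, mk_cond("sensight_streaming")),
    legacy_telemetry_open = condition_tone_plan(profile, mk_cond("legacy_open")),
    legacy_streaming = legacy_str,
    communicator = condition_tone_plan(profile, mk_cond("communicator_near")),
    stim_bipolar = rbind(
      data.frame(source = "stim", freq = f_stim, rel_db = 40),
      condition_tone_plan(profile, mk_cond("bipolar"))),
    stim_monopolar = rbind(
      data.frame(source = "stim", freq = f_stim, rel_db = 55),
      condition_tone_plan(profile, mk_cond("monopolar")))
  )
  sigs <- lapply(lib, function(d) sort(unique(d$freq[d$freq <= fmax])))
  if (!is.null(profile$opm_modulation_freq)) {
    fmod <- profile$opm_modulation_freq
    quad <- predict_intermod(f_stim, fmod, profile$fs, n_max = 8, m_max = 1,
                             f_ceiling = fmax)
    cubic <- setdiff(predict_intermod(f_stim, fmod, profile$fs, n_max = 14,
                                      m_max = 2, f_ceiling = fmax), quad)
    # quadratic products are visible whenever stimulation is on; the weaker
    # cubic family only emerges under the high-amplitude monopolar path
    sigs$stim_bipolar <- sort(unique(c(sigs$stim_bipolar, quad)))
    sigs$stim_monopolar <- sort(unique(c(sigs$stim_monopolar, quad, cubic)))
  }
  sigs <- sigs[vapply(sigs, length, integer(1)) > 0]
  structure(sigs, class = "signature_library",
            exclusive = list(telemetry = c("sensight_telemetry",
                                           "legacy_telemetry_open",
                                           "legacy_streaming"),
                             stim = c("stim_bipolar", "stim_monopolar")))
}

#' Classify which artefact sources are active
#'
#' Scores each source in the library by the fraction of its expected peaks
#' found in the table within `tol`. Sources scoring at least `threshold` are
#' reported active; mutually exclusive telemetry modes are resolved in favour
#' of the highest score (larger matched count on ties). Mains-line peaks are
#' excluded before matching.
#'
#' @param peaks A `peak_table`.
#' @param lib A [signature_library()].
#' @param tol Frequency tolerance, Hz (default 0.5).
#' @param threshold Activation threshold on the match score (default 0.8).
#' @return Data frame with `source`, `score`, `n_expected`, `n_found`,
#'   `active`.
#' @export
classify_condition <- function(peaks, lib, tol = 0.5, threshold = 0.8) {
  if (length(lib) == 0) stop("signature library is empty")
  peaks <- exclude_line_peaks(peaks)
  found <- peaks$freq
  res <- do.call(rbind, lapply(names(lib), function(src) {
    expect <- lib[[src]]
    hit <- vapply(expect, function(f) any(abs(found - f) <= tol),
                  logical(1))
    data.frame(source = src, score = mean(hit),
               n_expected = length(expect), n_found = sum(hit))
  }))
  res$active <- res$score >= threshold
  for (group in attr(lib, "exclusive")) {
    excl <- intersect(group, res$source[res$active])
    if (length(excl) > 1) {
      # the candidate explaining more peaks wins (a subset signature always
      # scores at least as high as its superset); score breaks ties
      sub <- res[res$source %in% excl, ]
      best <- sub$source[order(-sub$n_found, -sub$score)][1]
      res$active[res$source %in% setdiff(excl, best)] <- FALSE
    }
  }
  rownames(res) <- NULL
  res
}
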
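#' Flag segments containing flat stretches or discontinuous jumps
#'
#' Scans the recording on the same segmentation the Welch estimator uses
#' (segments of `segment_length` s at 50% overlap) and rejects, per channel,
#' any segment containing a run of at least `flat_len` identical samples
#' (reason `"flat"`) or any first difference exceeding `jump_k` times the
#' normal-consistent median absolute deviation of that channel's first
#' differences (reason `"jump"`). This is the cleaning step required for
#' cryogenic recordings contaminated by SQUID flux jumps.
#'
#' @param rec A `meg_recording`.
#' @param flat_len Minimum run length of identical samples to reject (>= 2).
#' @param jump_k Threshold multiplier on the diff-MAD (default 20).
#' @param segment_length Segment length, s (default 3, matching [welch_asd()]).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return Object of class `segment_mask`: list with logical `keep`
#'   (channels x segments), character `reason` (same shape, `NA` where kept),
#'   and the segmentation parameters.
#' @export
reject_bad_segments <- function(rec, flat_len = 10, jump_k = 20,
                                segment_length = 3, overlap = 0.5) {
  stopifnot(inherits(rec, "meg_recording"))
  if (flat_len < 2) stop("flat_len must be >= 2")
  n <- ncol(rec$data)
  if (n < 2) stop("recording is empty or too short")
  seg <- segment_starts(n, rec$fs, segment_length, overlap)
  n_seg <- length(seg$starts)
  n_ch <- nrow(rec$data)
  keep <- matrix(TRUE, n_ch, n_seg)
  reason <- matrix(NA_character_, n_ch, n_seg)
  for (ch in seq_len(n_ch)) {
    d <- diff(rec$data[ch, ])
    mad_d <- robust_sd(d)
    jump_idx <- if (mad_d > 0) which(abs(d) > jump_k * mad_d) else integer(0)
    flat_idx <- integer(0)
    r <- rle(d == 0)
    if (any(r$values & r$lengths >= flat_len - 1)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      sel <- which(r$values & r$lengths >= flat_len - 1)
      flat_idx <- unlist(lapply(sel, function(i) starts[i]:ends[i]))
    }
    if (length(jump_idx) == 0 && length(flat_idx) == 0) next
    for (s in seq_len(n_seg)) {
      lo <- seg$starts[s]
      hi <- lo + seg$len - 1L
      has_jump <- any(jump_idx >= lo & jump_idx < hi)
      has_flat <- any(flat_idx >= lo & flat_idx < hi)
      if (has_jump || has_flat) {
        keep[ch, s] <- FALSE
        reason[ch, s] <- if (has_jump) "jump" else "flat"
      }
    }
  }
  structure(list(keep = keep, reason = reason, segment_length = segment_length,
                 overlap = overlap, seg_len_samples = seg$len,
                 starts = seg$starts, channel_names = rec$channel_meta$name),
            class = "segment_mask")
}

#' @noRd
segment_starts <- function(n, fs, segment_length, overlap) {
  len <- round(segment_length * fs)
  if (n < len)
    stop("recording (", n, " samples) is shorter than one ",
         segment_length, " s segment")
  hop <- max(1L, round(len * (1 - overlap)))
  starts <- seq(1L, n - len + 1L, by = hop)
  list(starts = starts, len = len, hop = hop)
}

#' Welch amplitude spectral density
#'
#' One-sided amplitude spectral density per channel (square root of the Welch
#' power spectral density), using Hann-windowed segments of `segment_length`
#' seconds at 50% overlap with per-segment constant detrending and window
#' power correction, so the white-noise closed form
#' `ASD = sqrt(2 sigma^2 / fs)` holds in expectation. Segments rejected by an
#' optional [reject_bad_segments()] mask are excluded per channel.
#'
#' @param rec A `meg_recording`.
#' @param segment_length Segment ("trial") length, s; default 3, giving a
#'   1/3 Hz frequency resolution.
#' @param mask Optional `segment_mask` on the same segmentation.
#' @param overlap Fractional overlap (default 0.5).
#' @return Object of class `spectrum_set`: list with `freqs` (Hz), `asd`
#'   (channels x freqs matrix; rows all-`NA` when every segment of a channel
#'   was rejected, with a warning), `n_segments_used`, `segment_length`, and
#'   the channel metadata.
#' @examples
#' rec <- new_recording(matrix(rnorm(2 * 6000), 2), fs = 1000,
#'                      channel_meta = data.frame(name = c("a", "b"),
#'                                                type = "mag", units = "fT",
#'                                                px = 0, py = 0, pz = 0.1,
#'                                                ox = 0, oy = 0, oz = 1,
#'                                                dx = NA, dy = NA, dz = NA))
#' sp <- welch_asd(rec, segment_length = 1)
#' @export
welch_asd <- function(rec, segment_length = 3, mask = NULL, overlap = 0.5) {
  stopifnot(inherits(rec, "meg_recording"))
  n <- ncol(rec$data)
  fs <- rec$fs
  if (n / fs < 2 * segment_length)
    stop("recording must be at least twice the segment length")
  seg <- segment_starts(n, fs, segment_length, overlap)
  len <- seg$len
  n_seg <- length(seg$starts)
  if (!is.null(mask)) {
    if (!inherits(mask, "segment_mask") || ncol(mask$keep) != n_seg ||
        nrow(mask$keep) != nrow(rec$data))
      stop("mask does not match the segmentation of this recording")
  }
  w <- hann_window(len)
  wss <- sum(w^2)
  n_freq <- len %/% 2 + 1L
  freqs <- (0:(n_freq - 1L)) * fs / len
  n_ch <- nrow(rec$data)
  asd <- matrix(NA_real_, n_ch, n_freq)
  n_used <- integer(n_ch)
  for (ch in seq_len(n_ch)) {
    keep <- if (is.null(mask)) rep(TRUE, n_seg) else mask$keep[ch, ]
    if (!any(keep)) {
      warning("all segments rejected for channel ",
              rec$channel_meta$name[ch], "; ASD marked missing")
      next
    }
    idx <- seg$starts[keep]
    segmat <- matrix(0, len, length(idx))
    for (j in seq_along(idx))
      segmat[, j] <- rec$data[ch, idx[j]:(idx[j] + len - 1L)]
    segmat <- sweep(segmat, 2, colMeans(segmat))     # constant detrend
    X <- stats::mvfft(segmat * w)
    P <- rowMeans(Mod(X[seq_len(n_freq), , drop = FALSE])^2)
    scale <- 2 / (fs * wss)
    P <- P * scale
    P[1] <- P[1] / 2                                  # DC not doubled
    if (len %% 2 == 0L) P[n_freq] <- P[n_freq] / 2    # Nyquist not doubled
    asd[ch, ] <- sqrt(P)
    n_used[ch] <- length(idx)
  }
  rownames(asd) <- rec$channel_meta$name
  structure(list(freqs = freqs, asd = asd, segment_length = segment_length,
                 n_segments_used = n_used, channel_meta = rec$channel_meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set>", nrow(x$asd), "channels x", length(x$freqs),
      sprintf("bins (0-%g Hz, df = %g Hz)\n", max(x$freqs),
              x$freqs[2] - x$freqs[1]))
  invisible(x)
}

#' Median spectrum across channels
#'
#' Per-frequency median of the ASD over a channel selection, the summary
#' curve used throughout the artefact characterisation.
#'
#' @param spec A `spectrum_set`.
#' @param channel_selector Optional: character channel names, integer
#'   indices, logical mask, or a channel type (e.g. `"planar_grad"`).
#'   Default: all channels with a valid spectrum.
#' @return Object of class `median_spectrum`: list with `freqs`, `asd`,
#'   `n_channels`, and the selected per-channel matrix in `channel_asd`.
#' @export
median_spectrum <- function(spec, channel_selector = NULL) {
  stopifnot(inherits(spec, "spectrum_set"))
  idx <- resolve_channels(spec$channel_meta, channel_selector)
  idx <- idx[rowSums(is.na(spec$asd[idx, , drop = FALSE])) <
               length(spec$freqs)]
  if (length(idx) == 0L) stop("empty channel selection")
  m <- spec$asd[idx, , drop = FALSE]
  structure(list(freqs = spec$freqs,
                 asd = apply(m, 2, stats::median, na.rm = TRUE),
                 n_channels = length(idx), channel_asd = m),
            class = "median_spectrum")
}

#' @noRd
resolve_channels <- function(meta, selector) {
  if (is.null(selector)) return(seq_len(nrow(meta)))
  if (is.logical(selector)) return(which(selector))
  if (is.numeric(selector)) return(as.integer(selector))
  if (is.character(selector)) {
    if (all(selector %in% meta$type)) return(which(meta$type %in% selector))
    idx <- match(selector, meta$name)
    if (anyNA(idx)) stop("unknown channel(s): ",
                         paste(selector[is.na(idx)], collapse = ", "))
    return(idx)
  }
  stop("unsupported channel selector")
}
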
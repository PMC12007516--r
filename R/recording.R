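#' Construct a multichannel recording
#'
#' The universal data container of the pipeline: a channels x samples matrix
#' in sensor units (fT; fT/mm for planar gradiometers; uV for LFP) with
#' per-channel metadata, sampling rate, and an optional ground-truth block
#' carried through from the simulator for testing.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate, Hz.
#' @param channel_meta Data frame with one row per channel: `name`, `type`,
#'   `units`, position `px,py,pz` (m), orientation `ox,oy,oz` (unit vector),
#'   and for planar gradiometers the in-plane derivative direction
#'   `dx,dy,dz`.
#' @param t0 Time of the first sample, s.
#' @param provenance Optional list (condition spec + seed).
#' @param truth Optional ground-truth list (injected artefact frequencies,
#'   stimulation on/off times, clock map, jump times, coherent source).
#' @return Object of class `meg_recording`.
#' @export
new_recording <- function(data, fs, channel_meta, t0 = 0, provenance = NULL,
                          truth = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != nrow(channel_meta))
    stop("channel count mismatch: data has ", nrow(data),
         " rows but channel_meta has ", nrow(channel_meta))
  if (fs <= 0) stop("fs must be positive")
  if (!all(is.finite(data))) stop("recording data must be finite")
  rownames(data) <- channel_meta$name
  structure(list(data = data, fs = fs, t0 = t0, channel_meta = channel_meta,
                 provenance = provenance, truth = truth),
            class = "meg_recording")
}

#' @export
print.meg_recording <- function(x, ...) {
  cat("<meg_recording>", nrow(x$data), "channels x", ncol(x$data),
      sprintf("samples @ %g Hz (%.1f s)\n", x$fs, ncol(x$data) / x$fs))
  tt <- table(x$channel_meta$type)
  cat("  types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  if (!is.null(x$provenance$condition))
    cat("  condition:", x$provenance$condition, " seed:",
        x$provenance$seed, "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `meg_recording`.
#' @return Numeric scalar.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Construct a bipolar LFP stream
#'
#' Two-channel (one per hemisphere) local field potential stream as telemetered
#' by the stimulator, on its own clock. The `clock` field records the affine
#' map from MEG time to LFP nominal time, `t_lfp = offset + rate * t_meg`.
#'
#' @param data 2 x samples numeric matrix, uV.
#' @param fs Sampling rate, Hz (default 250).
#' @param clock List with `offset` (s) and `rate` (ratio) relative to the MEG
#'   clock.
#' @param truth Optional ground-truth list.
#' @return Object of class `lfp_stream`.
#' @export
new_lfp_stream <- function(data, fs = 250, clock = list(offset = 0, rate = 1),
                           truth = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != 2L) stop("LFP stream must have exactly 2 channels")
  if (fs <= 2 * 35) stop("LFP fs must exceed twice the 35 Hz analysis band")
  rownames(data) <- c("LFP_L", "LFP_R")
  structure(list(data = data, fs = fs, clock = clock, truth = truth),
            class = "lfp_stream")
}

#' @export
print.lfp_stream <- function(x, ...) {
  cat("<lfp_stream> 2 channels x", ncol(x$data),
      sprintf("samples @ %g Hz\n", x$fs))
  cat(sprintf("  clock: offset %.4f s, rate %.7f\n", x$clock$offset,
              x$clock$rate))
  invisible(x)
}
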
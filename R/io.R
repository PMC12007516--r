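#' Write / read the native recording format
#'
#' The native format is a little-endian binary array payload (`.dat`,
#' channel-major: all samples of channel 1, then channel 2, ...) next to a
#' JSON sidecar (`.json`) holding the sampling rate, start time, channel
#' metadata, provenance and ground-truth block. The default payload dtype is
#' 32-bit float per the format definition; `"float64"` is available when a
#' bit-exact round trip of double-precision data is required (float32
#' payloads round-trip bit-exactly once the data are float32-quantised,
#' i.e. after one write/read pass).
#'
#' @param rec A `meg_recording`.
#' @param path Output path without extension (or with `.dat`).
#' @param dtype `"float32"` (default) or `"float64"`.
#' @return `write_recording`: the path, invisibly. `read_recording`: a
#'   `meg_recording`.
#' @export
write_recording <- function(rec, path, dtype = c("float32", "float64")) {
  stopifnot(inherits(rec, "meg_recording"))
  dtype <- match.arg(dtype)
  path <- sub("\\.dat$", "", path)
  size <- if (dtype == "float32") 4L else 8L
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(t(rec$data)), con, size = size, endian = "little")
  sidecar <- list(
    format = "perceptmeg-native", version = 1L,
    dtype = dtype, byte_order = "little",
    n_channels = nrow(rec$data), n_samples = ncol(rec$data),
    fs = rec$fs, t0 = rec$t0,
    channel_meta = rec$channel_meta,
    provenance = rec$provenance,
    truth = rec$truth
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  path <- sub("\\.dat$", "", path)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  known <- c("format", "version", "dtype", "byte_order", "n_channels",
             "n_samples", "fs", "t0", "channel_meta", "provenance", "truth")
  extra <- setdiff(names(sidecar), known)
  if (length(extra))
    warning("ignoring unknown sidecar key(s): ", paste(extra, collapse = ", "))
  size <- if (identical(sidecar$dtype, "float64")) 8L else 4L
  n_vals <- sidecar$n_channels * sidecar$n_samples
  payload_bytes <- file.info(paste0(path, ".dat"))$size
  if (is.na(payload_bytes) || payload_bytes != n_vals * size)
    stop("payload size mismatch: sidecar declares ", n_vals * size,
         " bytes (n_channels x n_samples x ", size, ") but payload has ",
         payload_bytes)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, numeric(), n = n_vals, size = size, endian = "little")
  meta <- as.data.frame(sidecar$channel_meta)
  if (nrow(meta) != sidecar$n_channels)
    stop("sidecar inconsistency: channel_meta has ", nrow(meta),
         " rows but n_channels = ", sidecar$n_channels)
  data <- t(matrix(x, ncol = sidecar$n_channels))
  new_recording(data, sidecar$fs, meta, t0 = sidecar$t0 %||% 0,
                provenance = sidecar$provenance, truth = sidecar$truth)
}

#' Export a recording to a standard interchange format
#'
#' Supported dialects: `"brainvision"` (INI-style `.vhdr` text header +
#' little-endian IEEE float32 multiplexed `.eeg` payload + `.vmrk` marker
#' file; a widely readable interchange format) and `"tsv"` (plain delimited
#' text with a header row, one column per channel). Aspects without a
#' standard slot (ground truth, provenance, sensor geometry in the TSV case)
#' are skipped with a logged message.
#'
#' @param rec A `meg_recording`.
#' @param path Output path without extension.
#' @param dialect `"brainvision"` or `"tsv"`.
#' @return The main written file path, invisibly.
#' @export
export_standard <- function(rec, path, dialect = c("brainvision", "tsv")) {
  stopifnot(inherits(rec, "meg_recording"))
  if (length(dialect) == 1 && !dialect %in% c("brainvision", "tsv"))
    stop("unsupported dialect '", dialect,
         "'; supported: brainvision, tsv")
  dialect <- match.arg(dialect)
  if (!is.null(rec$truth))
    message("export_standard: ground-truth block has no standard slot; skipped")
  if (dialect == "tsv") {
    f <- paste0(path, ".tsv")
    d <- as.data.frame(t(rec$data))
    names(d) <- rec$channel_meta$name
    d <- cbind(time = (seq_len(ncol(rec$data)) - 1) / rec$fs, d)
    utils::write.table(d, f, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(f))
  }
  base <- basename(path)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,%s", seq_len(nrow(rec$data)),
            rec$channel_meta$name, rec$channel_meta$units)
  )
  writeLines(hdr, paste0(path, ".vhdr"))
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "", "[Common Infos]", "Codepage=UTF-8",
               paste0("DataFile=", base, ".eeg"),
               "", "[Marker Infos]",
               "Mk1=New Segment,,1,1,0"), paste0(path, ".vmrk"))
  con <- file(paste0(path, ".eeg"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  invisible(paste0(path, ".vhdr"))
}

#' Read a BrainVision export (independent minimal reader)
#'
#' Minimal reader for the BrainVision dialect written by
#' [export_standard()], parsing the INI header independently of the writer;
#' used to validate exports in environments without a third-party reader.
#'
#' @param path Path to the `.vhdr` file (or base path).
#' @return List with `data` (channels x samples), `fs`, `channel_names`.
#' @export
read_brainvision <- function(path) {
  path <- sub("\\.vhdr$", "", path)
  lines <- readLines(paste0(path, ".vhdr"))
  get_val <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)[1]
    sub(paste0("^", key, "="), "", ln)
  }
  n_ch <- as.integer(get_val("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_val("SamplingInterval"))
  if (get_val("BinaryFormat") != "IEEE_FLOAT_32")
    stop("unsupported binary format")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[[`, character(1), 1)
  datafile <- file.path(dirname(paste0(path, ".vhdr")), get_val("DataFile"))
  n_bytes <- file.info(datafile)$size
  con <- file(datafile, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, numeric(), n = n_bytes / 4, size = 4L, endian = "little")
  list(data = matrix(x, nrow = n_ch), fs = fs, channel_names = ch_names)
}

#' Write / read a spectrum set as delimited text
#'
#' Tabular serialisation of a `spectrum_set` (first column frequency, one
#' column per channel) with a `#`-prefixed metadata line.
#'
#' @param spec A `spectrum_set`.
#' @param path Output `.csv` path.
#' @return The path (write) or a `spectrum_set` (read).
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_set"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("# segment_length=", spec$segment_length,
                    " types=", paste(spec$channel_meta$type, collapse = ",")),
             con)
  d <- data.frame(freq = spec$freqs, t(spec$asd))
  names(d) <- c("freq", spec$channel_meta$name)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  hdr <- readLines(path, n = 1)
  seg_len <- as.numeric(sub(".*segment_length=([0-9.]+).*", "\\1", hdr))
  types <- strsplit(sub(".*types=", "", hdr), ",")[[1]]
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  asd <- t(as.matrix(d[, -1]))
  meta <- data.frame(name = rownames(asd), type = types, units = "",
                     px = NA, py = NA, pz = NA, ox = NA, oy = NA, oz = NA,
                     dx = NA, dy = NA, dz = NA)
  structure(list(freqs = d$freq, asd = asd, segment_length = seg_len,
                 n_segments_used = rep(NA_integer_, nrow(asd)),
                 channel_meta = meta),
            class = "spectrum_set")
}
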
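#' Stimulation settings
#'
#' Parameters of the implanted stimulator's pulse train. The defaults are the
#' high-end clinical settings used throughout the phantom protocol: 5 mA,
#' 60 us pulse width, 145 Hz (chosen above the common 130 Hz so stimulation
#' peaks stay distinct from the 123 Hz telemetry line).
#'
#' @param amplitude Pulse amplitude, mA (>= 0).
#' @param pulse_width Single-phase pulse width, microseconds.
#' @param frequency Pulse repetition rate, Hz.
#' @param mode `"off"`, `"bipolar"` (between two lead contacts, mild MEG
#'   interference) or `"monopolar"` (lead contact to stimulator case, severe
#'   interference).
#' @param ramping If `TRUE` the amplitude ramps up over several seconds at
#'   onset; disable for alignment by stimulation toggling.
#' @return Object of class `stim_settings`.
#' @export
stim_settings <- function(amplitude = 5, pulse_width = 60, frequency = 145,
                          mode = c("off", "bipolar", "monopolar"),
                          ramping = FALSE) {
  mode <- match.arg(mode)
  if (amplitude < 0) stop("stimulation amplitude must be >= 0")
  if (frequency <= 0) stop("stimulation frequency must be > 0")
  if (pulse_width * frequency >= 1e6)
    stop("pulse_width * frequency must stay below 1e6 (duty cycle < 1)")
  structure(list(amplitude = amplitude, pulse_width = pulse_width,
                 frequency = frequency, mode = mode, ramping = ramping),
            class = "stim_settings")
}

#' Operating-condition specification
#'
#' Describes one operating condition of the stimulator/telemetry system for
#' the phantom simulator. Use `condition_spec(name)` for a named preset, or
#' override individual factors.
#'
#' Presets:
#' * `empty_room`: no implant present; system noise and mains lines only.
#' * `quiescent`: implant connected, telemetry closed, stimulation off
#'   (spectrally indistinguishable from empty room except system-specific
#'   quirks).
#' * `communicator_near`: quiescent with the telemetry communicator close to
#'   the array, adding a 2 Hz harmonic comb between 4 and 48 Hz.
#' * `movement`: quiescent plus breathing-like implant motion (low-frequency
#'   artefact confined below 20 Hz).
#' * `sensight_streaming`: open SenSight telemetry + data streaming; a single
#'   narrow 123 Hz peak (harmonics beyond 200 Hz).
#' * `legacy_open`: open legacy telemetry without streaming; comb at 14.3 Hz
#'   harmonics.
#' * `legacy_streaming`: legacy telemetry streaming; dense comb covering the
#'   range up to 150 Hz (4.7667 Hz harmonics with 1/n decay) on top of the
#'   14.3 Hz family.
#' * `bipolar`: bipolar stimulation at the default settings; 145 Hz peak plus
#'   system-specific extras (CTF extra tones; MEGIN 72.5 Hz subharmonic on a
#'   channel subset; OPM intermodulation products).
#' * `monopolar`: monopolar stimulation; severe broadband interference,
#'   sidelobes at -16/+11 Hz around the stimulation peak (CTF), SQUID jumps
#'   on cryogenic channels.
#' * `brainsense_zero`: streaming + monopolar path with 0 mA amplitude;
#'   123 Hz and a residual stimulation-frequency peak with CTF sidelobes.
#' * `toggling`: BrainSense-like monopolar stimulation toggled on/off in
#'   cycles for clock alignment, ramping disabled.
#'
#' @param name Preset name (see Details) or `"custom"`.
#' @param ... Named fields overriding the preset (any of `telemetry`,
#'   `streaming`, `stim`, `movement`, `communicator_near`, `telemetry_freq`,
#'   `legacy_comb_fundamental`, `legacy_streaming_dense_comb`,
#'   `communicator_comb`, `sidelobe_offsets`, `subharmonic`, `extra_tones`,
#'   `ipg_present`, `toggle`, `clock`, `source`, `lfp_ecg`).
#' @return Object of class `condition_spec`.
#' @export
condition_spec <- function(name = "quiescent", ...) {
  base <- list(
    name = name,
    telemetry = "closed",              # closed | open_sensight | open_legacy
    streaming = FALSE,
    stim = stim_settings(mode = "off"),
    movement = FALSE,
    communicator_near = FALSE,
    telemetry_freq = 123,
    legacy_comb_fundamental = 14.3,
    legacy_streaming_dense_comb = FALSE,
    communicator_comb = list(fundamental = 2, range = c(4, 48)),
    sidelobe_offsets = c(below = 16, above = 11),
    subharmonic = list(factor = 0.5, channel_fraction = 0.25),
    extra_tones = list(
      ctf_bipolar = c(32.6, 65, 80, 112, 177),
      ctf_misc = 52
    ),
    ipg_present = TRUE,
    toggle = NULL,                     # list(n_cycles, on_s, off_s, start_s)
    clock = list(offset = 1.25, rate = 1 + 5e-5),
    source = NULL,                     # list(freq, bandwidth, coherence, location, amp_db)
    lfp_ecg = FALSE
  )
  preset <- switch(name,
    custom = list(),
    empty_room = list(ipg_present = FALSE),
    quiescent = list(),
    communicator_near = list(communicator_near = TRUE),
    movement = list(movement = TRUE),
    sensight_streaming = list(telemetry = "open_sensight", streaming = TRUE),
    legacy_open = list(telemetry = "open_legacy", streaming = FALSE),
    legacy_streaming = list(telemetry = "open_legacy", streaming = TRUE,
                            legacy_streaming_dense_comb = TRUE),
    bipolar = list(stim = stim_settings(mode = "bipolar")),
    monopolar = list(stim = stim_settings(mode = "monopolar")),
    brainsense_zero = list(telemetry = "open_sensight", streaming = TRUE,
                           stim = stim_settings(amplitude = 0,
                                                mode = "monopolar")),
    toggling = list(telemetry = "open_sensight", streaming = TRUE,
                    stim = stim_settings(mode = "monopolar", ramping = FALSE),
                    toggle = list(n_cycles = 5, on_s = 8, off_s = 8,
                                  start_s = 5)),
    stop("unknown condition preset '", name, "'")
  )
  spec <- utils::modifyList(base, preset)
  spec <- utils::modifyList(spec, list(...))
  validate_condition(spec)
  structure(spec, class = "condition_spec")
}

#' @noRd
validate_condition <- function(spec) {
  if (!spec$telemetry %in% c("closed", "open_sensight", "open_legacy"))
    stop("telemetry must be closed, open_sensight or open_legacy")
  if (spec$streaming && spec$telemetry == "closed")
    stop("streaming requires an open telemetry session")
  if (!inherits(spec$stim, "stim_settings"))
    stop("stim must be a stim_settings object")
  if (!is.null(spec$clock) && abs(spec$clock$rate - 1) >= 1e-3)
    stop("clock rate ratio must satisfy |rate - 1| < 1e-3")
  invisible(spec)
}

# All deterministic artefact tone frequencies a condition injects for a given
# profile (used by simulate_condition, the truth block and the signature
# library). Returns data.frame(source, freq, rel_db) with levels in dB above
# the local noise floor at the default 3 s spectral resolution.
#' @noRd
condition_tone_plan <- function(profile, cond) {
  rows <- list()
  add <- function(source, freq, rel_db) {
    keep <- freq > 0 & freq < profile$fs / 2
    if (any(keep))
      rows[[length(rows) + 1L]] <<- data.frame(
        source = source, freq = freq[keep], rel_db = rel_db[keep])
  }
  tele_open <- cond$telemetry != "closed"
  if (cond$telemetry == "open_sensight") {
    add("sensight_telemetry", cond$telemetry_freq * c(1, 2, 3), c(35, 25, 20))
  }
  if (cond$telemetry == "open_legacy") {
    f0 <- cond$legacy_comb_fundamental
    k <- seq_len(floor(150 / f0))
    add("legacy_telemetry_open", f0 * k, 35 - 10 * log10(k))
    if (cond$streaming && cond$legacy_streaming_dense_comb) {
      fd <- f0 / 3
      kd <- seq_len(floor(150 / fd))
      kd <- kd[kd %% 3 != 0]           # the 14.3 family is already present
      add("legacy_streaming_comb", fd * kd, 35 - 20 * log10(kd))
    }
  }
  if (cond$communicator_near) {
    cc <- cond$communicator_comb
    f <- seq(cc$range[1], cc$range[2], by = cc$fundamental)
    add("communicator", f, rep(24, length(f)))
  }
  stim <- cond$stim
  stim_active <- stim$mode != "off" && stim$amplitude > 0
  stim_tone_only <- stim$mode == "monopolar" && stim$amplitude == 0 &&
    cond$streaming                      # BrainSense at 0 mA: residual tone
  if (stim_active || stim_tone_only) {
    if (stim$mode == "monopolar" || stim_tone_only) {
      if (profile$name == "ctf") {
        # levels sit 20 dB above the monopolar-lifted broadband floor
        add("stim_sidelobes",
            stim$frequency + c(-cond$sidelobe_offsets[["below"]],
                               cond$sidelobe_offsets[["above"]]),
            c(40, 40))
        add("ctf_misc", cond$extra_tones$ctf_misc, 35)
      }
    }
    if (stim$mode == "bipolar" && profile$name == "ctf") {
      add("ctf_bipolar_extras", cond$extra_tones$ctf_bipolar,
          rep(24, length(cond$extra_tones$ctf_bipolar)))
    }
    if (stim$mode == "bipolar" && profile$name == "megin") {
      add("megin_subharmonic", stim$frequency * cond$subharmonic$factor, 28)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(source = character(), freq = numeric(),
                      rel_db = numeric()))
  do.call(rbind, rows)
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("<condition_spec>", x$name, "\n")
  cat("  telemetry:", x$telemetry, if (x$streaming) "(streaming)" else "", "\n")
  cat("  stim:", x$stim$mode,
      if (x$stim$mode != "off") sprintf("%g mA / %g us / %g Hz",
                                        x$stim$amplitude, x$stim$pulse_width,
                                        x$stim$frequency) else "", "\n")
  flags <- c(movement = x$movement, communicator_near = x$communicator_near,
             ipg_present = x$ipg_present)
  cat("  flags:", paste(names(flags)[flags], collapse = ", "), "\n")
  invisible(x)
}
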
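#' MEG system profiles
#'
#' A system profile is a declarative description of one of the three MEG
#' systems emulated by the phantom simulator:
#'
#' * `"ctf"`: 275 axial gradiometers sampled at 19.2 kHz, flat empty-room
#'   noise floor of 3.5 fT/sqrt(Hz) (below the 5 fT/sqrt(Hz) reference bound),
#'   50/60 Hz mains families, SQUID sensors susceptible to flux jumps.
#' * `"megin"`: 102 sensor triplets (one magnetometer + two orthogonal planar
#'   gradiometers, 306 channels) at 5 kHz. Gradiometer floor below
#'   0.6 fT/(mm sqrt(Hz)); magnetometer floor rising towards 100 fT/sqrt(Hz)
#'   below 50 Hz and below 10 fT/sqrt(Hz) above 100 Hz.
#' * `"opm"`: 62 channels (31 dual-axis optically pumped magnetometers) at
#'   6 kHz. Floor below 30 fT/sqrt(Hz) above 30 Hz, rising to 540 fT/sqrt(Hz)
#'   around 10 Hz; intrinsic narrowband peaks at 26, 120, 155, 160, 173 and
#'   180 Hz; internal modulation tone at 923 Hz with a weak polynomial
#'   nonlinearity that creates intermodulation products with strong
#'   interferers.
#'
#' Noise floors are piecewise log-log amplitude-spectral-density curves per
#' sensor type, interpolated with [noise_floor_level()].
#'
#' @param name One of `"ctf"`, `"megin"`, `"opm"`.
#' @return An object of class `system_profile`.
#' @examples
#' p <- make_profile("opm")
#' p$opm_modulation_freq
#' @export
make_profile <- function(name) {
  valid <- c("ctf", "megin", "opm")
  if (length(name) != 1L || !name %in% valid) {
    stop("unknown system profile '", paste(name, collapse = ","),
         "'; valid options are: ", paste(valid, collapse = ", "))
  }
  prof <- switch(name,
    ctf = list(
      name = "ctf",
      fs = 19200,
      n_channels = c(axial_grad = 275L),
      noise_floor_spec = list(
        axial_grad = list(freq = c(0.1, 9600), level = c(3.5, 3.5))
      ),
      intrinsic_peaks = list(axial_grad = NULL),
      line_freqs = c(50, 60, 120, 150, 180),
      opm_modulation_freq = NULL,
      opm_nonlinearity = c(alpha = 0, beta = 0),
      squid_jump_susceptible = TRUE,
      gradiometer_baseline = 0.05,
      sensor_radius = 0.12
    ),
    megin = list(
      name = "megin",
      fs = 5000,
      n_channels = c(planar_grad = 204L, mag = 102L),
      noise_floor_spec = list(
        planar_grad = list(freq = c(0.5, 5, 20, 45, 100, 2500),
                           level = c(3, 1.0, 0.45, 0.42, 0.40, 0.40)),
        mag = list(freq = c(0.5, 5, 20, 45, 80, 100, 2500),
                   level = c(400, 120, 85, 70, 20, 9, 7))
      ),
      intrinsic_peaks = list(planar_grad = NULL, mag = NULL),
      line_freqs = c(50, 100, 150),
      opm_modulation_freq = NULL,
      opm_nonlinearity = c(alpha = 0, beta = 0),
      squid_jump_susceptible = TRUE,
      gradiometer_baseline = 0.0168,   # planar baseline, m
      sensor_radius = 0.13
    ),
    opm = list(
      name = "opm",
      fs = 6000,
      n_channels = c(mag = 62L),
      noise_floor_spec = list(
        mag = list(freq = c(0.5, 2, 10, 20, 30, 45, 100, 3000),
                   level = c(1500, 900, 540, 80, 28, 22, 20, 15))
      ),
      intrinsic_peaks = list(
        mag = data.frame(freq = c(26, 120, 155, 160, 173, 180),
                         rel_db = c(14, 12, 12, 12, 12, 12))
      ),
      line_freqs = c(50, 100, 150),
      opm_modulation_freq = 923,
      opm_nonlinearity = c(alpha = 9e-8, beta = 1.2e-13),
      squid_jump_susceptible = FALSE,
      gradiometer_baseline = NA_real_,
      sensor_radius = 0.102
    )
  )
  prof$geometry <- full_array_geometry(prof)
  structure(prof, class = "system_profile")
}

#' Interpolate a piecewise noise-floor curve
#'
#' Log-log linear interpolation of an amplitude-spectral-density floor
#' specification, clamped at the curve ends.
#'
#' @param spec List with numeric `freq` (Hz, increasing) and `level`
#'   (sensor units per sqrt(Hz), positive).
#' @param freq Frequencies at which to evaluate (Hz).
#' @return Numeric vector of ASD levels.
#' @export
noise_floor_level <- function(spec, freq) {
  stopifnot(is.list(spec), length(spec$freq) == length(spec$level))
  if (any(spec$level <= 0)) stop("noise floor levels must be positive")
  f <- pmax(freq, min(spec$freq))
  f <- pmin(f, max(spec$freq))
  if (length(spec$freq) == 1L) return(rep(spec$level, length(freq)))
  10^stats::approx(log10(spec$freq), log10(spec$level), xout = log10(f),
                   rule = 2)$y
}

# Full-array sensor geometry on a spherical cap (Fibonacci layout), radial
# orientations; MEGIN triplet sites carry one magnetometer plus two
# orthogonal tangential-derivative planar gradiometers.
#' @noRd
full_array_geometry <- function(prof) {
  cap_points <- function(n, radius, max_theta = 2.0) {
    i <- seq_len(n) - 0.5
    # area-uniform in cos(theta) over the cap, golden-angle azimuth
    costh <- 1 - (1 - cos(max_theta)) * i / n
    theta <- acos(costh)
    phi <- i * pi * (3 - sqrt(5))
    cbind(x = radius * sin(theta) * cos(phi),
          y = radius * sin(theta) * sin(phi),
          z = radius * cos(theta))
  }
  tangents <- function(pos) {
    # two orthonormal tangent vectors per radial site
    r <- pos / sqrt(rowSums(pos^2))
    ref <- matrix(rep(c(0, 0, 1), each = nrow(pos)), ncol = 3)
    near_pole <- abs(r[, 3]) > 0.95
    ref[near_pole, ] <- matrix(rep(c(1, 0, 0), each = sum(near_pole)), ncol = 3)
    e1 <- t(vapply(seq_len(nrow(pos)), function(i) {
      v <- cross3(ref[i, ], r[i, ]); v / sqrt(sum(v^2))
    }, numeric(3)))
    e2 <- t(vapply(seq_len(nrow(pos)), function(i) cross3(r[i, ], e1[i, ]),
                   numeric(3)))
    list(e1 = e1, e2 = e2)
  }
  mk <- function(nm, type, units, pos, ori, pdir = NULL) {
    d <- data.frame(name = nm, type = type, units = units,
                    px = pos[, 1], py = pos[, 2], pz = pos[, 3],
                    ox = ori[, 1], oy = ori[, 2], oz = ori[, 3],
                    stringsAsFactors = FALSE)
    if (is.null(pdir)) pdir <- matrix(NA_real_, nrow(pos), 3)
    d$dx <- pdir[, 1]; d$dy <- pdir[, 2]; d$dz <- pdir[, 3]
    d
  }
  R <- prof$sensor_radius
  if (prof$name == "ctf") {
    pos <- cap_points(prof$n_channels[["axial_grad"]], R)
    ori <- pos / sqrt(rowSums(pos^2))
    mk(sprintf("MLC%03d", seq_len(nrow(pos))), "axial_grad", "fT", pos, ori)
  } else if (prof$name == "opm") {
    nsites <- prof$n_channels[["mag"]] / 2L
    pos <- cap_points(nsites, R)
    r <- pos / sqrt(rowSums(pos^2))
    tg <- tangents(pos)
    rbind(
      mk(sprintf("OPM%02dR", seq_len(nsites)), "mag", "fT", pos, r),
      mk(sprintf("OPM%02dT", seq_len(nsites)), "mag", "fT", pos, tg$e1)
    )
  } else {
    nsites <- prof$n_channels[["mag"]]
    pos <- cap_points(nsites, R)
    r <- pos / sqrt(rowSums(pos^2))
    tg <- tangents(pos)
    rbind(
      mk(sprintf("MEG%03d1", seq_len(nsites)), "mag", "fT", pos, r),
      mk(sprintf("MEG%03d2", seq_len(nsites)), "planar_grad", "fT/mm", pos, r,
         tg$e1),
      mk(sprintf("MEG%03d3", seq_len(nsites)), "planar_grad", "fT/mm", pos, r,
         tg$e2)
    )
  }
}

#' @export
print.system_profile <- function(x, ...) {
  cat("<system_profile>", x$name, "\n")
  cat("  fs:", x$fs, "Hz; channels:",
      paste(sprintf("%s=%d", names(x$n_channels), x$n_channels),
            collapse = ", "), "\n")
  cat("  line frequencies:", paste(x$line_freqs, collapse = ", "), "Hz\n")
  if (!is.null(x$opm_modulation_freq))
    cat("  OPM modulation:", x$opm_modulation_freq, "Hz\n")
  invisible(x)
}
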
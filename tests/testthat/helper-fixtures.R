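# Shared fixtures: small channel metadata, toy recordings, and desk-scale
# simulation helpers. All fixtures are generated in code under fixed seeds.

toy_meta <- function(n = 2, type = "mag", units = "fT") {
  data.frame(name = paste0("ch", seq_len(n)), type = type, units = units,
             px = 0, py = 0, pz = 0.1, ox = 0, oy = 0, oz = 1,
             dx = NA_real_, dy = NA_real_, dz = NA_real_,
             stringsAsFactors = FALSE)
}

toy_recording <- function(data, fs, type = "mag") {
  data <- if (is.null(dim(data))) matrix(data, nrow = 1) else data
  new_recording(data, fs, toy_meta(nrow(data), type))
}

# Cached desk-scale simulations shared across test files (short durations,
# few channels; profiles keep their native sampling rates).
.sim_cache <- new.env(parent = emptyenv())
sim_cached <- function(profile, condition, duration = 36, seed = 11,
                      n_channels = 4, ...) {
  key <- paste(profile, condition, duration, seed, n_channels, sep = "|")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_condition(
      make_profile(profile), condition_spec(condition, ...),
      duration = duration, seed = seed, n_channels = n_channels)
  }
  .sim_cache[[key]]
}

# Small sensor array + source grid + lead field for source-space tests.
toy_array <- function(n_sens = 20) {
  prof <- make_profile("opm")
  sens <- prof$geometry[seq(1, nrow(prof$geometry), by = 3), ][seq_len(n_sens), ]
  rownames(sens) <- NULL
  sens
}

toy_grid <- function(spacing = 0.01) {
  gx <- seq(-0.04, 0.04, by = spacing)
  grid <- as.matrix(expand.grid(gx, gx, c(0.02, 0.03, 0.04, 0.05)))
  grid[sqrt(rowSums(grid^2)) < 0.07, ]
}

# Coupled MEG/reference construction: a band-limited source projected
# through a dipole topography plus white sensor noise; reference shares a
# known coherence with the source.
coupled_epochs <- function(lf, src_index, fs = 128, n_ep = 60, band = c(18, 22),
                           gamma = 0.6, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  sens <- lf$sensors
  n <- n_ep * fs
  topo <- lf$L[src_index, , ] %*% c(0.7, 0.7, 0)
  topo <- topo / max(abs(topo))
  bp <- function(x) perceptmeg:::fft_bandpass(x, fs, band[1], band[2])
  s <- bp(rnorm(n)); s <- s / sd(s)
  indep <- bp(rnorm(n)); indep <- indep / sd(indep)
  ref <- sqrt(gamma) * s + sqrt(1 - gamma) * indep
  meg <- matrix(rnorm(nrow(sens) * n) * noise_sd, nrow(sens), n) +
    topo %*% t(matrix(s, ncol = 1))
  rec <- new_recording(meg, fs, sens)
  epoch_pair(rec, matrix(ref, nrow = 1), length = 1)
}
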
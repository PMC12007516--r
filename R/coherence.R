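#' Epoch an aligned MEG + LFP pair
#'
#' Cuts contiguous non-overlapping epochs of `length` seconds from a
#' recording and an LFP waveform already resampled onto the MEG clock
#' ([resample_to_meg_clock()]). The LFP reference is carried as an extra
#' channel. Epochs overlapping segments rejected by a [reject_bad_segments()]
#' mask (on any channel) are dropped.
#'
#' @param meg A `meg_recording`.
#' @param lfp_aligned Numeric vector (one reference channel) or 2-row matrix
#'   on the same time base and sampling rate as `meg`.
#' @param length Epoch length, s (default 1, giving 1 Hz coherence
#'   resolution).
#' @param mask Optional `segment_mask` from [reject_bad_segments()].
#' @return Object of class `epochs_set`: list with `data` (trials x channels
#'   x samples array), `fs`, `channel_names` (LFP channels last),
#'   `epoch_length`.
#' @export
epoch_pair <- function(meg, lfp_aligned, length = 1, mask = NULL) {
  stopifnot(inherits(meg, "meg_recording"))
  if (is.null(dim(lfp_aligned))) lfp_aligned <- matrix(lfp_aligned, nrow = 1)
  n <- min(ncol(meg$data), ncol(lfp_aligned))
  len <- round(length * meg$fs)
  n_ep <- n %/% len
  lfp_names <- rownames(lfp_aligned)
  if (is.null(lfp_names)) lfp_names <- paste0("LFP", seq_len(nrow(lfp_aligned)))
  ch_names <- c(meg$channel_meta$name, lfp_names)
  n_ch <- length(ch_names)
  bad_epoch <- rep(FALSE, n_ep)
  if (!is.null(mask)) {
    rej <- which(!apply(mask$keep, 2, all))
    for (s in rej) {
      lo <- mask$starts[s]
      hi <- lo + mask$seg_len_samples - 1L
      e_lo <- (lo - 1L) %/% len + 1L
      e_hi <- min(n_ep, (hi - 1L) %/% len + 1L)
      if (e_lo <= n_ep) bad_epoch[e_lo:min(e_hi, n_ep)] <- TRUE
    }
  }
  keep_ep <- which(!bad_epoch)
  if (length(keep_ep) < 10)
    stop("fewer than 10 usable epochs (", length(keep_ep),
         "); recording too short or too contaminated for coherence")
  arr <- array(0, dim = c(length(keep_ep), n_ch, len),
               dimnames = list(NULL, ch_names, NULL))
  for (j in seq_along(keep_ep)) {
    idx <- ((keep_ep[j] - 1L) * len + 1L):(keep_ep[j] * len)
    arr[j, seq_len(nrow(meg$data)), ] <- meg$data[, idx]
    arr[j, nrow(meg$data) + seq_len(nrow(lfp_aligned)), ] <-
      lfp_aligned[, idx, drop = FALSE]
  }
  structure(list(data = arr, fs = meg$fs, channel_names = ch_names,
                 epoch_length = length, meg_channels = meg$channel_meta$name,
                 channel_meta = meg$channel_meta),
            class = "epochs_set")
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epochs_set>", d[1], "epochs x", d[2], "channels x", d[3],
      sprintf("samples (%g s @ %g Hz)\n", x$epoch_length, x$fs))
  invisible(x)
}

# Hann-tapered per-epoch spectra: array trials x channels x freqs (complex).
#' @noRd
epoch_spectra <- function(epochs) {
  d <- dim(epochs$data)
  len <- d[3]
  w <- hann_window(len)
  n_freq <- len %/% 2 + 1L
  X <- array(complex(real = 0), dim = c(d[1], d[2], n_freq))
  for (tr in seq_len(d[1])) {
    seg <- t(epochs$data[tr, , , drop = TRUE])
    if (d[2] == 1L) seg <- matrix(epochs$data[tr, 1, ], ncol = 1)
    seg <- sweep(seg, 2, colMeans(seg))
    F <- stats::mvfft(seg * w)
    X[tr, , ] <- t(F[seq_len(n_freq), , drop = FALSE])
  }
  list(X = X, freqs = (0:(n_freq - 1L)) / epochs$epoch_length)
}

#' Magnitude-squared coherence against a reference channel
#'
#' Per-channel, per-frequency magnitude-squared coherence with the reference
#' channel, from Hann-tapered per-epoch cross- and auto-spectra (one taper
#' per epoch; 1 Hz resolution for 1 s epochs). Under independence the
#' estimator's expectation is approximately `1/L` for `L` epochs.
#'
#' @param epochs An `epochs_set` (>= 10 epochs).
#' @param ref Reference channel name or index.
#' @param fmax Highest frequency retained (default 100 Hz).
#' @return Object of class `coherence_map` with `domain = "sensor"`:
#'   list with `values` (channels x freqs in `[0, 1]`; `NA` rows for
#'   zero-variance channels), `freqs`, `channels`, `ref`, `n_epochs`.
#' @export
msc <- function(epochs, ref, fmax = 100) {
  stopifnot(inherits(epochs, "epochs_set"))
  d <- dim(epochs$data)
  if (d[1] < 10) stop("coherence needs at least 10 epochs")
  ref_idx <- if (is.character(ref)) match(ref, epochs$channel_names) else ref
  if (is.na(ref_idx)) stop("unknown reference channel '", ref, "'")
  sp <- epoch_spectra(epochs)
  keep_f <- sp$freqs <= fmax
  freqs <- sp$freqs[keep_f]
  Xr <- sp$X[, ref_idx, keep_f, drop = TRUE]
  n_ch <- d[2]
  vals <- matrix(NA_real_, n_ch, length(freqs))
  Srr <- colMeans(Mod(Xr)^2)
  for (ch in seq_len(n_ch)) {
    Xc <- sp$X[, ch, keep_f, drop = TRUE]
    Scc <- colMeans(Mod(Xc)^2)
    if (all(Scc == 0)) next                  # zero-variance channel
    Scr <- colMeans(Xc * Conj(Xr))
    vals[ch, ] <- Mod(Scr)^2 / (Scc * Srr)
  }
  rownames(vals) <- epochs$channel_names
  structure(list(domain = "sensor", values = vals, freqs = freqs,
                 channels = epochs$channel_names, ref = epochs$channel_names[ref_idx],
                 n_epochs = d[1]),
            class = "coherence_map")
}

#' @export
print.coherence_map <- function(x, ...) {
  cat("<coherence_map>", x$domain, "domain,",
      if (x$domain == "sensor") paste(nrow(x$values), "channels x",
                                      length(x$freqs), "freqs")
      else paste(nrow(x$grid), "grid points"), "\n")
  invisible(x)
}

#' Permutation test of sensor-level coherence
#'
#' Builds `n_perm` null coherence images by permuting the reference channel's
#' epoch order (seeded; the identity permutation is excluded), then tests the
#' observed image against the null set with a two-sample equal-variance
#' t-statistic per (channel, frequency) cell. Before testing, coherence
#' values are mapped through the exact null quantile transform
#' `qnorm(1 - (1 - coh)^(L-1))` (for `L` epochs the null magnitude-squared
#' coherence satisfies `P(C > c) = (1-c)^(L-1)`), which makes the cells
#' near-Gaussian so the far Bonferroni tail of the t reference is usable.
#' Family-wise error is controlled by Bonferroni
#' correction over cells at level `alpha`; significant cells in connected
#' components (adjacent frequency bins within a channel, or the same bin on
#' adjacent channels) smaller than the extent threshold are removed.
#'
#' @param epochs An `epochs_set` (>= 20 epochs).
#' @param ref Reference channel name or index.
#' @param n_perm Number of permutations (default 10).
#' @param alpha Family-wise significance level (default 0.05).
#' @param extent Cluster extent threshold in cells. Default `NULL` scales the
#'   full-resolution threshold of 100 cells proportionally to the image size
#'   (never below 1).
#' @param fmax Highest frequency tested (default 45 Hz).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `perm_result`: list with `t_map`, `p_map`
#'   (Bonferroni-adjusted), `mask` (significant cells after extent
#'   thresholding), `observed`, `null_mean`, `freqs`, `channels`, `n_perm`.
#' @export
permutation_test <- function(epochs, ref, n_perm = 10, alpha = 0.05,
                             extent = NULL, fmax = 45, seed = 1) {
  stopifnot(inherits(epochs, "epochs_set"))
  d <- dim(epochs$data)
  if (n_perm < 2) stop("n_perm must be at least 2")
  if (d[1] < 20) stop("permutation test needs at least 20 epochs")
  ref_idx <- if (is.character(ref)) match(ref, epochs$channel_names) else ref
  chan_idx <- setdiff(seq_len(d[2]), ref_idx)
  sp <- epoch_spectra(epochs)
  keep_f <- sp$freqs > 0 & sp$freqs <= fmax
  freqs <- sp$freqs[keep_f]
  Xr <- sp$X[, ref_idx, keep_f, drop = TRUE]
  Xc <- sp$X[, chan_idx, keep_f, drop = FALSE]
  Srr <- colMeans(Mod(Xr)^2)
  Scc <- apply(Mod(Xc)^2, c(2, 3), mean)
  coh_image <- function(ord) {
    Xrp <- Xr[ord, , drop = FALSE]
    n_chn <- length(chan_idx)
    out <- matrix(0, n_chn, length(freqs))
    for (j in seq_len(n_chn)) {
      Scr <- colMeans(Xc[, j, ] * Conj(Xrp))
      out[j, ] <- Mod(Scr)^2 / (Scc[j, ] * Srr)
    }
    out
  }
  obs <- coh_image(seq_len(d[1]))
  perms <- vector("list", n_perm)
  with_sub_seed(seed, "perm", {
    got <- 0L
    while (got < n_perm) {
      p <- sample(d[1])
      if (all(p == seq_len(d[1]))) next   # identity excluded
      got <- got + 1L
      perms[[got]] <- p
    }
  })
  nulls <- lapply(perms, coh_image)
  zq <- function(coh) {
    p <- pmin(pmax((1 - pmin(coh, 1 - 1e-15))^(d[1] - 1), 1e-15), 1 - 1e-15)
    stats::qnorm(p, lower.tail = FALSE)
  }
  z_obs <- zq(obs)
  z_null <- lapply(nulls, zq)
  null_arr <- simplify2array(z_null)               # ch x freq x n_perm
  mu <- apply(null_arr, c(1, 2), mean)
  s2 <- apply(null_arr, c(1, 2), stats::var)
  # two-sample equal-variance t with n1 = 1 observed image vs n2 = n_perm
  t_map <- (z_obs - mu) / sqrt(s2 * (1 + 1 / n_perm))
  df <- n_perm - 1
  p_unc <- stats::pt(t_map, df, lower.tail = FALSE)
  n_cells <- length(t_map)
  if (is.null(extent))
    extent <- max(1L, round(100 * n_cells / 2e5))
  p_crit <- alpha / n_cells
  if (n_perm < 5 && p_crit < 1e-4)
    stop("n_perm = ", n_perm, " cannot resolve the Bonferroni threshold ",
         signif(p_crit, 2), "; increase n_perm")
  sig <- p_unc < p_crit
  mask <- extent_filter(sig, extent)
  dimnames(t_map) <- list(epochs$channel_names[chan_idx], freqs)
  structure(list(t_map = t_map, p_map = pmin(p_unc * n_cells, 1),
                 mask = mask, observed = obs, null_mean = mu, freqs = freqs,
                 channels = epochs$channel_names[chan_idx],
                 n_perm = n_perm, alpha = alpha, extent = extent),
            class = "perm_result")
}

# Remove connected components (4-connectivity on the channel x frequency
# grid) smaller than the extent threshold.
#' @noRd
extent_filter <- function(sig, extent) {
  if (extent <= 1 || !any(sig)) return(sig)
  lab <- matrix(0L, nrow(sig), ncol(sig))
  cur <- 0L
  for (i in seq_len(nrow(sig))) for (j in seq_len(ncol(sig))) {
    if (!sig[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + dd
        if (q[1] >= 1 && q[1] <= nrow(sig) && q[2] >= 1 && q[2] <= ncol(sig) &&
            sig[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= extent)
  sig & matrix(lab %in% keep, nrow(sig), ncol(sig))
}

#' DICS beamformer coherence image in a frequency band
#'
#' Dynamic Imaging of Coherent Sources: the sensor cross-spectral density is
#' averaged over the band, inverted through an eigendecomposition truncated
#' to `rank` components, and for every grid point a scalar beamformer with
#' the optimal (dominant generalized eigenvector) orientation estimates the
#' source signal, whose magnitude-squared coherence with the reference
#' channel is imaged. The returned image carries both raw coherence and its
#' z-scored version.
#'
#' @param epochs An `epochs_set`.
#' @param ref Reference channel name or index.
#' @param band Length-2 numeric, frequency band in Hz (alpha 7-13,
#'   beta 15-35 by convention).
#' @param lf A [sphere_leadfield()] whose sensors match the MEG channels of
#'   `epochs`.
#' @param rank Dimensionality retained when inverting the CSD (default 150,
#'   clamped with a warning to the channel count on smaller arrays).
#' @return Object of class `coherence_map` with `domain = "source"`:
#'   `values` (raw coherence per grid point), `z` (z-scored), `grid`, `band`.
#' @export
dics_band <- function(epochs, ref, band, lf, rank = 150) {
  stopifnot(inherits(epochs, "epochs_set"), inherits(lf, "lead_field"))
  d <- dim(epochs$data)
  ref_idx <- if (is.character(ref)) match(ref, epochs$channel_names) else ref
  chan_idx <- match(lf$sensors$name, epochs$channel_names)
  if (anyNA(chan_idx)) stop("lead field sensors missing from epochs")
  sp <- epoch_spectra(epochs)
  in_band <- sp$freqs >= band[1] & sp$freqs <= band[2]
  if (!any(in_band)) stop("band ", band[1], "-", band[2],
                          " Hz outside spectral support")
  n_sens <- length(chan_idx)
  if (rank > n_sens) {
    warning("rank ", rank, " exceeds channel count ", n_sens, "; clamped")
    rank <- n_sens
  }
  fbins <- which(in_band)
  C <- matrix(complex(real = 0), n_sens, n_sens)
  cr <- complex(real = numeric(n_sens))
  srr <- 0
  for (f in fbins) {
    Xf <- sp$X[, chan_idx, f, drop = TRUE]
    if (is.null(dim(Xf))) Xf <- matrix(Xf, ncol = n_sens)
    xr <- sp$X[, ref_idx, f]
    C <- C + t(Xf) %*% Conj(Xf) / d[1]
    cr <- cr + colMeans(Xf * Conj(xr))
    srr <- srr + mean(Mod(xr)^2)
  }
  C <- C / length(fbins); cr <- cr / length(fbins); srr <- srr / length(fbins)
  eg <- eigen(C, symmetric = TRUE)
  vals <- Re(eg$values)
  keep <- seq_len(rank)
  Ci <- eg$vectors[, keep, drop = FALSE] %*%
    (Conj(t(eg$vectors[, keep, drop = FALSE])) / vals[keep])
  n_grid <- dim(lf$L)[1]
  coh <- numeric(n_grid)
  for (g in seq_len(n_grid)) {
    L <- lf$L[g, , ]                       # sensors x 3
    sv <- svd(L)
    nc <- sum(sv$d > 1e-8 * sv$d[1])
    nc <- min(nc, 2L)                      # tangential space in a sphere
    L2 <- L %*% sv$v[, seq_len(nc), drop = FALSE]
    G <- Re(Conj(t(L2)) %*% Ci %*% L2)
    eg2 <- eigen(G, symmetric = TRUE)
    u <- eg2$vectors[, which.min(eg2$values)]   # unit-gain power-optimal
    l <- as.numeric(L2 %*% u)
    Cil <- Ci %*% l
    denom <- Re(crossprod(l, Cil))[1]
    w <- Cil / denom
    s_ss <- Re(Conj(t(w)) %*% C %*% w)[1]
    s_sr <- (Conj(t(w)) %*% cr)[1]
    coh[g] <- Mod(s_sr)^2 / (s_ss * srr)
  }
  z <- (coh - mean(coh)) / stats::sd(coh)
  structure(list(domain = "source", values = coh, z = z, grid = lf$grid,
                 band = band, ref = epochs$channel_names[ref_idx],
                 rank = rank),
            class = "coherence_map")
}
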
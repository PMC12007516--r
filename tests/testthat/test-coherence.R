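test_that("epoch_pair counts epochs and drops rejected ones", {
  fs <- 200
  rec <- toy_recording(matrix(rnorm(2 * 120 * fs), 2), fs)
  lfp <- rnorm(120 * fs)
  ep <- epoch_pair(rec, lfp, length = 1)
  expect_equal(dim(ep$data), c(120L, 3L, fs))

  # epochs overlapping rejected 3 s segments are dropped
  m <- reject_bad_segments(rec)
  bad_segs <- c(5, 20, 40)
  m$keep[1, bad_segs] <- FALSE
  ep2 <- epoch_pair(rec, lfp, length = 1, mask = m)
  expect_lte(dim(ep2$data)[1], 120 - 3)     # >= 3 s lost per rejected segment
  expect_gte(dim(ep2$data)[1], 120 - 3 * 4)

  expect_error(epoch_pair(toy_recording(matrix(rnorm(2 * 5 * fs), 2), fs),
                          rnorm(5 * fs)), "10 usable epochs")
})

test_that("msc matches analytic expectations", {
  fs <- 100
  set.seed(21)
  rec <- toy_recording(matrix(rnorm(2 * 60 * fs), 2), fs)
  ep <- epoch_pair(rec, rnorm(60 * fs), length = 1)
  # self-coherence is 1 everywhere
  cm <- msc(ep, ref = "LFP1", fmax = 45)
  ref_row <- which(ep$channel_names == "LFP1")
  expect_true(all(abs(cm$values[ref_row, ] - 1) < 1e-9))
  # independence bias: mean coherence ~ 1/L
  L <- cm$n_epochs
  expect_equal(mean(cm$values[1:2, cm$freqs > 2]), 1 / L, tolerance = 0.3)
  expect_true(all(cm$values >= 0 & cm$values <= 1 + 1e-12, na.rm = TRUE))
})

test_that("msc recovers a constructed coherence level", {
  fs <- 100
  n_ep <- 120
  n <- n_ep * fs
  set.seed(22)
  bp <- function(x) perceptmeg:::fft_bandpass(x, fs, 18, 22)
  s <- bp(rnorm(n)); s <- s / sd(s)
  u <- bp(rnorm(n)); u <- u / sd(u)
  gam <- 0.5
  x <- s + 0.0 * rnorm(n)
  y <- sqrt(gam) * s + sqrt(1 - gam) * u
  rec <- toy_recording(matrix(x, 1), fs)
  ep <- epoch_pair(rec, y, length = 1)
  cm <- msc(ep, ref = "LFP1", fmax = 45)
  est <- cm$values[1, cm$freqs == 20]
  # sampling CI at L = 120 epochs: sd(coh) ~ sqrt(2/L) * coh * (1 - coh)
  expect_equal(unname(est), gam, tolerance = 3 * sqrt(2 / n_ep))
  # zero-variance channel is marked missing
  rec0 <- toy_recording(rbind(x, 0), fs)
  ep0 <- epoch_pair(rec0, y, length = 1)
  cm0 <- msc(ep0, ref = "LFP1")
  expect_true(all(is.na(cm0$values[2, ])))
})

test_that("permutation test: identity-only null gives near-zero t", {
  fs <- 100
  set.seed(23)
  rec <- toy_recording(matrix(rnorm(4 * 30 * fs), 4), fs)
  ep <- epoch_pair(rec, rnorm(30 * fs), length = 1)
  pr <- permutation_test(ep, ref = "LFP1", n_perm = 10, seed = 3, extent = 1)
  # observed and null come from the same distribution: t-map centred near 0
  expect_lt(abs(mean(pr$t_map)), 0.5)
  expect_error(permutation_test(ep, ref = "LFP1", n_perm = 1), "at least 2")
})

test_that("permutation test controls family-wise error on null data", {
  fs <- 100
  set.seed(24)
  meta <- toy_meta(8)
  hits <- vapply(1:60, function(r) {
    rec <- new_recording(matrix(rnorm(8 * 25 * fs), 8), fs, meta)
    ep <- epoch_pair(rec, rnorm(25 * fs), length = 1)
    any(permutation_test(ep, ref = "LFP1", n_perm = 10, seed = r,
                         extent = 1)$mask)
  }, logical(1))
  expect_lte(mean(hits), 0.1)   # 2x the nominal 0.05
})

test_that("permutation test detects planted coupling on the right channels", {
  fs <- 100
  n_ep <- 40
  n <- n_ep * fs
  set.seed(25)
  bp <- function(x) perceptmeg:::fft_bandpass(x, fs, 19, 21)
  s <- bp(rnorm(n)); s <- s / sd(s)
  dat <- matrix(rnorm(60 * n), 60, n)
  dat[1:5, ] <- dat[1:5, ] + 1.5 * matrix(rep(s, 5), 5, byrow = TRUE)
  rec <- new_recording(dat, fs, toy_meta(60))
  ep <- epoch_pair(rec, s + 0.8 * rnorm(n), length = 1)
  pr <- permutation_test(ep, ref = "LFP1", n_perm = 10, seed = 5, extent = 1)
  in_band <- pr$freqs >= 19 & pr$freqs <= 21
  hit <- which(rowSums(pr$mask[, in_band, drop = FALSE]) > 0)
  expect_gte(length(intersect(hit, 1:5)), 4L)
  expect_lte(length(setdiff(hit, 1:5)), 1L)
})

test_that("sphere lead field: radial silence, rotation equivariance, oracle", {
  sens <- toy_array(12)
  lf <- sphere_leadfield(rbind(c(0.02, 0.01, 0.04)), sens)
  # radial dipole (along the position vector) is silent
  r0 <- c(0.02, 0.01, 0.04)
  B_rad <- lf$L[1, , ] %*% (r0 / sqrt(sum(r0^2)))
  tang <- c(-0.01, 0.02, 0) - sum(c(-0.01, 0.02, 0) * r0) * r0 / sum(r0^2)
  B_tan <- lf$L[1, , ] %*% (tang / sqrt(sum(tang^2)))
  expect_lt(max(abs(B_rad)), 1e-10 * max(abs(B_tan)))

  # independent transcription of the closed-form field as an oracle
  oracle <- function(r, r0, Q) {
    a <- r - r0
    na <- sqrt(sum(a * a)); nr <- sqrt(sum(r * r))
    F_ <- na * (nr * na + nr^2 - sum(r0 * r))
    gF <- (na^2 / nr + sum(a * r) / na + 2 * na + 2 * nr) * r -
      (na + 2 * nr + sum(a * r) / na) * r0
    qxr0 <- c(Q[2] * r0[3] - Q[3] * r0[2],
              Q[3] * r0[1] - Q[1] * r0[3],
              Q[1] * r0[2] - Q[2] * r0[1])
    1e-7 / F_^2 * (F_ * qxr0 - sum(qxr0 * r) * gF) * 1e15
  }
  set.seed(26)
  for (i in 1:100) {
    r0 <- runif(3, -0.03, 0.03)
    r <- r0 + c(0, 0, 0.2)
    Q <- rnorm(3)
    got <- perceptmeg:::sarvas_field(r, r0, Q)
    want <- oracle(r, r0, Q)
    expect_equal(got, want, tolerance = 1e-9)
  }

  # rotation equivariance: rotate source, sensors and moment together
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  r0 <- c(0.02, 0.01, 0.04); Q <- c(1, 2, 0.5); r <- c(0.05, -0.03, 0.1)
  b1 <- perceptmeg:::sarvas_field(as.numeric(R %*% r), as.numeric(R %*% r0),
                                  as.numeric(R %*% Q))
  b2 <- as.numeric(R %*% perceptmeg:::sarvas_field(r, r0, Q))
  expect_equal(b1, b2, tolerance = 1e-12)

  # centre point dropped with warning; outside-sphere grid errors
  expect_warning(lf0 <- sphere_leadfield(rbind(c(0, 0, 0), c(0.02, 0, 0.03)),
                                         sens), "centre")
  expect_equal(dim(lf0$L)[1], 1L)
  expect_error(sphere_leadfield(rbind(c(0, 0, 0.2)), sens), "inside")
})

test_that("DICS localises a planted coherent dipole and respects rank", {
  sens <- toy_array(20)
  grid <- toy_grid()
  lf <- sphere_leadfield(grid, sens)
  src_i <- which.min(colSums((t(grid) - c(0.02, 0.01, 0.04))^2))
  hits <- vapply(1:8, function(sd_i) {
    ep <- coupled_epochs(lf, src_i, seed = sd_i)
    dm <- dics_band(ep, ref = "LFP1", band = c(15, 35), lf, rank = 20)
    est <- dm$grid[which.max(dm$values), ]
    sqrt(sum((est - grid[src_i, ])^2))
  }, numeric(1))
  expect_true(all(hits <= 0.015))   # within one 10 mm grid step

  ep <- coupled_epochs(lf, src_i, seed = 99)
  # full-rank truncation equals the unregularised inverse
  d_full <- dics_band(ep, ref = "LFP1", band = c(15, 35), lf, rank = 20)
  expect_warning(d_clamp <- dics_band(ep, ref = "LFP1", band = c(15, 35),
                                      lf, rank = 150), "clamped")
  expect_equal(d_full$values, d_clamp$values, tolerance = 1e-9)
  expect_true(all(d_full$values >= 0 & d_full$values <= 1 + 1e-9))

  # paired comparison: uncoupled reference yields a weaker image maximum
  ep0 <- coupled_epochs(lf, src_i, gamma = 0, seed = 31)
  ep1 <- coupled_epochs(lf, src_i, gamma = 0.6, seed = 31)
  z0 <- max(dics_band(ep0, ref = "LFP1", band = c(15, 35), lf, rank = 20)$values)
  z1 <- max(dics_band(ep1, ref = "LFP1", band = c(15, 35), lf, rank = 20)$values)
  expect_gt(z1, z0)

  expect_error(dics_band(ep, ref = "LFP1", band = c(300, 400), lf, rank = 20),
               "outside")
})

test_that("a simulated sensorimotor-like coherent source maps to its quadrant", {
  # structural mirror of the patient analysis: a dipole coherent with the
  # right-hemisphere LFP in the beta band produces an image argmax in the
  # correct hemisphere quadrant
  sens <- toy_array(20)
  grid <- toy_grid()
  lf <- sphere_leadfield(grid, sens)
  src_i <- which.min(colSums((t(grid) - c(0.03, 0.02, 0.04))^2))
  ep <- coupled_epochs(lf, src_i, seed = 41, gamma = 0.5)
  dm <- dics_band(ep, ref = "LFP1", band = c(15, 35), lf, rank = 20)
  est <- dm$grid[which.max(dm$z), ]
  expect_gt(est[1], 0)   # same x-hemisphere as the planted source
})
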
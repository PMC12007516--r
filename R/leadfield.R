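#' Analytic single-sphere lead field
#'
#' Magnetic field of a current dipole inside a homogeneous conducting sphere
#' (Sarvas closed form). Radially oriented dipoles are magnetically silent, so
#' each grid point effectively spans a two-dimensional tangential source
#' space. Channel responses follow the channel type in `sensors`:
#' magnetometers project the field on the sensing orientation, axial
#' gradiometers take the difference between the field at the coil and at a
#' second coil one baseline further out along the orientation, and planar
#' gradiometers return the tangential finite difference per millimetre
#' (fT/mm).
#'
#' @param grid Numeric matrix n x 3 of source positions (m), in the sphere
#'   frame.
#' @param sensors Channel metadata data frame as in [new_recording()]
#'   (columns `type`, `px..pz`, `ox..oz`, `dx..dz`), plus optionally
#'   `baseline` (m) for axial/planar gradiometers via the `baseline` argument.
#' @param sphere_center Length-3 numeric, centre of the conductor sphere (m).
#' @param baseline Gradiometer baseline (m); default 0.05 for axial, the
#'   planar coil separation for planar types.
#' @return Object of class `lead_field`: list with `L` (array
#'   n_grid x n_channels x 3, field per unit dipole moment along x,y,z),
#'   `grid`, `sensors`, `sphere_center`. Grid points at the sphere centre are
#'   dropped with a warning (orientation basis undefined).
#' @examples
#' prof <- make_profile("opm")
#' sens <- prof$geometry[1:10, ]
#' lf <- sphere_leadfield(rbind(c(0.02, 0, 0.04)), sens)
#' dim(lf$L)
#' @export
sphere_leadfield <- function(grid, sensors, sphere_center = c(0, 0, 0),
                             baseline = 0.05) {
  grid <- matrix(as.numeric(grid), ncol = 3)
  center_dist <- sqrt(rowSums(sweep(grid, 2, sphere_center)^2))
  if (any(center_dist < 1e-9)) {
    warning("dropping ", sum(center_dist < 1e-9),
            " grid point(s) at the sphere centre (orientation undefined)")
    grid <- grid[center_dist >= 1e-9, , drop = FALSE]
  }
  sens_r <- sqrt(rowSums((as.matrix(sensors[, c("px", "py", "pz")]) -
                            matrix(sphere_center, nrow(sensors), 3,
                                   byrow = TRUE))^2))
  if (any(sqrt(rowSums(sweep(grid, 2, sphere_center)^2)) >= min(sens_r)))
    stop("all grid points must lie strictly inside the sensor sphere radius")
  n_grid <- nrow(grid)
  n_ch <- nrow(sensors)
  L <- array(0, dim = c(n_grid, n_ch, 3))
  I3 <- diag(3)
  for (g in seq_len(n_grid)) {
    r0 <- grid[g, ] - sphere_center
    for (ch in seq_len(n_ch)) {
      pos <- as.numeric(sensors[ch, c("px", "py", "pz")]) - sphere_center
      ori <- as.numeric(sensors[ch, c("ox", "oy", "oz")])
      type <- sensors$type[ch]
      for (q in 1:3) {
        Q <- I3[q, ]
        L[g, ch, q] <- switch(type,
          mag = sum(sarvas_field(pos, r0, Q) * ori),
          lfp = 0,
          axial_grad = {
            b1 <- sum(sarvas_field(pos, r0, Q) * ori)
            b2 <- sum(sarvas_field(pos + baseline * ori, r0, Q) * ori)
            b1 - b2
          },
          planar_grad = {
            pd <- as.numeric(sensors[ch, c("dx", "dy", "dz")])
            d <- if (is.finite(sensors$baseline[1] %||% NA)) sensors$baseline[1] else 0.0168
            bp <- sum(sarvas_field(pos + d / 2 * pd, r0, Q) * ori)
            bm <- sum(sarvas_field(pos - d / 2 * pd, r0, Q) * ori)
            (bp - bm) / (d * 1000)     # per mm
          },
          stop("unknown channel type '", type, "'")
        )
      }
    }
  }
  structure(list(L = L, grid = grid, sensors = sensors,
                 sphere_center = sphere_center, baseline = baseline),
            class = "lead_field")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Sarvas (1987) closed-form field of a current dipole Q (A*m) at r0 inside a
# conducting sphere centred at the origin, evaluated at sensor position r (m).
# Returns field in fT (mu0/4pi = 1e-7 T*m/A, scaled by 1e15).
#' @noRd
sarvas_field <- function(r, r0, Q) {
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2))
  R <- sqrt(sum(r^2))
  ar <- sum(a_vec * r)
  F_ <- a * (R * a + R^2 - sum(r0 * r))
  if (abs(F_) < 1e-30) return(c(0, 0, 0))
  gradF <- (a^2 / R + ar / a + 2 * a + 2 * R) * r -
    (a + 2 * R + ar / a) * r0
  Qxr0 <- cross3(Q, r0)
  B <- 1e-7 / F_^2 * (F_ * Qxr0 - sum(Qxr0 * r) * gradF)
  B * 1e15
}

#' @export
print.lead_field <- function(x, ...) {
  cat("<lead_field>", dim(x$L)[1], "grid points x", dim(x$L)[2],
      "channels x 3 orientations\n")
  invisible(x)
}
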
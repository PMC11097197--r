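#' Time-resolved 2D velocity field on a uniform grid
#'
#' In-plane vector field with an isotropic uniform grid and a lumen mask.
#' Arrays are indexed `[y, x, t]` with `y` increasing upward and `x`
#' increasing rightward (physical frame; image readers/writers perform the
#' row flip).
#'
#' @param x,y Grid node coordinates in mm (uniform, same spacing in both
#'   axes).
#' @param time Time stamps in s.
#' @param vx,vy Velocity components in cm/s, arrays `[length(y), length(x),
#'   length(time)]` (a matrix is accepted for a single time sample).
#' @param mask Logical lumen mask `[length(y), length(x)]`; `TRUE` inside the
#'   lumen. Defaults to all `TRUE`.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(x, y, time, vx, vy,
                           mask = matrix(TRUE, length(y), length(x))) {
  nx <- length(x); ny <- length(y); nt <- length(time)
  if (nx < 2L || ny < 2L) stop("grid needs at least 2 nodes per axis")
  dx <- diff(x); dy <- diff(y)
  if (any(dx <= 0) || any(dy <= 0)) stop("grid coordinates must increase")
  sp <- dx[1]
  if (max(abs(c(dx, dy) - sp)) > 1e-6 * sp)
    stop("grid spacing must be uniform and isotropic")
  dim3 <- c(ny, nx, nt)
  vx <- array(vx, dim3); vy <- array(vy, dim3)
  mask <- matrix(as.logical(mask), ny, nx)
  inside <- which(rep(mask, nt))
  if (any(!is.finite(vx[inside])) || any(!is.finite(vy[inside])))
    stop("velocity components must be finite inside the mask")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 time = as.numeric(time), vx = vx, vy = vy, mask = mask,
                 spacing = sp),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("Velocity field: %d x %d nodes (%.3g mm spacing), %d time samples\n",
              length(x$x), length(x$y), x$spacing, length(x$time)))
  sp <- sqrt(x$vx^2 + x$vy^2)
  cat(sprintf("  %d lumen nodes; peak speed %.4g cm/s\n",
              sum(x$mask), max(sp[rep(x$mask, length(x$time))], 0)))
  invisible(x)
}

#' @export
plot.velocity_field <- function(x, t_index = 1L, skip = 2L, scale = NULL,
                                ...) {
  sp <- sqrt(x$vx[, , t_index]^2 + x$vy[, , t_index]^2)
  graphics::image(x$x, x$y, t(sp), xlab = "x (mm)", ylab = "y (mm)",
                  col = grDevices::hcl.colors(64, "viridis"), asp = 1, ...)
  ii <- seq(1, length(x$y), by = skip); jj <- seq(1, length(x$x), by = skip)
  if (is.null(scale)) scale <- 2 * x$spacing * skip / max(sp, 1e-9)
  xs <- rep(x$x[jj], each = length(ii)); ys <- rep(x$y[ii], length(jj))
  u <- as.vector(x$vx[ii, jj, t_index]); v <- as.vector(x$vy[ii, jj, t_index])
  keep <- as.vector(x$mask[ii, jj]) & (abs(u) + abs(v) > 0)
  graphics::arrows(xs[keep], ys[keep], xs[keep] + scale * u[keep],
                   ys[keep] + scale * v[keep], length = 0.03)
  invisible(x)
}

#' Straight-tube field from a radial velocity profile
#'
#' Extrudes an axial velocity profile along a straight horizontal tube:
#' `vx(x, y, t) = u(r = y, t)`, `vy = 0`, lumen `|y| <= R`.
#'
#' @param profile A [flow_profile].
#' @param length_mm Tube length in mm.
#' @param grid_spacing Grid spacing in mm.
#' @return A [velocity_field] in cm/s.
#' @export
straight_tube_field <- function(profile, length_mm = 30,
                                grid_spacing = 0.25) {
  stopifnot(inherits(profile, "flow_profile"))
  R <- profile$radius
  x <- seq(0, length_mm, by = grid_spacing)
  y <- seq(-R, R, by = grid_spacing)
  nt <- length(profile$time)
  u_y <- apply(profile$u, 2, function(col)
    stats::approx(profile$r, col, xout = y, rule = 2)$y)
  u_y <- matrix(u_y, length(y), nt)
  vx <- array(0, c(length(y), length(x), nt))
  for (k in seq_len(nt)) vx[, , k] <- matrix(u_y[, k], length(y), length(x))
  mask <- matrix(abs(y) <= R + 1e-9, length(y), length(x))
  vx[!rep(mask, nt)] <- 0
  velocity_field(x, y, profile$time, vx, array(0, dim(vx)), mask)
}

#' Analytic stenotic-jet velocity field with recirculation
#'
#' Divergence-free 2D surrogate of post-stenotic flow: a smooth contraction
#' of the lumen at the stenosis, a jet whose mean velocity scales as
#' `inlet / (1 - area_reduction)`, and symmetric recirculation zones beside
#' the jet that decay over `jet_length`. The field is built from a
#' streamfunction and differentiated by central differences, so its discrete
#' divergence vanishes identically and the cross-sectional flux is the same
#' through every section at each time.
#'
#' The planar slice carries a 2D flux calibrated so that the straight-section
#' centerline velocity matches the axisymmetric Poiseuille value for the
#' waveform's flow rate (`flux = (8/3) Q / (pi R)`).
#'
#' @param vessel A [vessel_spec]; CFA radius and stenosis severity are used.
#' @param waveform A [flow_waveform] driving the inflow (mL/s). Time samples
#'   may be thinned with `time_indices`.
#' @param jet_length Decay length of the jet/recirculation pattern in mm.
#' @param grid_spacing Grid spacing in mm.
#' @param vessel_length Domain length in mm.
#' @param stenosis_center Stenosis position along the vessel in mm.
#' @param time_indices Indices of waveform samples to realise (default: all).
#' @return A [velocity_field]; the per-time target flux (cm/s x mm units) is
#'   stored in attribute `"flux"`.
#' @export
stenotic_field <- function(vessel, waveform, jet_length = 15,
                           grid_spacing = 0.2, vessel_length = 40,
                           stenosis_center = 10,
                           time_indices = seq_along(waveform$time)) {
  stopifnot(inherits(vessel, "vessel_spec"), inherits(waveform, "flow_waveform"))
  ar <- vessel$stenosis_area_reduction
  if (ar >= 1) stop("`stenosis_area_reduction` must be < 1")
  if (grid_spacing <= 0) stop("`grid_spacing` must be positive")
  R0 <- vessel$cfa_diameter / 2
  sig_s <- 2.5   # stenosis throat half-width parameter, mm

  x <- seq(0, vessel_length, by = grid_spacing)
  y <- seq(-R0, R0, by = grid_spacing)
  nx <- length(x); ny <- length(y)

  half_width <- function(xx)
    R0 * (1 - ar * exp(-((xx - stenosis_center) / sig_s)^2))
  # jet-shape blending: off upstream, on just after the throat, exponential
  # decay over jet_length
  blend <- function(xx) {
    if (ar <= 0) return(0 * xx)
    on <- 1 / (1 + exp(-(xx - stenosis_center - 1.5 * sig_s) / 1.0))
    decay <- exp(-pmax(xx - stenosis_center - 1.5 * sig_s, 0) / jet_length)
    on * decay
  }
  # normalized cross-stream shapes of vx (eta = y / h in [-1, 1])
  eta_fine <- seq(-1, 1, length.out = 401)
  parab <- 1.5 * (1 - eta_fine^2)
  jet <- (1 - eta_fine^2) *
    (exp(-(eta_fine / 0.35)^2) - 0.5 * exp(-((abs(eta_fine) - 0.8) / 0.15)^2))

  # streamfunction shape g(eta, x): integral of the blended vx shape,
  # normalized to g(-1) = -1, g(1) = 1 so the flux is x-invariant
  g_of <- function(beta) {
    w <- (1 - beta) * parab + beta * jet
    ci <- pracma::cumtrapz(eta_fine, w)
    -1 + 2 * ci / ci[length(ci)]
  }

  # pad by one node each side for the central differences
  xp <- c(x[1] - grid_spacing, x, x[nx] + grid_spacing)
  yp <- c(y[1] - grid_spacing, y, y[ny] + grid_spacing)
  hx <- half_width(xp)
  bx <- blend(xp)
  g_cols <- vapply(seq_along(xp), function(j) {
    eta <- pmin(pmax(yp / hx[j], -1), 1)
    stats::approx(eta_fine, g_of(bx[j]), xout = eta)$y
  }, numeric(length(yp)))            # [ny+2, nx+2]

  q_mm3 <- waveform$flow_rate[time_indices] * 1000
  flux <- (8 / 3) * q_mm3 / (pi * R0)      # 2D flux, mm^2/s
  nt <- length(time_indices)

  vx <- array(0, c(ny, nx, nt)); vy <- array(0, c(ny, nx, nt))
  ii <- 2:(ny + 1); jj <- 2:(nx + 1)
  dpsi_dy <- (g_cols[ii + 1, jj] - g_cols[ii - 1, jj]) / (2 * grid_spacing)
  dpsi_dx <- (g_cols[ii, jj + 1] - g_cols[ii, jj - 1]) / (2 * grid_spacing)
  mask <- outer(seq_len(ny), seq_len(nx),
                function(i, j) abs(y[i]) <= half_width(x[j]) + 1e-9)
  # no masking of the differentiated field: outside the lumen psi is
  # constant so vx, vy vanish there anyway, and keeping the raw central
  # differences preserves the telescoping cross-section flux exactly
  for (k in seq_len(nt)) {
    a <- flux[k] / 2 / 10            # psi scale; mm/s -> cm/s
    vx[, , k] <- a * dpsi_dy
    vy[, , k] <- -a * dpsi_dx
  }
  out <- velocity_field(x, y, waveform$time[time_indices], vx, vy, mask)
  attr(out, "flux") <- flux / 10     # cm/s * mm per cross-section
  out
}

# Bilinear interpolation of one time slice of a field component.
# `xq`, `yq` in mm; values outside the grid clamp to the edge.
.interp_bilinear <- function(gx, gy, z, xq, yq) {
  nx <- length(gx); ny <- length(gy)
  sx <- (xq - gx[1]) / (gx[2] - gx[1])
  sy <- (yq - gy[1]) / (gy[2] - gy[1])
  j0 <- pmin(pmax(floor(sx), 0), nx - 2); i0 <- pmin(pmax(floor(sy), 0), ny - 2)
  fx <- pmin(pmax(sx - j0, 0), 1); fy <- pmin(pmax(sy - i0, 0), 1)
  i0 <- i0 + 1L; j0 <- j0 + 1L
  z[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    z[cbind(i0, j0 + 1L)] * fx * (1 - fy) +
    z[cbind(i0 + 1L, j0)] * (1 - fx) * fy +
    z[cbind(i0 + 1L, j0 + 1L)] * fx * fy
}

# Velocity (cm/s) at arbitrary points and time, with linear interpolation in
# time between the field's stored samples.
.field_velocity_at <- function(field, xq, yq, t) {
  tt <- field$time
  if (length(tt) == 1L) {
    k0 <- 1L; k1 <- 1L; w <- 0
  } else {
    k0 <- findInterval(t, tt, rightmost.closed = TRUE)
    k0 <- pmin(pmax(k0, 1L), length(tt) - 1L)
    k1 <- k0 + 1L
    w <- (t - tt[k0]) / (tt[k1] - tt[k0])
    w <- pmin(pmax(w, 0), 1)
  }
  vx <- (1 - w) * .interp_bilinear(field$x, field$y, field$vx[, , k0], xq, yq) +
    w * .interp_bilinear(field$x, field$y, field$vx[, , k1], xq, yq)
  vy <- (1 - w) * .interp_bilinear(field$x, field$y, field$vy[, , k0], xq, yq) +
    w * .interp_bilinear(field$x, field$y, field$vy[, , k1], xq, yq)
  list(vx = vx, vy = vy)
}

# Linear temporal interpolation of a field at arbitrary times (clamped to
# the stored range); returns a velocity_field on the same grid.
.field_time_slices <- function(field, times) {
  nt <- length(field$time)
  ny <- length(field$y); nx <- length(field$x)
  vx <- array(0, c(ny, nx, length(times)))
  vy <- vx
  for (j in seq_along(times)) {
    if (nt == 1L) { k0 <- 1L; k1 <- 1L; w <- 0 } else {
      k0 <- min(max(findInterval(times[j], field$time,
                                 rightmost.closed = TRUE), 1L), nt - 1L)
      k1 <- k0 + 1L
      w <- min(max((times[j] - field$time[k0]) /
                     (field$time[k1] - field$time[k0]), 0), 1)
    }
    vx[, , j] <- (1 - w) * field$vx[, , k0] + w * field$vx[, , k1]
    vy[, , j] <- (1 - w) * field$vy[, , k0] + w * field$vy[, , k1]
  }
  velocity_field(field$x, field$y, times, vx, vy, field$mask)
}

#' Cross-sectional flux of a field at every station along x
#'
#' Trapezoidal integral of `vx` over the full y extent (velocities are zero
#' outside the lumen), per time sample. Used to verify conservation of the
#' analytic phantom fields.
#'
#' @param field A [velocity_field].
#' @return Matrix `[n_x, n_t]` of fluxes in cm/s x mm.
#' @export
field_flux <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  nt <- length(field$time)
  out <- matrix(NA_real_, length(field$x), nt)
  for (k in seq_len(nt))
    for (j in seq_along(field$x))
      out[j, k] <- pracma::trapz(field$y, field$vx[, j, k])
  out
}
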
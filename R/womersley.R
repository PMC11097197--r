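# Bessel J0/J1 at complex argument via the integral representation
#   J_n(z) = (1/pi) * int_0^pi cos(n*theta - z*sin(theta)) dtheta,
# valid for all complex z (integer n). Gauss-Legendre quadrature on [0, pi];
# 200 nodes resolve the <= ~10 oscillations of the integrand at the argument
# magnitudes reached by 20 harmonics of a femoral-scale Womersley number.
.bessel_gl <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(200, 0, pi)
    cache
  }
})

besselJ_complex <- function(z, nu = 0L) {
  gl <- .bessel_gl()
  st <- sin(gl$x)
  # rows: quadrature nodes, cols: elements of z
  arg <- outer(st, z, function(s, zz) -zz * s) + nu * gl$x
  drop(crossprod(gl$w, cos(arg))) / pi
}

# Complex frequency parameter Lambda = i^(3/2) * alpha of the oscillatory
# pipe-flow solution.
.womersley_lambda <- function(alpha) alpha * exp(1i * 3 * pi / 4)

# Flow-weighted Bessel factor F = 2 J1(L) / (L J0(L)); the profile of
# harmonic k is u(r) = A (1 - J0(L r/R)/J0(L)) with Q = A pi R^2 (1 - F).
.womersley_F <- function(lambda) {
  2 * besselJ_complex(lambda, 1L) / (lambda * besselJ_complex(lambda, 0L))
}

#' Womersley number
#'
#' `alpha = R * sqrt(omega / nu)` with `omega = 2*pi*frequency`, the
#' dimensionless ratio of oscillatory inertial to viscous forces.
#'
#' @param radius Vessel radius in mm.
#' @param frequency Oscillation frequency in Hz.
#' @param fluid A [fluid_props].
#' @return The dimensionless Womersley number.
#' @examples
#' womersley_number(4.45, 1, fluid_props(1144, 4.17e-3))  # ~5.84
#' @export
womersley_number <- function(radius, frequency, fluid = fluid_props()) {
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be positive")
  (radius * 1e-3) * sqrt(2 * pi * frequency / fluid$kinematic_viscosity)
}

#' Time-resolved axial velocity profile across a vessel diameter
#'
#' @param r Radial coordinate in mm spanning `[-R, R]`, symmetric about 0.
#' @param time Sample times in s.
#' @param u Axial velocity in cm/s, matrix `length(r)` x `length(time)`.
#' @param radius Vessel radius R in mm.
#' @return An object of class `flow_profile`.
#' @export
flow_profile <- function(r, time, u, radius) {
  u <- as.matrix(u)
  if (nrow(u) != length(r) || ncol(u) != length(time))
    stop("`u` must be length(r) x length(time)")
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be positive")
  if (max(abs(r + rev(r))) > 1e-9 * radius)
    stop("`r` must be symmetric about 0")
  structure(list(r = as.numeric(r), time = as.numeric(time), u = u,
                 radius = radius),
            class = "flow_profile")
}

#' Pulsatile Womersley velocity profile from a flow waveform
#'
#' Decomposes the uniformly sampled periodic waveform into Fourier harmonics
#' and superposes the steady Poiseuille component with the per-harmonic
#' oscillatory pipe-flow (Womersley) solutions, whose complex Bessel-function
#' profiles are scaled so the cross-sectional integral of the result
#' reproduces each flow harmonic. The profile satisfies no-slip exactly:
#' `u(+/-R, t) = 0`.
#'
#' @param waveform A [flow_waveform] (mL/s), uniformly sampled.
#' @param radius Vessel radius in mm.
#' @param fluid A [fluid_props].
#' @param n_harmonics Number of Fourier harmonics retained (>= 1).
#' @param n_r Number of radial samples across the diameter (odd recommended).
#' @return A [flow_profile] with velocities in cm/s on the waveform's time
#'   base.
#' @export
womersley_profile <- function(waveform, radius, fluid = fluid_props(),
                              n_harmonics = 20L, n_r = 101L) {
  stopifnot(inherits(waveform, "flow_waveform"))
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be positive")
  if (n_harmonics < 1L) stop("`n_harmonics` must be >= 1")

  t <- waveform$time
  q <- waveform$flow_rate * 1000   # mL/s -> mm^3/s
  n <- length(t)
  # drop the duplicated endpoint (if present) for the DFT
  span <- max(t) - min(t)
  if (abs(span - waveform$period) < 1e-9 * waveform$period) n <- n - 1L
  ch <- stats::fft(q[seq_len(n)]) / n
  n_harm <- min(n_harmonics, (n - 1L) %/% 2L)

  r <- seq(-radius, radius, length.out = n_r)
  xi <- r / radius
  area <- pi * radius^2
  # steady Poiseuille term
  q0 <- Re(ch[1])
  u <- outer((2 * q0 / area) * (1 - xi^2), rep(1, length(t)))

  nu_mm <- fluid$kinematic_viscosity * 1e6   # m^2/s -> mm^2/s
  for (k in seq_len(n_harm)) {
    omega <- 2 * pi * k / waveform$period
    alpha <- radius * sqrt(omega / nu_mm)
    lambda <- .womersley_lambda(alpha)
    j0l <- besselJ_complex(lambda, 0L)
    shape <- 1 - besselJ_complex(lambda * xi, 0L) / j0l   # 0 at |xi| = 1
    a_k <- ch[k + 1] / (area * (1 - .womersley_F(lambda)))
    u <- u + Re(outer(2 * a_k * shape, exp(1i * omega * t)))
  }
  u[c(1L, n_r), ] <- 0   # enforce exact no-slip against quadrature residue
  flow_profile(r, t, u / 10, radius)   # mm/s -> cm/s
}

#' Steady Poiseuille velocity profile
#'
#' Parabolic profile `u(r) = u_max (1 - r^2/R^2)` with
#' `u_max = 2 Q / (pi R^2)`; the steady special case of the pulsatile
#' fully-developed-flow theory.
#'
#' @param flow_rate Steady volumetric flow rate in mL/s.
#' @param radius Vessel radius in mm.
#' @param time Time stamps for the (time-invariant) profile, s.
#' @param n_r Number of radial samples.
#' @return A [flow_profile] in cm/s.
#' @examples
#' p <- poiseuille_profile(10, 4.45)
#' max(p$u)  # ~32.1 cm/s at the centerline
#' @export
poiseuille_profile <- function(flow_rate, radius, time = 0, n_r = 101L) {
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be positive")
  r <- seq(-radius, radius, length.out = n_r)
  u_max <- 2 * (flow_rate * 1000) / (pi * radius^2)   # mm/s
  u <- outer(u_max * (1 - (r / radius)^2), rep(1, length(time)))
  flow_profile(r, time, u / 10, radius)
}

# Centerline velocity (mm/s) per unit flow (mm^3/s) for harmonic k of the
# Womersley solution; steady term is 2 / (pi R^2).
.centerline_factor <- function(alpha, radius) {
  if (alpha == 0) return(2 / (pi * radius^2))
  lambda <- .womersley_lambda(alpha)
  j0l <- besselJ_complex(lambda, 0L)
  (1 - 1 / j0l) / (pi * radius^2 * (1 - .womersley_F(lambda)))
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("Velocity profile: %d radial x %d time samples, R = %g mm\n",
              length(x$r), length(x$time), x$radius))
  cat(sprintf("  peak |u| = %.4g cm/s\n", max(abs(x$u))))
  invisible(x)
}

#' @export
plot.flow_profile <- function(x, t_index = which.max(apply(abs(x$u), 2, max)),
                              ...) {
  graphics::plot(x$r, x$u[, t_index], type = "l", xlab = "r (mm)",
                 ylab = "axial velocity (cm/s)", ...)
  graphics::abline(v = c(-x$radius, x$radius), lty = 3)
  invisible(x)
}
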
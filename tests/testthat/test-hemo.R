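test_that("diameter integration matches closed forms to 0.1%", {
  # parabolic: Q = pi u_max R^2 / 2 (u in cm/s, r in mm -> mL/s via units)
  p <- parabolic_profile(1, 1, n_r = 201)
  q <- flow_rate_from_profile(p)
  expect_equal(q$flow_rate[1], pi * 10 * 1^2 / 2 / 1000, tolerance = 1e-3)
  # uniform u = 1 cm/s, R = 1 mm -> Q = pi c R^2
  r <- seq(-1, 1, length.out = 201)
  u <- matrix(1, 201, 1)
  q2 <- flow_rate_from_profile(flow_profile(r, 0, u, 1))
  expect_equal(q2$flow_rate[1], pi * 10 * 1^2 / 1000, tolerance = 1e-3)
  # zero velocity integrates to zero
  q3 <- flow_rate_from_profile(flow_profile(r, 0, 0 * u, 1))
  expect_equal(q3$flow_rate[1], 0)
})

test_that("profiles not reaching the wall are extrapolated with a warning", {
  r <- seq(-0.8, 0.8, length.out = 81)
  u <- matrix(1 - r^2, 81, 1)
  expect_warning(q <- flow_rate_from_profile(flow_profile(r, 0, u, 1)),
                 "extrapolat")
  expect_gt(q$flow_rate[1], 0)
})

test_that("centerline inversion recovers steady and pulsatile flow", {
  # steady: v = 32.1 cm/s at R = 4.45 mm -> ~10 mL/s
  q <- flow_rate_from_centerline(rep(32.148, 101), 1, 4.45)
  expect_equal(mean(q$flow_rate), 10, tolerance = 1e-3)
  # pulsatile round trip through the forward Womersley solution
  wf <- make_triphasic_waveform(n_samples = 401L)
  p <- womersley_profile(wf, 4.45, n_harmonics = 20L, n_r = 201)
  ctr <- p$u[101, ]
  q2 <- flow_rate_from_centerline(ctr, 1.0, 4.45, n_harmonics = 20L)
  rel <- sqrt(mean((q2$flow_rate - wf$flow_rate)^2)) /
    sqrt(mean(wf$flow_rate^2))
  expect_lt(rel, 0.01)
  # zero series maps to zero flow
  q0 <- flow_rate_from_centerline(rep(0, 50), 1, 4.45)
  expect_equal(max(abs(q0$flow_rate)), 0)
})

test_that("vector complexity reproduces the canonical direction mixtures", {
  x <- seq(0, 2, by = 0.5); y <- seq(0, 2, by = 0.5)
  mk <- function(vx, vy)
    velocity_field(x, y, 0, array(vx, c(5, 5, 1)), array(vy, c(5, 5, 1)))
  # unidirectional flow
  expect_equal(vector_complexity(mk(1, 0))$vc, 0)
  # equal and opposite
  vx <- matrix(1, 5, 5); vx[1:2, ] <- -1
  reg <- matrix(FALSE, 5, 5); reg[1:4, ] <- TRUE
  v <- vector_complexity(mk(vx, matrix(0, 5, 5)), region = reg)
  expect_equal(v$vc, 1)
  # half +x, half +y
  vx2 <- matrix(0, 5, 5); vy2 <- matrix(0, 5, 5)
  vx2[1:2, ] <- 1; vy2[3:4, ] <- 1
  v2 <- vector_complexity(mk(vx2, vy2), region = reg)
  expect_equal(v2$vc, 1 - sqrt(0.5), tolerance = 1e-12)
})

test_that("vector complexity invariances and degenerate cases", {
  set.seed(6)
  x <- seq(0, 3, by = 0.5); y <- seq(0, 3, by = 0.5)
  n <- length(x) * length(y)
  vx <- array(rnorm(n), c(7, 7, 1)); vy <- array(rnorm(n), c(7, 7, 1))
  f <- velocity_field(x, y, 0, vx, vy)
  v0 <- vector_complexity(f)$vc
  expect_gte(v0, 0); expect_lte(v0, 1)
  # uniform magnitude scaling
  fs <- velocity_field(x, y, 0, 5 * vx, 5 * vy)
  expect_equal(vector_complexity(fs)$vc, v0, tolerance = 1e-12)
  # global rotation
  th <- 0.7
  fr <- velocity_field(x, y, 0, cos(th) * vx - sin(th) * vy,
                       sin(th) * vx + cos(th) * vy)
  expect_equal(vector_complexity(fr)$vc, v0, tolerance = 1e-12)
  # all-zero region reports missing
  fz <- velocity_field(x, y, 0, 0 * vx, 0 * vy)
  expect_true(is.na(vector_complexity(fz)$vc))
})

test_that("TAWSS on steady Poiseuille matches 2 mu u_max / R within 10%", {
  R <- 4.45; u_max <- 100
  fld <- straight_tube_field(parabolic_profile(u_max, R),
                             length_mm = 10, grid_spacing = 0.2)
  mu <- fluid_props()$dynamic_viscosity
  expected <- 2 * mu * (u_max * 10) / R
  for (w in list(straight_wall_contour(-R, c(2, 8), 8, +1),
                 straight_wall_contour(R, c(2, 8), 8, -1))) {
    tw <- tawss(fld, w)
    expect_true(all(abs(tw$tawss - expected) / expected < 0.1))
  }
})

test_that("TAWSS is zero for zero flow and linear in velocity", {
  R <- 4.45
  fld <- straight_tube_field(parabolic_profile(100, R), length_mm = 10,
                             grid_spacing = 0.2)
  wall <- straight_wall_contour(-R, c(2, 8), 6, +1)
  t1 <- tawss(fld, wall)
  fld2 <- fld; fld2$vx <- 2 * fld$vx
  t2 <- tawss(fld2, wall)
  expect_equal(t2$tawss, 2 * t1$tawss, tolerance = 1e-9)
  fld0 <- fld; fld0$vx[] <- 0
  t0 <- tawss(fld0, wall)
  expect_equal(max(abs(t0$tawss)), 0)
})

test_that("TAWSS validates sampling parameters", {
  R <- 4.45
  fld <- straight_tube_field(parabolic_profile(100, R), 10, 0.2)
  wall <- straight_wall_contour(-R, c(2, 8), 6, +1)
  expect_error(tawss(fld, wall, sample_depth = 0.1), "grid spacings")
  expect_error(tawss(fld, wall, n_samples = 3), ">= 4")
})

test_that("Reynolds number reproduces the printed femoral jet value", {
  expect_equal(round(reynolds_number(1550, 8.9, 1.14e-6, 4.16e-6)), 3780)
  # linear in velocity
  expect_equal(reynolds_number(2 * 1550, 8.9, 1.14e-6, 4.16e-6),
               2 * reynolds_number(1550, 8.9, 1.14e-6, 4.16e-6))
  # invariant under a self-consistent change of units (mm,kg,s -> m,kg,s)
  expect_equal(reynolds_number(1.550, 8.9e-3, 1.14e-6 * 1e9, 4.16e-6 * 1e3),
               reynolds_number(1550, 8.9, 1.14e-6, 4.16e-6),
               tolerance = 1e-12)
  expect_error(reynolds_number(-1, 1, 1, 1), "positive")
})

test_that("Kolmogorov length follows the isotropic-turbulence scaling", {
  expect_equal(kolmogorov_length(3780, 8.9), 8.9 * 3780^(-0.75),
               tolerance = 1e-12)
  expect_equal(kolmogorov_length(3780, 8.9), 0.0185, tolerance = 1e-2)
  expect_equal(kolmogorov_length(1, 5), 5)
  re <- c(10, 100, 1000)
  expect_true(all(diff(kolmogorov_length(re, 1)) < 0))
})
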
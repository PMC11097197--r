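test_that("frame pairing conventions and pair rates", {
  p <- pair_frames(8, 8000, "non_overlapping")
  expect_equal(nrow(p), 4)
  expect_equal(p[1, ], c(a = 1L, b = 2L))
  expect_equal(attr(p, "pair_rate"), 4000)

  p2 <- pair_frames(6, 3000, "sliding")
  expect_equal(nrow(p2), 5)
  expect_equal(p2[, "b"] - p2[, "a"], rep(1L, 5))
  expect_equal(attr(p2, "pair_rate"), 3000)

  expect_equal(nrow(pair_frames(2, 1, "non_overlapping")), 1)
  expect_equal(nrow(pair_frames(2, 1, "sliding")), 1)
  expect_error(pair_frames(1), "at least 2")
})

test_that("rate arithmetic reproduces the pipeline output rates", {
  expect_equal(fields_per_second(9000, 3, "sliding", 10), 300)
  expect_equal(fields_per_second(8000, 1, "non_overlapping", 10), 400)
  expect_equal(fields_per_second(1000, 1, "sliding", 1), 1000)
  expect_error(fields_per_second(0), ">= 1")
})

test_that("uniform integer and subpixel shifts are recovered", {
  im3 <- render_uniform(3.0, seed = 21, n_frames = 4)
  g <- ncc_pass(im3, pair_frames(4, 1000, "sliding"), 32, 0.5,
                correlation_averaging_n = 3L)
  interior <- g$dx[2:(nrow(g$dx) - 1), 2:(ncol(g$dx) - 1)]
  expect_true(all(abs(interior - 3.0) < 0.05))

  imq <- render_uniform(0.25, seed = 22)
  gq <- ncc_pass(imq, pair_frames(4, 1000, "sliding"), 32, 0.5)
  expect_lt(abs(mean(gq$dx, na.rm = TRUE) - 0.25), 0.05)
})

test_that("identical frame pair yields zero displacement", {
  im <- render_uniform(0, seed = 23, n_frames = 2)
  g <- ncc_pass(im, cbind(a = 1L, b = 1L), 32, 0.5)
  expect_equal(max(abs(g$dx), na.rm = TRUE), 0)
  expect_equal(max(abs(g$dy), na.rm = TRUE), 0)
})

test_that("uniform-translation recovery holds across the working range", {
  # displacements from 0.1 to 0.4 x final window; mean error < 0.1 px
  sch <- piv_schedule(c(32L, 16L), 0.5)
  for (d in c(0.4, 1.6, 3.7, 6.4)) {
    im <- render_uniform(d, seed = 100 + round(10 * d))
    pf <- multipass_piv(im, sch)
    disp <- pf$vx / (im$pixel_size * im$frame_rate / 10)
    expect_lt(abs(mean(disp) - d), 0.1)
  }
})

test_that("Galilean shift moves every recovered vector by the added offset", {
  sch <- piv_schedule(c(32L, 16L), 0.5)
  base <- 1.3; offset <- 2.0
  im_a <- render_uniform(base, seed = 31)
  im_b <- render_uniform(base + offset, seed = 31)
  pa <- multipass_piv(im_a, sch)
  pb <- multipass_piv(im_b, sch)
  dd <- (pb$vx - pa$vx) / (im_a$pixel_size * im_a$frame_rate / 10)
  expect_lt(abs(mean(dd) - offset), 0.1)
})

test_that("grid spacing law holds exactly", {
  im <- render_uniform(1.0, seed = 33)
  pf <- multipass_piv(im, piv_schedule(c(32L, 16L), 0.5))
  expect_equal(diff(pf$x)[1], 16 * 0.5 * im$pixel_size)
  # the optical preset on 0.0525 mm pixels gives 0.42 mm vector spacing
  expect_equal(16 * (1 - 0.5) * 0.0525, 0.42)
})

test_that("zero-flow sequence stays at the noise floor", {
  im <- render_uniform(0, seed = 35, noise_sd = 2)
  pf <- multipass_piv(im, piv_schedule(c(32L, 16L), 0.5))
  expect_lt(max(abs(pf$vx), abs(pf$vy)),
            0.01 * im$pixel_size * im$frame_rate / 10 * 10)
})

test_that("multipass recovers a Poiseuille profile within 5% of u_max", {
  prof <- parabolic_profile(32.1, 4.45)
  fld <- straight_tube_field(prof, length_mm = 15, grid_spacing = 0.2)
  im <- render_particle_images(fld, pixel_size = 0.075, frame_rate = 4000,
                               n_frames = 6, seed = 41)
  pf <- multipass_piv(im, piv_schedule(c(32L, 16L), 0.5),
                      origin = c(min(fld$x), min(fld$y)))
  truth <- stats::approx(prof$r, prof$u[, 1], xout = pf$y, rule = 2)$y
  interior <- abs(pf$y) < 0.8 * 4.45
  err <- sweep(pf$vx[, , 1], 1, truth)
  expect_lt(sqrt(mean(err[interior, ]^2)) / max(prof$u), 0.05)
})

test_that("correlation averaging does not increase error on noisy data", {
  f <- uniform_field(2.5, frame_rate = 1000)
  f$time <- c(0, 0.012)
  im <- render_particle_images(f, seeding_density = 0.02, pixel_size = 0.05,
                               frame_rate = 1000, n_frames = 12,
                               noise_sd = 25, seed = 51)
  pairs <- pair_frames(12, 1000, "sliding")
  g1 <- ncc_pass(im, pairs[1, , drop = FALSE], 16, 0.5,
                 correlation_averaging_n = 1L)
  g10 <- ncc_pass(im, pairs[1:10, ], 16, 0.5, correlation_averaging_n = 10L)
  rms1 <- sqrt(mean((g1$dx - 2.5)^2, na.rm = TRUE))
  rms10 <- sqrt(mean((g10$dx - 2.5)^2, na.rm = TRUE))
  expect_lte(rms10, rms1)
})

test_that("schedule validation and oversized windows error", {
  expect_error(piv_schedule(c(16L, 32L)), "non-increasing")
  expect_error(piv_schedule(c(16L, 4L)), "8 px")
  im <- render_uniform(1, seed = 61)
  expect_error(multipass_piv(im, piv_schedule(256L)), "exceeds image size")
})

test_that("named presets match the published pipelines", {
  op <- piv_preset("opiv")
  expect_equal(op$window_sizes, c(64L, 32L, 16L))
  expect_equal(op$overlap, 0.5)
  expect_equal(op$pairing, "non_overlapping")
  ec <- piv_preset("epiv_control")
  expect_equal(ec$window_sizes, c(32L, 32L, 16L, 16L, 8L, 8L))
  expect_equal(ec$overlap, 0.75)
  expect_equal(ec$correlation_averaging_n, 10L)
  es <- piv_preset("epiv_stenosed")
  expect_equal(es$window_sizes[1:2], c(64L, 64L))
  expect_equal(es$window_sizes[-(1:2)], ec$window_sizes)
})

test_that("optical preprocessing removes a constant background", {
  im <- render_uniform(1.5, seed = 71, n_frames = 6)
  bg <- 40
  lifted <- im
  lifted$frames <- lapply(im$frames, function(f) f * (215 / 255) + bg)
  scaled <- im
  scaled$frames <- lapply(im$frames, function(f) f * (215 / 255))
  # a constant additive background cancels exactly in the moving minimum
  out_l <- suppressWarnings(preprocess_optical(lifted, 500, clahe_clip = NA))
  out_0 <- suppressWarnings(preprocess_optical(scaled, 500, clahe_clip = NA))
  resid <- max(mapply(function(a, b) max(abs(a - b)), out_l$frames,
                      out_0$frames))
  expect_lte(resid, 1)
  # window longer than the sequence falls back with a warning
  expect_warning(preprocess_optical(lifted, 500, clahe_clip = NA),
                 "global minimum")
})

test_that("all-zero frames stay zero through preprocessing", {
  z <- particle_images(list(matrix(0, 64, 64), matrix(0, 64, 64),
                            matrix(0, 64, 64)), 0.05, 1000)
  out <- preprocess_optical(z, background_window = 2)
  expect_true(all(vapply(out$frames, max, 0) == 0))
})

test_that("a static bright particle survives background subtraction minus its floor", {
  # static objects are part of the moving minimum and are removed with it;
  # this documents the contract
  f <- matrix(0, 64, 64); f[32, 32] <- 200
  seq_static <- particle_images(list(f, f, f, f), 0.05, 1000)
  out <- preprocess_optical(seq_static, background_window = 2,
                            clahe_clip = NA)
  expect_equal(out$frames[[2]][32, 32], 0)
})

test_that("postprocessing filters behave as declared", {
  im <- render_uniform(2, seed = 81, n_frames = 8)
  pf <- multipass_piv(im, piv_schedule(c(32L, 16L), 0.5))
  # identity configuration
  same <- postprocess_fields(pf, spatial_gaussian = FALSE,
                             temporal_window = 1L)
  expect_equal(same$vx, pf$vx)
  # constant field unchanged by both filters
  cf <- velocity_field(pf$x, pf$y, pf$time,
                       array(7, dim(pf$vx)), array(0, dim(pf$vx)))
  sm <- postprocess_fields(cf, spatial_gaussian = TRUE, temporal_window = 3L,
                           temporal_mode = "moving_average")
  expect_equal(sm$vx, cf$vx, tolerance = 1e-12)
  # block ensemble reduces the field rate by the window factor
  be <- postprocess_fields(pf, spatial_gaussian = FALSE,
                           temporal_window = 3L,
                           temporal_mode = "block_ensemble")
  expect_equal(length(be$time), length(pf$time) %/% 3)
})
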
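# pulsatile tube sequence spanning several identical (or jittered) cycles
make_cycles <- function(n_cycles, jitter_s = 0, seed = 1, n_t = 40,
                        radius = 4.45) {
  set.seed(seed)
  wf <- make_triphasic_waveform(n_samples = n_t + 1L)
  prof <- womersley_profile(wf, radius, n_harmonics = 8L, n_r = 41)
  f1 <- straight_tube_field(prof, length_mm = 8, grid_spacing = 0.5)
  ny <- length(f1$y); nx <- length(f1$x)
  times <- c(); vx <- NULL
  for (c in seq_len(n_cycles)) {
    dtau <- if (jitter_s > 0) stats::runif(1, -jitter_s, jitter_s) else 0
    tt <- f1$time[-(n_t + 1L)] + (c - 1)
    # jitter shifts the waveform phase within the cycle
    shift <- ((f1$time[-(n_t + 1L)] + dtau) %% 1)
    idx <- sapply(shift, function(s) which.min(abs(f1$time - s)))
    times <- c(times, tt)
    block <- f1$vx[, , idx, drop = FALSE]
    vx <- if (is.null(vx)) block else
      array(c(vx, block), c(ny, nx, length(times)))
  }
  velocity_field(f1$x, f1$y, times, vx, array(0, dim(vx)), f1$mask)
}

test_that("identical cycles average to a single cycle with zero SD", {
  fseq <- make_cycles(4)
  ens <- align_cycles(fseq, 1.0, 3)
  expect_lt(max(ens$sd_vx, na.rm = TRUE), 1e-4 * max(abs(ens$vx)))
  expect_equal(ens$n_cycles, 3L)
})

test_that("peak-systole alignment reduces SD under phase jitter", {
  fseq <- make_cycles(5, jitter_s = 0.06, seed = 8)
  ens <- align_cycles(fseq, 1.0, 4)
  aligned_sd <- mean(ens$sd_vx, na.rm = TRUE)
  # unaligned: average the same cycles on the absolute time grid
  nt1 <- sum(fseq$time < 1)
  stacks <- lapply(2:5, function(c)
    fseq$vx[, , ((c - 1) * nt1 + 1):(c * nt1)])
  arr <- simplify2array(stacks)
  unaligned_sd <- mean(apply(arr, 1:3, stats::sd))
  expect_lt(aligned_sd, unaligned_sd)
})

test_that("a single cycle returns itself with missing SD", {
  fseq <- make_cycles(2)
  ens <- align_cycles(fseq, 1.0, 1)
  expect_true(all(is.na(ens$sd_vx)))
  expect_equal(ens$n_cycles, 1L)
})

test_that("too few detectable cycles raises an informative error", {
  fseq <- make_cycles(2)
  expect_error(align_cycles(fseq, 1.0, 5), "span")
})

test_that("resampling onto the identical grid is the identity", {
  fseq <- make_cycles(3)
  ens <- align_cycles(fseq, 1.0, 2)
  geom <- list(x = ens$x, y = ens$y, mask = ens$mask)
  rs <- resample_to_reference(ens, geom, n_time = length(ens$tau))
  expect_equal(rs$vx, ens$vx, tolerance = 1e-9)
})

test_that("bilinear resampling reproduces affine fields exactly", {
  x <- seq(0, 10, by = 1); y <- seq(0, 6, by = 1)
  lin <- outer(y, x, function(yy, xx) 2 * xx - 3 * yy + 1)
  f <- velocity_field(x, y, c(0, 1), array(rep(lin, 2), c(7, 11, 2)),
                      array(0, c(7, 11, 2)))
  ens <- ensemble_from_field(f)
  x2 <- seq(0.25, 9.25, by = 0.75); y2 <- seq(0.5, 5.5, by = 0.75)
  geom <- list(x = x2, y = y2, mask = matrix(TRUE, length(y2), length(x2)))
  rs <- resample_to_reference(ens, geom, n_time = 2)
  truth <- outer(y2, x2, function(yy, xx) 2 * xx - 3 * yy + 1)
  expect_equal(rs$vx[, , 1], truth, tolerance = 1e-9)
})

test_that("half-overlapping grids restrict statistics to the intersection", {
  fseq <- make_cycles(3)
  ens <- align_cycles(fseq, 1.0, 2)
  x_shift <- ens$x + max(ens$x) / 2
  geom <- list(x = x_shift, y = ens$y,
               mask = matrix(TRUE, length(ens$y), length(x_shift)))
  rs <- resample_to_reference(ens, geom, n_time = length(ens$tau))
  expect_true(any(!rs$mask))
  expect_true(any(rs$mask))
  # disjoint grids error
  geom2 <- list(x = ens$x + 100, y = ens$y, mask = geom$mask)
  expect_error(resample_to_reference(ens, geom2), "overlap")
})

test_that("limits of agreement: trivial, bias-only and noise cases", {
  fseq <- make_cycles(3)
  ens <- align_cycles(fseq, 1.0, 2)
  same <- limits_of_agreement(ens, ens)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$sd_difference, 0)

  # constant bias on the speed of a strictly forward-flow ensemble
  base <- array(100, c(4, 4, 10))
  f <- velocity_field(seq(0, 3), seq(0, 3), seq(0, 1, length.out = 10),
                      base, array(0, dim(base)))
  ref <- ensemble_from_field(f)
  biased <- ref
  biased$vx <- base + 5
  b <- limits_of_agreement(biased, ref)
  expect_equal(b$mean_difference, 5, tolerance = 1e-9)
  expect_equal(b$sd_difference, 0, tolerance = 1e-9)
})

test_that("injected iid noise SD is recovered within 5% at >= 1e4 vectors", {
  set.seed(17)
  x <- seq(0, 15, by = 1); y <- seq(0, 15, by = 1)
  nt <- 50
  base <- array(100, c(16, 16, nt))
  f <- velocity_field(x, y, seq(0, 1, length.out = nt), base,
                      array(0, dim(base)))
  ref <- ensemble_from_field(f)
  test_e <- ref
  sigma <- 10
  n_vec <- prod(dim(base))
  expect_gte(n_vec, 1e4)
  test_e$vx <- base + array(stats::rnorm(n_vec, 0, sigma), dim(base))
  rep <- limits_of_agreement(test_e, ref)
  expect_lt(abs(rep$mean_difference), 0.05 * sigma)
  expect_lt(abs(rep$sd_difference - sigma) / sigma, 0.05)
  expect_equal(rep$loa_high, rep$mean_difference + 1.96 * rep$sd_difference)
  expect_equal(rep$loa_high - rep$loa_low, 2 * 1.96 * rep$sd_difference)
  # swapping test and reference negates the mean and keeps the SD
  swapped <- limits_of_agreement(ref, test_e)
  expect_equal(swapped$mean_difference, -rep$mean_difference)
  expect_equal(swapped$sd_difference, rep$sd_difference)
})

test_that("peak differences compare magnitudes only", {
  expect_equal(peak_difference(c(1, 2, 1), c(1, 2, 1)), 0)
  expect_equal(peak_difference(c(0, 110, 3), c(100, 2, 1)), 10)
  # invariant to a time shift of the peak
  a <- c(0, 0, 120, 0); b <- c(120, 0, 0, 0)
  expect_equal(peak_difference(a, b), 0)
})
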
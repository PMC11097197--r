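test_that("casorati SVD is exact and satisfies Parseval", {
  im <- tracer_sequence(seed = 2, n_frames = 10)
  dec <- casorati_svd(im)
  rec <- svd_reconstruct(dec)
  expect_lt(max(abs(rec[[4]] - im$frames[[4]])) / max(im$frames[[4]]), 1e-10)
  expect_equal(sum(dec$d^2), energy(im$frames), tolerance = 1e-9)
})

test_that("a static sequence is rank one", {
  f <- outer(1:20, 1:30) / 6
  st <- particle_images(list(f, f, f, f, f), 0.05, 1000, 16L)
  dec <- casorati_svd(st)
  expect_lt(dec$d[2] / dec$d[1], 1e-8)
})

test_that("leading components carry at least the injected clutter energy", {
  im <- tracer_sequence(seed = 2, n_frames = 16)
  for (k in c(1L, 3L)) {
    cl <- add_clutter(im, k, 16000, 0, seed = 5)
    dec <- casorati_svd(cl)
    e_lead <- sum(dec$d[seq_len(k)]^2)
    e_clutter <- energy(attr(cl, "clutter"))
    expect_gte(e_lead, e_clutter * 0.99)
  }
})

test_that("similarity thresholds find an injected static clutter block", {
  im <- tracer_sequence(seed = 7, n_frames = 24)
  lows <- vapply(c(7L, 13L, 21L, 35L), function(s) {
    cl <- add_clutter(im, 3L, 16000, 0, seed = s)
    select_rank_thresholds(casorati_svd(cl))$low
  }, integer(1))
  expect_true(all(lows >= 2L & lows <= 4L))
})

test_that("pure noise takes the warning path and returns (1, rank)", {
  set.seed(19)
  nz <- particle_images(lapply(1:12, function(i)
    matrix(pmax(stats::rnorm(32 * 32, 0, 30), 0), 32, 32)), 0.05, 1000)
  expect_warning(thr <- select_rank_thresholds(casorati_svd(nz)),
                 "no similarity block")
  expect_equal(thr$low, 1L)
  expect_equal(thr$high, 12L)
})

test_that("manual threshold overrides pass through unchanged", {
  im <- tracer_sequence(seed = 2, n_frames = 10)
  thr <- select_rank_thresholds(casorati_svd(im), low = 5L, high = 100L)
  expect_equal(thr$low, 5L)
  expect_equal(thr$high, 100L)
})

test_that("svd_filter identity and band selection", {
  im <- tracer_sequence(seed = 2, n_frames = 8)
  ident <- svd_filter(im, 0)
  expect_equal(ident$frames, im$frames, tolerance = 1e-9)
  # keeping only the weakest component
  dec <- casorati_svd(im)
  r <- length(dec$d)
  last <- svd_filter(im, r - 1L, r)
  only_last <- svd_reconstruct(dec, r)
  expect_equal(last$frames, only_last, tolerance = 1e-9)
  expect_error(svd_filter(im, 5L, 3L), "low < high")
})

test_that("filter with a shared decomposition is additive", {
  im <- tracer_sequence(seed = 2, n_frames = 8)
  cl <- add_clutter(im, 2L, 400, 0, seed = 3)
  dec <- casorati_svd(cl)
  whole <- svd_filter(cl, 2L, decomposition = dec)
  part_a <- svd_filter(im, 2L, decomposition = dec)
  clutter_only <- im
  clutter_only$frames <- attr(cl, "clutter")
  part_b <- svd_filter(clutter_only, 2L, decomposition = dec)
  together <- mapply(function(a, b) a + b, part_a$frames, part_b$frames,
                     SIMPLIFY = FALSE)
  expect_equal(whole$frames, together, tolerance = 1e-9)
})

test_that("rank-1 static clutter is removed while tracers are preserved", {
  im <- tracer_sequence(seed = 7, n_frames = 24)
  cl <- add_clutter(im, 1L, 16000, 0, seed = 9)
  dec <- casorati_svd(cl)
  u1 <- dec$u[, 1, drop = FALSE]
  proj_out <- function(X) X - u1 %*% crossprod(u1, X)
  Xc <- casorati_matrix(attr(cl, "clutter"))
  Xp <- casorati_matrix(im$frames)
  expect_lt(sum(proj_out(Xc)^2) / sum(Xc^2), 0.01)
  expect_gt(sum(proj_out(Xp)^2) / sum(Xp^2), 0.9)
})

test_that("clutter filtering improves PIV accuracy on cluttered sequences", {
  im <- tracer_sequence(seed = 7, n_frames = 24)
  cl <- add_clutter(im, 3L, 16000, 0, seed = 9)
  sch <- piv_schedule(c(32L, 16L), 0.5)
  thr <- select_rank_thresholds(casorati_svd(cl))
  filt <- svd_filter(cl, thr$low)
  to_px <- im$pixel_size * im$frame_rate / 10
  rms <- function(pf) sqrt(mean((pf$vx / to_px - 3)^2))
  expect_lt(rms(multipass_piv(filt, sch)), rms(multipass_piv(cl, sch)))
})
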
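# separable Gaussian blur (reflected edges), sigma in px
.gauss_blur <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(v) c(rev(v[seq_len(r)]), v, rev(v[length(v) - seq_len(r) + 1]))
  along <- function(mm) apply(mm, 2, function(col)
    stats::convolve(pad(col), rev(k), type = "filter"))
  t(along(t(along(m))))
}

#' Tracer-particle image sequence
#'
#' Multi-frame grayscale image stack with acquisition metadata. Frames are
#' numeric matrices in the physical row convention (row 1 = lowest y); the
#' TIFF writer flips rows so that files follow the usual image convention.
#'
#' @param frames List of numeric matrices (equal dimensions), intensities in
#'   `[0, 2^bit_depth - 1]`.
#' @param pixel_size Pixel size in mm.
#' @param frame_rate Acquisition frame rate in frames/s.
#' @param bit_depth Intensity bit depth (8 or 16).
#' @param ground_truth Optional [velocity_field] the frames were rendered
#'   from.
#' @return An object of class `particle_images`.
#' @export
particle_images <- function(frames, pixel_size, frame_rate, bit_depth = 8L,
                            ground_truth = NULL) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("`frames` must be a list of at least 2 matrices")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames must share the same dimensions")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be positive (mm)")
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("`frame_rate` must be positive (fps)")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < -1e-9 || rng[2] > 2^bit_depth - 1 + 1e-9)
    stop("intensities must lie within the bit-depth range")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_rate = frame_rate, bit_depth = as.integer(bit_depth),
                 ground_truth = ground_truth),
            class = "particle_images")
}

#' @export
print.particle_images <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Particle image sequence: %d frames of %d x %d px\n",
              length(x$frames), d[1], d[2]))
  cat(sprintf("  pixel size %.4g mm, %.5g fps, %d-bit\n",
              x$pixel_size, x$frame_rate, x$bit_depth))
  invisible(x)
}

#' Render a tracer-particle image sequence from a velocity field
#'
#' Seeds Gaussian-blob tracer particles uniformly over the lumen and advects
#' them between frames by a second-order Runge-Kutta (midpoint) integration
#' of the local velocity over `1/frame_rate`. Particles leaving the domain or
#' the lumen are replaced at the upstream (low-x) boundary so the seeding
#' density stays stationary. Output is reproducible for a fixed `seed`.
#'
#' @param field A [velocity_field] (cm/s) covering the image domain.
#' @param seeding_density Particles per pixel^2 (default 0.05, the synthetic
#'   PIV convention).
#' @param particle_diameter Apparent particle diameter in px; blobs are
#'   Gaussian with `sigma = diameter / 2.355`.
#' @param pixel_size Pixel size in mm.
#' @param frame_rate Frame rate in fps.
#' @param n_frames Number of frames to render.
#' @param noise_sd Additive Gaussian intensity noise SD (intensity units).
#' @param seed Integer seed for all randomness in this call.
#' @param t0 Field time at the first frame, s.
#' @param bit_depth Intensity bit depth.
#' @return A [particle_images] with `ground_truth` set to `field`.
#' @export
render_particle_images <- function(field, seeding_density = 0.05,
                                   particle_diameter = 3, pixel_size = 0.05,
                                   frame_rate = 1000, n_frames = 10L,
                                   noise_sd = 0, seed = 1L, t0 = field$time[1],
                                   bit_depth = 8L) {
  stopifnot(inherits(field, "velocity_field"))
  if (frame_rate <= 0) stop("`frame_rate` must be positive")
  if (n_frames < 2L) stop("need at least 2 frames")
  set.seed(seed)

  x0 <- min(field$x); x1 <- max(field$x)
  y0 <- min(field$y); y1 <- max(field$y)
  npx <- max(2L, floor((x1 - x0) / pixel_size))
  npy <- max(2L, floor((y1 - y0) / pixel_size))
  n_part <- max(1L, round(seeding_density * npx * npy))
  if (seeding_density * 16^2 < 3)
    warning("seeding density averages fewer than 3 particles per 16 px window")

  inside_lumen <- function(px, py) {
    m <- .interp_bilinear(field$x, field$y, field$mask * 1, px, py)
    m > 0.5
  }
  draw <- function(n) {
    cbind(stats::runif(n, x0, x1), stats::runif(n, y0, y1))
  }
  # rejection-seed inside the lumen
  pos <- matrix(NA_real_, 0, 2)
  while (nrow(pos) < n_part) {
    cand <- draw(2L * n_part)
    ok <- inside_lumen(cand[, 1], cand[, 2])
    pos <- rbind(pos, cand[ok, , drop = FALSE])
  }
  pos <- pos[seq_len(n_part), , drop = FALSE]
  amp <- stats::runif(n_part, 0.6, 1.0) * (2^bit_depth - 1) * 0.8

  sigma_px <- particle_diameter / 2.355
  half <- ceiling(3 * sigma_px)
  dt <- 1 / frame_rate
  frames <- vector("list", n_frames)
  maxI <- 2^bit_depth - 1

  stamp <- function(img, px_pos, amps) {
    # particle centers in pixel units (pixel i center at (i - 0.5) * size)
    cx <- (px_pos[, 1] - x0) / pixel_size + 0.5
    cy <- (px_pos[, 2] - y0) / pixel_size + 0.5
    for (p in seq_along(amps)) {
      j <- round(cx[p]); i <- round(cy[p])
      jr <- max(1, j - half):min(npx, j + half)
      ir <- max(1, i - half):min(npy, i + half)
      if (!length(jr) || !length(ir)) next
      gx <- exp(-((jr - cx[p])^2) / (2 * sigma_px^2))
      gy <- exp(-((ir - cy[p])^2) / (2 * sigma_px^2))
      img[ir, jr] <- img[ir, jr] + amps[p] * outer(gy, gx)
    }
    img
  }

  for (f in seq_len(n_frames)) {
    t <- t0 + (f - 1) * dt
    img <- stamp(matrix(0, npy, npx), pos, amp)
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(npy * npx, 0, noise_sd), npy, npx)
    frames[[f]] <- pmin(pmax(img, 0), maxI)
    if (f < n_frames) {
      # midpoint rule; velocities cm/s -> mm/s
      v1 <- .field_velocity_at(field, pos[, 1], pos[, 2], t)
      pm <- pos + 10 * dt / 2 * cbind(v1$vx, v1$vy)
      v2 <- .field_velocity_at(field, pm[, 1], pm[, 2], t + dt / 2)
      pos <- pos + 10 * dt * cbind(v2$vx, v2$vy)
      # re-seed leavers at the inflow edge to keep density stationary
      out <- pos[, 1] < x0 | pos[, 1] > x1 | pos[, 2] < y0 | pos[, 2] > y1 |
        !inside_lumen(pmin(pmax(pos[, 1], x0), x1),
                      pmin(pmax(pos[, 2], y0), y1))
      n_out <- sum(out)
      if (n_out > 0) {
        ylum <- field$y[rowSums(field$mask) > 0]
        pos[out, 1] <- x0 + stats::runif(n_out, 0, 2 * pixel_size)
        pos[out, 2] <- stats::runif(n_out, min(ylum), max(ylum))
        amp[out] <- stats::runif(n_out, 0.6, 1.0) * maxI * 0.8
      }
    }
  }
  particle_images(frames, pixel_size, frame_rate, bit_depth,
                  ground_truth = field)
}

#' Add a low-rank, slowly moving clutter component to an image sequence
#'
#' Superimposes a spatially smooth tissue-like signal whose Casorati matrix
#' (pixels x frames) has numerical rank at most `clutter_rank`. Apparent
#' motion up to `clutter_velocity` is emulated through a first-order Taylor
#' pair (pattern plus its spatial gradient with a linearly growing
#' coefficient), which preserves the rank bound. The tracer signal is kept
#' additively: the injected component is returned in attribute `"clutter"`.
#'
#' @param images A [particle_images].
#' @param clutter_rank Maximum rank of the injected component (>= 1).
#' @param clutter_amplitude Peak intensity of the clutter (intensity units).
#'   0 returns the input unchanged.
#' @param clutter_velocity Apparent clutter velocity in mm/s (0 = static).
#' @param seed Integer seed.
#' @return A [particle_images] with the clutter added (intensities clipped to
#'   the bit-depth range only if requested via `clip`).
#' @param clip Clip the output to the bit-depth range (default `FALSE` so the
#'   addition stays exactly invertible).
#' @export
add_clutter <- function(images, clutter_rank = 1L, clutter_amplitude = 50,
                        clutter_velocity = 0, seed = 1L, clip = FALSE) {
  stopifnot(inherits(images, "particle_images"))
  if (clutter_rank < 1L) stop("`clutter_rank` must be >= 1")
  if (clutter_amplitude < 0) stop("`clutter_amplitude` must be >= 0")
  if (clutter_amplitude == 0) return(images)
  set.seed(seed)
  d <- dim(images$frames[[1]]); ny <- d[1]; nx <- d[2]
  n_frames <- length(images$frames)
  t_frame <- (seq_len(n_frames) - 1) / images$frame_rate

  # tissue-like base pattern: band-limited speckle modulated by a common
  # echogenicity envelope; all clutter components inherit the envelope,
  # which is what makes their singular-vector magnitudes mutually similar
  yy <- seq(-1, 1, length.out = ny); xx <- seq(-1, 1, length.out = nx)
  envelope <- outer(exp(-(yy / 0.45)^2), exp(-(xx / 0.45)^2))
  envelope <- 0.05 + 0.95 * envelope / max(envelope)
  speckle <- function() {
    p <- .gauss_blur(matrix(stats::rnorm(ny * nx), ny, nx), 2)
    p <- p * envelope
    p / max(abs(p))
  }
  ddx <- function(p) {
    cbind(p[, 2] - p[, 1],
          (p[, 3:nx, drop = FALSE] - p[, 1:(nx - 2), drop = FALSE]) / 2,
          p[, nx] - p[, nx - 1])
  }

  # per-frame lateral shift of the tissue, px: either the requested drift or
  # a sub-pixel micro-oscillation over the acquisition block
  s_norm <- (seq_len(n_frames) - 1) / n_frames
  shift_px <- if (clutter_velocity > 0)
    clutter_velocity / images$pixel_size * t_frame
  else 0.5 * sin(2 * pi * s_norm)

  # translation emulated by its Taylor expansion: pattern, d/dx, d2/dx2 ...
  # with coefficients (-shift)^m / m!; rank bound holds by construction
  base <- speckle()
  modes <- list(base); coefs <- list(rep(1, n_frames))
  k <- 1L
  deriv <- base
  while (k < min(clutter_rank, 3L)) {
    k <- k + 1L
    deriv <- ddx(deriv)
    modes[[k]] <- deriv
    coefs[[k]] <- (-shift_px)^(k - 1) / factorial(k - 1)
  }
  # further components: independent speckle with slow modulation
  while (k < clutter_rank) {
    k <- k + 1L
    modes[[k]] <- speckle() * 0.5
    coefs[[k]] <- sin(pi * (k - 2) * s_norm + stats::runif(1, 0, 2 * pi))
  }

  clutter <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    c_f <- matrix(0, ny, nx)
    for (m in seq_len(k)) c_f <- c_f + coefs[[m]][f] * modes[[m]]
    clutter[[f]] <- clutter_amplitude * c_f
  }
  maxI <- 2^images$bit_depth - 1
  frames <- mapply(function(fr, cl) {
    out <- fr + cl
    if (clip) out <- pmin(pmax(out, 0), maxI)
    out
  }, images$frames, clutter, SIMPLIFY = FALSE)
  out <- images
  out$frames <- frames
  attr(out, "clutter") <- clutter
  out
}
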
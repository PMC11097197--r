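# shared fixture builders (all programmatic, seeded per use)

# constant-velocity field producing `disp_px` pixels of displacement per
# frame at the given pixel size and frame rate
uniform_field <- function(disp_px, pixel_size = 0.05, frame_rate = 1000,
                          extent = 6.4, spacing = 0.2) {
  v_cms <- disp_px * pixel_size * frame_rate / 10
  x <- seq(0, extent, by = spacing)
  y <- seq(0, extent, by = spacing)
  d3 <- c(length(y), length(x), 2)
  velocity_field(x, y, c(0, 2 / frame_rate),
                 array(v_cms, d3), array(0, d3))
}

render_uniform <- function(disp_px, seed, n_frames = 4, pixel_size = 0.05,
                           frame_rate = 1000, noise_sd = 0) {
  render_particle_images(uniform_field(disp_px, pixel_size, frame_rate),
                         pixel_size = pixel_size, frame_rate = frame_rate,
                         n_frames = n_frames, noise_sd = noise_sd,
                         seed = seed)
}

# steady parabolic profile as a flow_profile, u_max in cm/s
parabolic_profile <- function(u_max, radius, n_r = 201) {
  r <- seq(-radius, radius, length.out = n_r)
  flow_profile(r, 0, matrix(u_max * (1 - (r / radius)^2), n_r, 1), radius)
}

# small particle sequence of pure moving tracers for clutter benchmarks
tracer_sequence <- function(seed = 7, n_frames = 24, disp_px = 3) {
  render_uniform(disp_px, seed = seed, n_frames = n_frames)
}

energy <- function(frames) sum(vapply(frames, function(f) sum(f^2), 0))

casorati_matrix <- function(frames)
  vapply(frames, as.vector, numeric(length(frames[[1]])))
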
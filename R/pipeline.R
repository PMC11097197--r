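#' Wrap a single velocity-field sequence as a degenerate cardiac ensemble
#'
#' Treats the field's time samples as one already-averaged cycle so that
#' [resample_to_reference()] and [limits_of_agreement()] can compare a field
#' against a reference without cycle averaging (SD over cycles is `NA`).
#'
#' @param field A [velocity_field].
#' @return A `cardiac_ensemble` with `n_cycles = 1`.
#' @export
ensemble_from_field <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  nt <- length(field$time)
  speed_mean <- vapply(seq_len(nt), function(k)
    mean(sqrt(field$vx[, , k]^2 + field$vy[, , k]^2)[field$mask]),
    numeric(1))
  structure(list(x = field$x, y = field$y, tau = field$time,
                 vx = field$vx, vy = field$vy,
                 sd_vx = array(NA_real_, dim(field$vx)),
                 sd_vy = array(NA_real_, dim(field$vy)),
                 mask = field$mask, n_cycles = 1L,
                 period = diff(range(field$time)),
                 peak_times = field$time[which.max(speed_mean)],
                 peak_index = which.max(speed_mean)),
            class = "cardiac_ensemble")
}

.pipeline_schema <- list(
  seed = NULL,
  synth = list(waveform = c("period", "forward_volume", "backflow_volume",
                            "systolic_fraction", "backflow_fraction",
                            "diastolic_share", "n_samples"),
               vessel = c("cfa_diameter", "sfa_diameter", "dfa_diameter",
                          "bifurcation_angle", "stenosis_area_reduction"),
               field = c("grid_spacing", "vessel_length", "jet_length",
                         "stenosis_center", "n_times"),
               render = c("pixel_size", "frame_rate", "n_frames",
                          "seeding_density", "particle_diameter", "noise_sd")),
  clutter = list(add = c("rank", "amplitude", "velocity"),
                 filter = c("mode", "low", "high")),
  piv = list(schedule = c("preset", "window_sizes", "overlap",
                          "correlation_averaging_n", "pairing"),
             postprocess = c("spatial_gaussian", "temporal_window",
                             "temporal_mode")),
  analyze = c("vc"),
  compare = c("against_truth", "scope")
)

.check_keys <- function(cfg, schema, path = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop(sprintf("unknown config key%s at '%s': %s",
                 if (length(unknown) > 1) "s" else "", path,
                 paste(unknown, collapse = ", ")))
  for (k in names(cfg)) {
    sch <- schema[[k]]
    if (is.list(sch)) {
      .check_keys(cfg[[k]], sch, paste0(path, k, "/"))
    } else if (is.character(sch)) {
      bad <- setdiff(names(cfg[[k]]), sch)
      if (length(bad))
        stop(sprintf("unknown config key(s) at '%s%s': %s", path, k,
                     paste(bad, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

.cfg_get <- function(x, key, default) {
  if (is.null(x[[key]])) default else x[[key]]
}

#' Run the full synthetic phantom / PIV / hemodynamics pipeline
#'
#' Executes the configured stages in order: synthetic phantom generation
#' (waveform, analytic velocity field, tracer-image rendering), optional
#' clutter injection and SVD filtering, multi-pass PIV, vector-complexity
#' analysis, and agreement statistics against the known ground truth. Every
#' threshold actually used (PIV schedule, SVD ranks) is recorded in the run
#' manifest, and the whole run is deterministic for a fixed seed.
#'
#' @param config Configuration as a nested list or a path to a YAML file.
#'   Unknown keys are rejected before any computation.
#' @return A list with elements `manifest` (class `run_manifest`), plus the
#'   stage outputs `waveform`, `split`, `truth_field`, `images`, `piv_field`,
#'   `vc` and `agreement` as configured.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .check_keys(config, .pipeline_schema)
  seed <- .cfg_get(config, "seed", 1L)
  started <- Sys.time()
  thresholds <- list()
  out <- list()

  ## synth
  syn <- .cfg_get(config, "synth", list())
  wf_cfg <- .cfg_get(syn, "waveform", list())
  waveform <- do.call(make_triphasic_waveform, wf_cfg)
  out$waveform <- waveform
  out$split <- split_waveform(waveform)
  vessel <- do.call(vessel_spec, .cfg_get(syn, "vessel", list()))
  f_cfg <- .cfg_get(syn, "field", list())
  n_times <- .cfg_get(f_cfg, "n_times", 8L)
  idx <- unique(round(seq(1, length(waveform$time), length.out = n_times)))
  truth <- stenotic_field(
    vessel, waveform,
    jet_length = .cfg_get(f_cfg, "jet_length", 15),
    grid_spacing = .cfg_get(f_cfg, "grid_spacing", 0.25),
    vessel_length = .cfg_get(f_cfg, "vessel_length", 40),
    stenosis_center = .cfg_get(f_cfg, "stenosis_center", 10),
    time_indices = idx)
  out$truth_field <- truth

  r_cfg <- .cfg_get(syn, "render", list())
  t0 <- truth$time[which.max(abs(waveform$flow_rate[idx]))]
  images <- render_particle_images(
    truth,
    seeding_density = .cfg_get(r_cfg, "seeding_density", 0.05),
    particle_diameter = .cfg_get(r_cfg, "particle_diameter", 3),
    pixel_size = .cfg_get(r_cfg, "pixel_size", 0.15),
    frame_rate = .cfg_get(r_cfg, "frame_rate", 6000),
    n_frames = .cfg_get(r_cfg, "n_frames", 12L),
    noise_sd = .cfg_get(r_cfg, "noise_sd", 2),
    seed = seed, t0 = t0)

  ## clutter
  cl <- .cfg_get(config, "clutter", NULL)
  if (!is.null(cl)) {
    add <- .cfg_get(cl, "add", NULL)
    if (!is.null(add))
      images <- add_clutter(images,
                            clutter_rank = .cfg_get(add, "rank", 1L),
                            clutter_amplitude = .cfg_get(add, "amplitude", 40),
                            clutter_velocity = .cfg_get(add, "velocity", 0),
                            seed = seed + 1L)
    flt <- .cfg_get(cl, "filter", NULL)
    if (!is.null(flt) && !identical(.cfg_get(flt, "mode", "auto"), "none")) {
      if (identical(.cfg_get(flt, "mode", "auto"), "auto")) {
        thr <- select_rank_thresholds(casorati_svd(images))
      } else {
        thr <- list(low = flt$low, high = flt$high)
      }
      thresholds$svd_low <- thr$low
      thresholds$svd_high <- thr$high
      images <- svd_filter(images, thr$low, thr$high)
      maxI <- 2^images$bit_depth - 1
      images$frames <- lapply(images$frames, function(f)
        pmin(pmax(f, 0), maxI))
    }
  }
  out$images <- images

  ## piv
  p_cfg <- .cfg_get(config, "piv", list())
  s_cfg <- .cfg_get(p_cfg, "schedule",
                    list(window_sizes = c(32L, 16L)))
  if (is.character(s_cfg)) s_cfg <- list(preset = s_cfg)
  schedule <- if (!is.null(s_cfg$preset)) piv_preset(s_cfg$preset) else
    piv_schedule(unlist(s_cfg$window_sizes),
                 overlap = .cfg_get(s_cfg, "overlap", 0.5),
                 correlation_averaging_n =
                   .cfg_get(s_cfg, "correlation_averaging_n", 1L),
                 pairing = .cfg_get(s_cfg, "pairing", "non_overlapping"))
  thresholds$schedule <- schedule
  piv_field <- multipass_piv(images, schedule,
                             origin = c(min(truth$x), min(truth$y)))
  pp <- .cfg_get(p_cfg, "postprocess", NULL)
  if (!is.null(pp))
    piv_field <- postprocess_fields(
      piv_field,
      spatial_gaussian = .cfg_get(pp, "spatial_gaussian", TRUE),
      temporal_window = .cfg_get(pp, "temporal_window", 1L),
      temporal_mode = .cfg_get(pp, "temporal_mode", "moving_average"))
  out$piv_field <- piv_field

  ## analyze
  an <- .cfg_get(config, "analyze", list())
  if (isTRUE(.cfg_get(an, "vc", TRUE)))
    out$vc <- vector_complexity(piv_field)

  ## compare against ground truth
  cp <- .cfg_get(config, "compare", list())
  if (isTRUE(.cfg_get(cp, "against_truth", TRUE))) {
    # evaluate the ground truth at the PIV output times before the spatial
    # resampling so both ensembles share one time base
    truth_at_piv <- .field_time_slices(truth, t0 + piv_field$time)
    truth_ens <- ensemble_from_field(truth_at_piv)
    piv_ens <- ensemble_from_field(piv_field)
    n_t <- length(piv_field$time)
    truth_rs <- resample_to_reference(truth_ens, piv_field, n_time = n_t)
    out$agreement <- limits_of_agreement(
      piv_ens, truth_rs, scope = .cfg_get(cp, "scope", "all_timepoints"))
  }

  manifest <- structure(
    list(config = config, seed = seed, thresholds = thresholds,
         package_version = as.character(utils::packageVersion("hemoveloc")),
         started = started, finished = Sys.time()),
    class = "run_manifest")
  c(list(manifest = manifest), out)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat(sprintf("  seed: %d, package %s\n", x$seed, x$package_version))
  if (!is.null(x$thresholds$svd_low))
    cat(sprintf("  SVD thresholds: low %d, high %d\n",
                x$thresholds$svd_low, x$thresholds$svd_high))
  if (!is.null(x$thresholds$schedule))
    cat(sprintf("  PIV windows: %s px\n",
                paste(x$thresholds$schedule$window_sizes, collapse = "/")))
  invisible(x)
}
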
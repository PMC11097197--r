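#' Align cardiac cycles at peak systole and ensemble-average
#'
#' Peak systole of each cycle is located as a local maximum of the
#' spatial-mean velocity magnitude (minimum separation 0.6 periods, ties
#' broken by the earliest sample). Each cycle is cropped to one period
#' around its peak (`[-period/4, +3 period/4)`), resampled by linear
#' interpolation to 100 normalized time points, and averaged per node;
#' the per-node, per-time standard deviation over cycles is stored.
#'
#' @param fields A [velocity_field] sequence spanning at least `n_cycles`
#'   periods.
#' @param period Cardiac period in s.
#' @param n_cycles Number of cycles to average.
#' @param n_time Number of normalized cycle time samples (default 100).
#' @return An object of class `cardiac_ensemble` with per-node mean and SD
#'   components on a normalized cycle time axis, plus the alignment offsets.
#' @export
align_cycles <- function(fields, period, n_cycles, n_time = 100L) {
  stopifnot(inherits(fields, "velocity_field"))
  t <- fields$time
  if (diff(range(t)) < (n_cycles - 1) * period * 0.99)
    stop("sequence does not span the requested number of cycles")
  nt <- length(t)
  msk <- fields$mask
  speed_mean <- vapply(seq_len(nt), function(k) {
    sp <- sqrt(fields$vx[, , k]^2 + fields$vy[, , k]^2)
    mean(sp[msk])
  }, numeric(1))

  # local maxima with minimum separation of 0.6 periods
  peaks <- integer(0)
  ord <- order(-speed_mean, t)
  for (k in ord) {
    if (!length(peaks) || all(abs(t[k] - t[peaks]) >= 0.6 * period))
      peaks <- c(peaks, k)
  }
  peaks <- sort(peaks)
  if (length(peaks) < n_cycles)
    stop(sprintf("found only %d peak(s); %d cycles requested",
                 length(peaks), n_cycles))
  # keep the n_cycles peaks whose full window lies inside the record
  ok <- t[peaks] - period / 4 >= t[1] - 1e-9 &
    t[peaks] + 3 * period / 4 <= t[nt] + 1e-9
  peaks <- peaks[ok]
  if (length(peaks) < n_cycles)
    stop(sprintf("found only %d complete cycle(s); %d requested",
                 length(peaks), n_cycles))
  peaks <- peaks[seq_len(n_cycles)]

  tau <- seq(-period / 4, 3 * period / 4, length.out = n_time + 1L)[-(n_time + 1L)]
  ny <- length(fields$y); nx <- length(fields$x)
  acc_x <- array(0, c(ny, nx, n_time)); acc_y <- acc_x
  acc_x2 <- acc_x; acc_y2 <- acc_x
  for (p in peaks) {
    tq <- t[p] + tau
    for (j in seq_len(n_time)) {
      k0 <- findInterval(tq[j], t, rightmost.closed = TRUE)
      k0 <- min(max(k0, 1L), nt - 1L)
      wgt <- (tq[j] - t[k0]) / (t[k0 + 1L] - t[k0])
      wgt <- min(max(wgt, 0), 1)
      fx <- (1 - wgt) * fields$vx[, , k0] + wgt * fields$vx[, , k0 + 1L]
      fy <- (1 - wgt) * fields$vy[, , k0] + wgt * fields$vy[, , k0 + 1L]
      acc_x[, , j] <- acc_x[, , j] + fx
      acc_y[, , j] <- acc_y[, , j] + fy
      acc_x2[, , j] <- acc_x2[, , j] + fx^2
      acc_y2[, , j] <- acc_y2[, , j] + fy^2
    }
  }
  nC <- n_cycles
  mean_x <- acc_x / nC; mean_y <- acc_y / nC
  if (nC >= 2L) {
    sd_x <- sqrt(pmax(acc_x2 / nC - mean_x^2, 0) * nC / (nC - 1))
    sd_y <- sqrt(pmax(acc_y2 / nC - mean_y^2, 0) * nC / (nC - 1))
  } else {
    sd_x <- array(NA_real_, dim(mean_x)); sd_y <- sd_x
  }
  structure(list(x = fields$x, y = fields$y, tau = tau + period / 4,
                 vx = mean_x, vy = mean_y, sd_vx = sd_x, sd_vy = sd_y,
                 mask = msk, n_cycles = nC, period = period,
                 peak_times = t[peaks],
                 peak_index = which.min(abs(tau))),
            class = "cardiac_ensemble")
}

#' @export
print.cardiac_ensemble <- function(x, ...) {
  cat(sprintf("Cardiac ensemble: %d cycles, %d x %d nodes, %d cycle samples\n",
              x$n_cycles, length(x$x), length(x$y), length(x$tau)))
  invisible(x)
}

#' Resample a cardiac ensemble onto a reference grid and time base
#'
#' Bilinear spatial interpolation at the reference node locations and linear
#' temporal interpolation to `n_time` cycle samples. Reference nodes outside
#' the test ensemble's lumen mask (or outside its spatial extent) are flagged
#' missing and excluded from downstream statistics.
#'
#' @param test A [cardiac_ensemble].
#' @param reference_grid A [velocity_field] or [cardiac_ensemble] supplying
#'   the target `x`, `y` and `mask`.
#' @param n_time Number of target cycle samples.
#' @return A [cardiac_ensemble] on the reference geometry; missing nodes are
#'   `NA` in the components and `FALSE` in the mask.
#' @export
resample_to_reference <- function(test, reference_grid, n_time = 100L) {
  stopifnot(inherits(test, "cardiac_ensemble"))
  rx <- reference_grid$x; ry <- reference_grid$y
  rmask <- reference_grid$mask
  if (max(rx) < min(test$x) || min(rx) > max(test$x) ||
      max(ry) < min(test$y) || min(ry) > max(test$y))
    stop("no spatial overlap between the grids")
  ny <- length(ry); nx <- length(rx)
  xq <- rep(rx, each = ny); yq <- rep(ry, nx)
  inside <- xq >= min(test$x) & xq <= max(test$x) &
    yq >= min(test$y) & yq <= max(test$y)
  in_mask <- inside
  in_mask[inside] <- .interp_bilinear(test$x, test$y, test$mask * 1,
                                      xq[inside], yq[inside]) > 0.5
  if (!any(in_mask)) stop("no spatial overlap between the grids")

  tau_new <- seq(min(test$tau), max(test$tau), length.out = n_time)
  interp_t <- function(arr) {
    nt_old <- dim(arr)[3]
    out <- array(NA_real_, c(ny, nx, n_time))
    for (j in seq_len(n_time)) {
      k0 <- findInterval(tau_new[j], test$tau, rightmost.closed = TRUE)
      k0 <- min(max(k0, 1L), nt_old - 1L)
      wgt <- (tau_new[j] - test$tau[k0]) / (test$tau[k0 + 1L] - test$tau[k0])
      wgt <- min(max(wgt, 0), 1)
      sl <- (1 - wgt) * arr[, , k0] + wgt * arr[, , k0 + 1L]
      v <- rep(NA_real_, ny * nx)
      v[in_mask] <- .interp_bilinear(test$x, test$y, sl,
                                     xq[in_mask], yq[in_mask])
      out[, , j] <- matrix(v, ny, nx)
    }
    out
  }
  structure(list(x = rx, y = ry, tau = tau_new,
                 vx = interp_t(test$vx), vy = interp_t(test$vy),
                 sd_vx = if (all(is.na(test$sd_vx))) test$sd_vx else
                   interp_t(test$sd_vx),
                 sd_vy = if (all(is.na(test$sd_vy))) test$sd_vy else
                   interp_t(test$sd_vy),
                 mask = matrix(in_mask, ny, nx) & rmask,
                 n_cycles = test$n_cycles, period = test$period,
                 peak_times = test$peak_times,
                 peak_index = which.min(abs(tau_new - test$tau[test$peak_index]))),
            class = "cardiac_ensemble")
}

#' Bland-Altman limits of agreement between two ensembles
#'
#' Differences of velocity magnitudes (`test` speed minus `reference` speed)
#' are pooled over all common valid nodes, and over all cycle time samples
#' when `scope = "all_timepoints"` or at the reference's peak-systole sample
#' when `scope = "peak_systole"`. Reported are the mean difference, its SD,
#' the limits of agreement `mean +/- 1.96 SD`, per-node maps of the mean and
#' SD of the difference over the cycle, and the number of vector comparisons.
#'
#' @param test,reference [cardiac_ensemble]s on the same grid and time base
#'   (resample first with [resample_to_reference()]).
#' @param scope Pooling scope.
#' @return An object of class `agreement_report`.
#' @export
limits_of_agreement <- function(test, reference,
                                scope = c("all_timepoints", "peak_systole")) {
  scope <- match.arg(scope)
  stopifnot(inherits(test, "cardiac_ensemble"),
            inherits(reference, "cardiac_ensemble"))
  if (length(test$x) != length(reference$x) ||
      length(test$tau) != length(reference$tau))
    stop("ensembles must share grid and time base; resample first")
  common <- test$mask & reference$mask
  if (!any(common)) stop("no common valid nodes")
  nt <- length(test$tau)
  sp_t <- sqrt(test$vx^2 + test$vy^2)
  sp_r <- sqrt(reference$vx^2 + reference$vy^2)
  diff3 <- sp_t - sp_r
  k_set <- if (scope == "peak_systole") reference$peak_index else seq_len(nt)

  vals <- numeric(0)
  for (k in k_set) {
    d <- diff3[, , k][common]
    vals <- c(vals, d[is.finite(d)])
  }
  n <- length(vals)
  if (n == 0L) stop("no common valid nodes")
  m <- mean(vals); s <- stats::sd(vals)

  mean_map <- apply(diff3[, , k_set, drop = FALSE], c(1, 2), mean)
  sd_map <- apply(diff3[, , k_set, drop = FALSE], c(1, 2), stats::sd)
  mean_map[!common] <- NA_real_; sd_map[!common] <- NA_real_

  structure(list(mean_difference = m, sd_difference = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 mean_map = mean_map, sd_map = sd_map,
                 n = n, scope = scope),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (%s): n = %d vector comparisons\n",
              x$scope, x$n))
  cat(sprintf("  mean difference %.3g cm/s, SD %.3g cm/s\n",
              x$mean_difference, x$sd_difference))
  cat(sprintf("  limits of agreement [%.3g, %.3g] cm/s (mean +/- 1.96 SD)\n",
              x$loa_low, x$loa_high))
  invisible(x)
}

#' Absolute peak difference between two temporal velocity profiles
#'
#' `|max(test) - max(reference)|` of the cycle-averaged temporal profiles;
#' only the magnitudes of the peaks are compared, so the result is invariant
#' to a time shift of the peak.
#'
#' @param test_profile,reference_profile Velocity time series in cm/s on the
#'   same time base.
#' @return Absolute peak difference in cm/s.
#' @export
peak_difference <- function(test_profile, reference_profile) {
  abs(max(test_profile) - max(reference_profile))
}
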
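#' Write / read a flow waveform as CSV
#'
#' Two-column CSV with mandatory header `time_s, flow_mL_per_s`; extra
#' columns are ignored with a warning, non-monotone time is rejected with
#' the offending line number.
#'
#' @param waveform A [flow_waveform].
#' @param path File path.
#' @return `write_waveform_csv` returns `path` invisibly;
#'   `read_waveform_csv` returns a [flow_waveform].
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "flow_waveform"))
  df <- data.frame(time_s = waveform$time,
                   flow_mL_per_s = waveform$flow_rate)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "flow_mL_per_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (length(setdiff(names(df), need)))
    warning("ignoring extra column(s): ",
            paste(setdiff(names(df), need), collapse = ", "))
  t <- as.numeric(df$time_s)
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop(sprintf("time not strictly increasing at line %d", bad[1] + 2L))
  flow_waveform(t, as.numeric(df$flow_mL_per_s))
}

#' Write / read a velocity-field sequence as a plain-text container
#'
#' Single-file text container (`.hvf`): a key-value header (lines starting
#' with `#`) carrying the mandatory `units` attribute, the grid spacing and
#' the axis vectors, followed by a CSV body with one row per
#' (time, y, x) node holding `vx`, `vy`. Values are written with 17
#' significant digits so the round trip is bit-exact. A file without a
#' `units` key is rejected (guards against cm/s vs mm/s mix-ups); a file
#' without a `mask` key defaults to an all-true lumen with a warning.
#'
#' @param field A [velocity_field].
#' @param path File path.
#' @return `write_field_txt` returns `path` invisibly; `read_field_txt`
#'   returns a [velocity_field].
#' @export
write_field_txt <- function(field, path) {
  stopifnot(inherits(field, "velocity_field"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#hemoveloc-field 1",
               "#units cm/s",
               sprintf("#spacing_mm %.17g", field$spacing),
               sprintf("#x %s", num(field$x)),
               sprintf("#y %s", num(field$y)),
               sprintf("#t %s", num(field$time)),
               sprintf("#mask %s", paste(as.integer(field$mask),
                                         collapse = " ")),
               "t_index,row,col,vx,vy"), con)
  nt <- length(field$time); ny <- length(field$y); nx <- length(field$x)
  for (k in seq_len(nt)) {
    rows <- rep(seq_len(ny), nx); cols <- rep(seq_len(nx), each = ny)
    writeLines(sprintf("%d,%d,%d,%.17g,%.17g", k, rows, cols,
                       as.vector(field$vx[, , k]),
                       as.vector(field$vy[, , k])), con)
  }
  invisible(path)
}

#' @rdname write_field_txt
#' @export
read_field_txt <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^#", "", h), " ")[[1]]
    kv[[parts[1]]] <- parts[-1]
  }
  if (is.null(kv$units))
    stop("missing mandatory `units` attribute in field file")
  x <- as.numeric(kv$x); y <- as.numeric(kv$y); t <- as.numeric(kv$t)
  ny <- length(y); nx <- length(x); nt <- length(t)
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (nrow(body) != ny * nx * nt)
    stop(sprintf("structural error: %d body rows, expected %d",
                 nrow(body), ny * nx * nt))
  if (max(body$row) != ny || max(body$col) != nx)
    stop("structural error: body indices do not match axis lengths")
  dim3 <- c(ny, nx, nt)
  vx <- array(NA_real_, dim3); vy <- array(NA_real_, dim3)
  idx <- cbind(body$row, body$col, body$t_index)
  vx[idx] <- body$vx; vy[idx] <- body$vy
  if (is.null(kv$mask)) {
    warning("no `mask` in field file; defaulting to all-true lumen")
    mask <- matrix(TRUE, ny, nx)
  } else {
    mask <- matrix(as.integer(kv$mask) > 0, ny, nx)
  }
  velocity_field(x, y, t, vx, vy, mask)
}

#' Write / read a particle image sequence as multi-page TIFF with sidecar
#'
#' Frames are written as a multi-page grayscale TIFF (8- or 16-bit) in the
#' usual image convention (row 1 = top); the physical row flip is performed
#' here so in-memory frames keep row 1 = lowest y. Pixel size, frame rate
#' and bit depth are stored in a plain-text `key=value` sidecar next to the
#' TIFF (`<path>.meta`).
#'
#' @param images A [particle_images].
#' @param path TIFF file path.
#' @return `write_images_tiff` returns `path` invisibly;
#'   `read_images_tiff` returns a [particle_images].
#' @export
write_images_tiff <- function(images, path) {
  stopifnot(inherits(images, "particle_images"))
  maxI <- 2^images$bit_depth - 1
  flipped <- lapply(images$frames, function(f)
    f[rev(seq_len(nrow(f))), , drop = FALSE] / maxI)
  tiff::writeTIFF(flipped, path, bits.per.sample = images$bit_depth)
  writeLines(c(sprintf("pixel_size_mm=%.17g", images$pixel_size),
               sprintf("frame_rate_fps=%.17g", images$frame_rate),
               sprintf("bit_depth=%d", images$bit_depth)),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_images_tiff
#' @export
read_images_tiff <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) stop("sidecar file not found: ", meta_path)
  kv <- strsplit(readLines(meta_path), "=")
  meta <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  bit_depth <- as.integer(meta$bit_depth)
  raw <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  maxI <- 2^bit_depth - 1
  frames <- lapply(raw, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]
    f[rev(seq_len(nrow(f))), , drop = FALSE] * maxI
  })
  particle_images(frames, as.numeric(meta$pixel_size_mm),
                  as.numeric(meta$frame_rate_fps), bit_depth)
}
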
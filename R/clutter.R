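#' Singular value decomposition of the Casorati matrix
#'
#' Reshapes an image sequence into its Casorati matrix (pixels x frames) and
#' computes the thin SVD. Spatial singular vectors are stored one image per
#' component; temporal singular vectors one series per component. The
#' decomposition is exact: reconstruction from all components reproduces the
#' input to numerical precision.
#'
#' @param images A [particle_images] (>= 2 frames).
#' @return An object of class `svd_decomposition` with fields `d` (singular
#'   values, descending), `u` (pixels x rank spatial vectors), `v` (frames x
#'   rank temporal vectors), `dim` (image dimensions) and `meta` (acquisition
#'   metadata used to rebuild sequences).
#' @export
casorati_svd <- function(images) {
  stopifnot(inherits(images, "particle_images"))
  n <- length(images$frames)
  X <- vapply(images$frames, as.vector,
              numeric(length(images$frames[[1]])))
  s <- svd(X)
  structure(list(d = s$d, u = s$u, v = s$v, dim = dim(images$frames[[1]]),
                 meta = list(pixel_size = images$pixel_size,
                             frame_rate = images$frame_rate,
                             bit_depth = images$bit_depth,
                             ground_truth = images$ground_truth)),
            class = "svd_decomposition")
}

#' @export
print.svd_decomposition <- function(x, ...) {
  cat(sprintf("Casorati SVD: %d x %d px, %d frames, rank %d\n",
              x$dim[1], x$dim[2], nrow(x$v), length(x$d)))
  cat("  leading singular values:",
      paste(signif(utils::head(x$d, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Semi-automatic clutter/noise rank thresholds from the similarity matrix
#'
#' Computes the matrix of pairwise absolute correlation coefficients between
#' the magnitudes of the spatial singular vectors. Clutter components are
#' spatially coherent and mutually similar, forming a high-similarity leading
#' diagonal block; the lower threshold is set to the last component of the
#' uninterrupted leading run whose similarity to the first component stays at
#' or above `similarity_threshold`. The upper threshold defaults to the full
#' rank. Both can be overridden manually and are then returned unchanged.
#'
#' @param decomposition An [casorati_svd()] result (rank >= 3).
#' @param similarity_threshold Running-mean similarity cutoff (default 0.3).
#' @param low,high Manual overrides; if both given they are passed through.
#' @return List with elements `low`, `high` and the `similarity` matrix.
#' @export
select_rank_thresholds <- function(decomposition, similarity_threshold = 0.3,
                                   low = NULL, high = NULL) {
  stopifnot(inherits(decomposition, "svd_decomposition"))
  rank <- length(decomposition$d)
  if (rank < 3L) stop("decomposition rank must be >= 3")
  if (!is.null(low) && !is.null(high))
    return(list(low = low, high = high, similarity = NULL))
  au <- abs(decomposition$u)
  sim <- suppressWarnings(abs(stats::cor(au)))
  sim[!is.finite(sim)] <- 0
  s1 <- sim[1, ]
  below <- which(s1 < similarity_threshold)
  # a clutter block needs an energetically dominant leading subspace; a
  # flat singular spectrum means there is nothing to separate
  if (decomposition$d[1] < 3 * stats::median(decomposition$d)) {
    warning("no similarity block structure detected; returning (1, rank)")
    return(list(low = if (is.null(low)) 1L else low,
                high = if (is.null(high)) rank else high,
                similarity = sim))
  }
  lo <- if (length(below) == 0L) rank - 1L else max(1L, below[1] - 1L)
  hi <- rank
  list(low = if (is.null(low)) lo else low,
       high = if (is.null(high)) hi else high,
       similarity = sim)
}

#' SVD clutter filter
#'
#' Reconstructs the image sequence from singular components with index in
#' `(low, high]`, i.e. discarding the `low` strongest (clutter) components
#' and any components beyond `high` (noise). `low = 0, high = rank` is the
#' identity. The filter is linear: filtering a sum of sequences with shared
#' thresholds equals the sum of filtered sequences.
#'
#' @param images A [particle_images].
#' @param low Lower rank threshold (components 1..low removed); >= 0.
#' @param high Upper rank threshold (components > high removed); defaults to
#'   the full rank.
#' @param decomposition Optional [casorati_svd()] result supplying the
#'   basis. When given, the filter acts as the fixed linear projector onto
#'   the retained spatial subspace, which makes it exactly additive across
#'   sequences filtered with a shared decomposition; by default the basis is
#'   recomputed from `images`.
#' @return The filtered [particle_images]; intensities may leave the
#'   bit-depth range and are not clipped.
#' @export
svd_filter <- function(images, low, high = NULL, decomposition = NULL) {
  stopifnot(inherits(images, "particle_images"))
  dec <- if (is.null(decomposition)) casorati_svd(images) else decomposition
  rank <- length(dec$d)
  if (is.null(high)) high <- rank
  if (low < 0 || high > rank || low >= high)
    stop("need 0 <= low < high <= rank")
  keep <- (low + 1L):high
  if (is.null(decomposition)) {
    X <- dec$u[, keep, drop = FALSE] %*%
      (dec$d[keep] * t(dec$v[, keep, drop = FALSE]))
  } else {
    X0 <- vapply(images$frames, as.vector,
                 numeric(length(images$frames[[1]])))
    U <- dec$u[, keep, drop = FALSE]
    X <- U %*% crossprod(U, X0)
  }
  frames <- lapply(seq_len(ncol(X)), function(f)
    matrix(X[, f], dec$dim[1], dec$dim[2]))
  out <- images
  out$frames <- frames
  out
}

#' Reconstruct an image sequence from selected SVD components
#'
#' @param decomposition An [casorati_svd()] result.
#' @param components Indices of the singular components to keep.
#' @return List of frames (matrices).
#' @export
svd_reconstruct <- function(decomposition,
                            components = seq_along(decomposition$d)) {
  stopifnot(inherits(decomposition, "svd_decomposition"))
  X <- decomposition$u[, components, drop = FALSE] %*%
    (decomposition$d[components] * t(decomposition$v[, components,
                                                     drop = FALSE]))
  lapply(seq_len(ncol(X)), function(f)
    matrix(X[, f], decomposition$dim[1], decomposition$dim[2]))
}
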
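#' 3D photoacoustic volume
#'
#' Container for a 3D scalar field indexed `[x, y, z]` with per-axis voxel
#' spacing in micrometres. The third array axis is always the depth (A-line)
#' axis, increasing away from the scanning plane. Voxel `(i, j, k)` (1-based)
#' has its physical center at `((i - 0.5) * dx, (j - 0.5) * dy, (k - 0.5) * dz)`
#' micrometres, with the origin at the volume corner.
#'
#' @param data numeric 3D array, dimensions `(nx, ny, nz)`; finite values only.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in um; all > 0.
#' @param sampling_rate optional sampling rate along the depth axis in MHz;
#'   required by [bandpass()] on raw RF data.
#' @return An object of class `pa_volume`.
#' @export
pa_volume <- function(data, spacing, sampling_rate = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (x, y, z)")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel spacings (dx, dy, dz) in um")
  if (anyNA(data) || any(!is.finite(data)))
    stop("`data` must contain finite values only")
  if (!is.null(sampling_rate)) {
    if (length(sampling_rate) != 1L || sampling_rate <= 0)
      stop("`sampling_rate` must be a positive scalar (MHz)")
    sampling_rate <- as.numeric(sampling_rate)
  }
  structure(
    list(data = data, spacing = as.numeric(spacing),
         sampling_rate = sampling_rate),
    class = "pa_volume"
  )
}

#' @export
print.pa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pa_volume> %d x %d x %d voxels, spacing (%g, %g, %g) um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  if (!is.null(x$sampling_rate))
    cat(sprintf("  sampling rate: %g MHz (depth axis = 3)\n", x$sampling_rate))
  cat(sprintf("  amplitude range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Binary (thresholded) photoacoustic volume
#'
#' The occupancy field `P(x, y, z)` with vessel voxels set to 1 and the
#' background to 0.
#'
#' @param data 3D array of 0/1 (logical or numeric).
#' @param spacing voxel spacing `(dx, dy, dz)` in um.
#' @return An object of class `pa_binary_volume`.
#' @export
pa_binary_volume <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  } else if (!all(data %in% c(0L, 1L))) {
    stop("binary volume values must be 0 or 1 only")
  } else {
    storage.mode(data) <- "integer"
  }
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive voxel spacings in um")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "pa_binary_volume")
}

#' @export
print.pa_binary_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pa_binary_volume> %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

# Physical voxel-center coordinates along one axis (um).
axis_centers <- function(n, step) (seq_len(n) - 0.5) * step

# N x 3 matrix of physical centers of the foreground voxels of a binary
# volume. Used by the scoring kernel; computed once per volume.
ones_coords <- function(P) {
  stopifnot(inherits(P, "pa_binary_volume"))
  idx <- which(P$data == 1L)
  if (length(idx) == 0L)
    return(matrix(numeric(0), ncol = 3))
  ai <- arrayInd(idx, dim(P$data))
  cbind((ai[, 1] - 0.5) * P$spacing[1],
        (ai[, 2] - 0.5) * P$spacing[2],
        (ai[, 3] - 0.5) * P$spacing[3])
}

# Squared distance of every voxel center from a 3D point, as an array
# matching `dims`. Built from outer sums so it stays cheap on full volumes.
voxel_dist2 <- function(dims, spacing, center) {
  ax <- (axis_centers(dims[1], spacing[1]) - center[1])^2
  ay <- (axis_centers(dims[2], spacing[2]) - center[2])^2
  az <- (axis_centers(dims[3], spacing[3]) - center[3])^2
  outer(outer(ax, ay, "+"), az, "+")
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
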
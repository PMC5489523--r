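#' 2D depth map over the scan plane
#'
#' @param values numeric matrix `(nx, ny)` of depths/distances in um; `NA`
#'   at background pixels.
#' @param background_mask logical matrix, `TRUE` where there is no signal.
#' @param kind `"conventional"` (depth of the maximum signal below the
#'   scanning plane) or `"surface_based"` (signed radial distance from the
#'   estimated eyeball surface).
#' @param spacing pixel spacing `(dx, dy)` um.
#' @param amplitude optional matrix of the per-pixel maximum amplitudes.
#' @return An object of class `depth_map`.
#' @export
depth_map <- function(values, background_mask, kind, spacing,
                      amplitude = NULL) {
  kind <- match.arg(kind, c("conventional", "surface_based"))
  stopifnot(is.matrix(values), is.matrix(background_mask),
            all(dim(values) == dim(background_mask)))
  values[background_mask] <- NA_real_
  structure(list(values = values, background_mask = background_mask,
                 kind = kind, spacing = as.numeric(spacing),
                 amplitude = amplitude),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %s, %d x %d px, %d background (%.1f%%)\n",
              x$kind, nrow(x$values), ncol(x$values), sum(x$background_mask),
              100 * mean(x$background_mask)))
  if (any(!x$background_mask))
    cat(sprintf("  depth range: [%.1f, %.1f] um\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Conventional depth-encoded map (depth of the maximum signal)
#'
#' Per lateral pixel, the physical depth (um, voxel-center convention) of the
#' maximum enveloped amplitude along the A-line. When several voxels tie for
#' the maximum, the shallowest (smallest z) is returned. Pixels whose maximum
#' amplitude does not exceed the background rule's threshold are masked.
#'
#' @param volume enveloped (nonnegative) [pa_volume()].
#' @param background_rule [threshold_rule()] deciding which pixels carry
#'   signal. Default: fraction 0.1 of the volume maximum.
#' @return A `"conventional"` [depth_map()] carrying the per-pixel maximum
#'   amplitude in `$amplitude`.
#' @export
conventional_depth_map <- function(volume,
                                   background_rule =
                                     threshold_rule(value = 0.1)) {
  stopifnot(inherits(volume, "pa_volume"))
  if (any(volume$data < 0))
    stop("depth maps require an enveloped (nonnegative) volume")
  d <- dim(volume$data)
  m <- matrix(volume$data, nrow = d[1] * d[2], ncol = d[3])
  k <- max.col(m, ties.method = "first")
  amp <- m[cbind(seq_len(nrow(m)), k)]
  thr <- compute_threshold(background_rule, volume$data)
  mask <- matrix(amp <= thr, d[1], d[2])
  vals <- matrix((k - 0.5) * volume$spacing[3], d[1], d[2])
  depth_map(vals, mask, "conventional", volume$spacing[1:2],
            amplitude = matrix(amp, d[1], d[2]))
}

#' Surface-based depth-encoded map
#'
#' Converts a conventional depth map into signed radial distance from the
#' estimated eyeball surface: per unmasked pixel,
#' `sqrt((x - x')^2 + (y - y')^2 + (D_c - z')^2) - r'`. Positive values lie
#' outside the estimated sphere (supra-surface), negative inside.
#'
#' @param D_c a `"conventional"` [depth_map()].
#' @param sphere the estimated [sphere_params()].
#' @return A `"surface_based"` [depth_map()] (amplitude carried over).
#' @export
surface_depth_map <- function(D_c, sphere) {
  stopifnot(inherits(D_c, "depth_map"), inherits(sphere, "sphere_params"))
  if (D_c$kind != "conventional")
    stop("`D_c` must be a conventional depth map")
  d <- dim(D_c$values)
  px <- axis_centers(d[1], D_c$spacing[1]) - sphere[["x"]]
  py <- axis_centers(d[2], D_c$spacing[2]) - sphere[["y"]]
  lat2 <- outer(px^2, py^2, "+")
  vals <- sqrt(lat2 + (D_c$values - sphere[["z"]])^2) - sphere[["r"]]
  depth_map(vals, D_c$background_mask, "surface_based", D_c$spacing,
            amplitude = D_c$amplitude)
}

#' Render a depth map as a depth-encoded color image
#'
#' Depth maps to hue over `display_range` (blue at the low end through red at
#' the high end), saturating out-of-range values at the endpoints; amplitude
#' maps to brightness; background renders black. The default range
#' (-50, +150) um spans the on-surface and supra-surface vessel layers.
#'
#' @param D a [depth_map()].
#' @param amplitude optional brightness matrix; defaults to the map's stored
#'   amplitude, or flat brightness if none.
#' @param display_range `(lo, hi)` um, `lo < hi`.
#' @return numeric array `(nx, ny, 3)` of RGB in `[0, 1]`.
#' @export
render_depth_encoded <- function(D, amplitude = NULL,
                                 display_range = c(-50, 150)) {
  stopifnot(inherits(D, "depth_map"))
  lo <- display_range[1]; hi <- display_range[2]
  if (!(lo < hi)) stop("display_range must satisfy lo < hi")
  if (is.null(amplitude)) amplitude <- D$amplitude
  bright <- if (is.null(amplitude)) {
    matrix(1, nrow(D$values), ncol(D$values))
  } else {
    mx <- max(amplitude[!D$background_mask], 0)
    if (mx > 0) pmin(pmax(amplitude / mx, 0), 1)
    else matrix(1, nrow(D$values), ncol(D$values))
  }
  t_ <- pmin(pmax((D$values - lo) / (hi - lo), 0), 1)
  hue <- depth_hue(t_)
  hue[is.na(hue)] <- 0
  bright[D$background_mask] <- 0
  col <- grDevices::hsv(h = hue, s = 1, v = as.vector(bright))
  rgb <- grDevices::col2rgb(col) / 255
  array(c(rgb[1, ], rgb[2, ], rgb[3, ]),
        dim = c(nrow(D$values), ncol(D$values), 3))
}

# Normalized depth in [0, 1] -> hue (blue = deep/low to red = high).
depth_hue <- function(t_) (1 - t_) * 0.7

#' Write an RGB array as a PNG image
#'
#' Thin convenience wrapper (requires the `png` package). The first array
#' axis (x) renders as image columns.
#'
#' @param img `(nx, ny, 3)` RGB array in `[0, 1]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_png_image <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing PNG images requires the `png` package")
  png::writePNG(aperm(img, c(2, 1, 3)), path)
  invisible(path)
}
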
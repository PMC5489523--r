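#' Cosine slope map of the estimated spherical surface
#'
#' Per unmasked pixel, `C = (z' - D_c) / (r' + D_s)`: the ratio of the
#' vertical leg to the radial distance of the pixel's signal point from the
#' estimated center. On the upper hemisphere this is exactly the cosine of
#' the angle between the local surface normal and the depth axis, so `1/C`
#' is the factor by which projecting the curved surface onto the scan plane
#' shrinks area. `C = 1` at the apex; `C <= 0` (signal at or below the
#' equator) is left in the map and excluded — with a logged count — by
#' [cnv_area()].
#'
#' @param D_c conventional [depth_map()].
#' @param D_s surface-based [depth_map()], aligned with `D_c`.
#' @param sphere estimated [sphere_params()].
#' @return numeric matrix; `NA` at background pixels.
#' @export
cosine_map <- function(D_c, D_s, sphere) {
  stopifnot(inherits(D_c, "depth_map"), inherits(D_s, "depth_map"),
            inherits(sphere, "sphere_params"))
  if (D_c$kind != "conventional" || D_s$kind != "surface_based")
    stop("need a conventional map and a surface-based map, in that order")
  if (!all(dim(D_c$values) == dim(D_s$values)))
    stop("depth maps are not aligned")
  (sphere[["z"]] - D_c$values) / (sphere[["r"]] + D_s$values)
}

#' Segment corneal new vessels
#'
#' `B_CNV = supra_surface_mask(D_s, band) AND roi`. The ROI mask stands in
#' for the manual upper-hemisphere selection demarcated by the limbal
#' vessels.
#'
#' @param D_s surface-based [depth_map()].
#' @param band [radial_band()]; default `(180, Inf)` um, the corneal
#'   new-vessel band.
#' @param roi 0/1 or logical matrix aligned with `D_s`.
#' @return integer 0/1 matrix.
#' @export
segment_cnv <- function(D_s, band = radial_band(180, Inf), roi) {
  stopifnot(inherits(D_s, "depth_map"))
  if (!all(dim(roi) == dim(D_s$values)))
    stop("`roi` is not aligned with the depth map")
  if (sum(roi) == 0) warning("empty ROI: segmentation is empty")
  out <- supra_surface_mask(D_s, band) * (roi != 0)
  mode(out) <- "integer"
  out
}

#' Slope-corrected neovascular area
#'
#' `A_CNV = A_pixel * sum over selected pixels of 1 / C(x, y)`: each selected
#' pixel's projected area is inflated by the local spherical slope, so the
#' result approximates the true area on the curved surface. Pixels whose
#' cosine is missing, nonpositive, or below `c_floor` are excluded from the
#' sum and counted — the sum diverges as `C -> 0`, so near-equator pixels
#' are guarded rather than allowed to inflate the area without bound. Set
#' `c_floor = 0` to keep every strictly positive cosine (the analytic
#' closed-form limit).
#'
#' @param B_CNV 0/1 segmentation matrix.
#' @param C cosine map from [cosine_map()].
#' @param pixel_area projected area of one pixel, mm^2 (`dx * dy * 1e-6` for
#'   spacings in um).
#' @param c_floor minimum accepted cosine; default 0.1.
#' @return An object of class `cnv_area_result`: `area` (mm^2),
#'   `pixel_area`, `n_pixels` (pixels summed), `n_excluded` (selected but
#'   invalid), and `cosine_stats` (min/mean of C over summed pixels).
#' @export
cnv_area <- function(B_CNV, C, pixel_area, c_floor = 0.1) {
  if (!all(dim(B_CNV) == dim(C))) stop("segmentation and cosine map differ")
  if (pixel_area <= 0) stop("pixel_area must be positive")
  if (c_floor < 0) stop("c_floor must be >= 0")
  sel <- B_CNV != 0
  valid <- sel & !is.na(C) & C > 0 & C >= c_floor
  n_excluded <- sum(sel) - sum(valid)
  cvals <- C[valid]
  structure(list(
    area = pixel_area * sum(1 / cvals),
    pixel_area = pixel_area,
    n_pixels = sum(valid),
    n_excluded = n_excluded,
    cosine_stats = if (length(cvals))
      c(min = min(cvals), mean = mean(cvals)) else c(min = NA, mean = NA)
  ), class = "cnv_area_result")
}

#' @export
print.cnv_area_result <- function(x, ...) {
  cat(sprintf("<cnv_area_result> %.4f mm^2 over %d pixels (%d excluded)\n",
              x$area, x$n_pixels, x$n_excluded))
  if (!is.na(x$cosine_stats[["min"]]))
    cat(sprintf("  cosine: min %.3f, mean %.3f\n",
                x$cosine_stats[["min"]], x$cosine_stats[["mean"]]))
  invisible(x)
}
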
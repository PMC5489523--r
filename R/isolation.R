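#' Radial band relative to the estimated surface
#'
#' Offsets are in um relative to the estimated half-diameter `r'`;
#' `hi_offset` may be `Inf` (everything above `lo_offset`). Band membership
#' is strict on both boundaries, matching the shell-mask convention of the
#' matching score.
#'
#' @param lo_offset,hi_offset band limits, um, `lo_offset < hi_offset`.
#' @return An object of class `radial_band`.
#' @export
radial_band <- function(lo_offset, hi_offset) {
  if (!(lo_offset < hi_offset)) stop("radial band requires lo < hi")
  structure(list(lo = lo_offset, hi = hi_offset), class = "radial_band")
}

#' Segment supra-surface vessels by thresholding the surface-based map
#'
#' Pixel selected iff it carries signal and its surface-based distance lies
#' strictly inside the band, e.g. band `(120, Inf)` isolates limbal and
#' episcleral vessels; `(180, Inf)` corneal new vessels.
#'
#' @param D_s a `"surface_based"` [depth_map()].
#' @param band a [radial_band()].
#' @return integer 0/1 matrix the size of the map.
#' @export
supra_surface_mask <- function(D_s, band) {
  stopifnot(inherits(D_s, "depth_map"), inherits(band, "radial_band"))
  if (D_s$kind != "surface_based")
    stop("supra-surface segmentation needs a surface-based depth map")
  sel <- !D_s$background_mask & D_s$values > band$lo & D_s$values < band$hi
  sel[is.na(sel)] <- FALSE
  mode(sel) <- "integer"
  sel
}

#' Project enveloped signal within a radial band (on-surface isolation)
#'
#' Per lateral pixel, the maximum enveloped amplitude over voxels whose
#' radial distance from the estimated center lies strictly inside
#' `(r' + lo, r' + hi)`, e.g. band `(0, 80)` isolates iris and
#' choroidal/retinal vessels lying on the surface. Signals below the
#' estimated surface are excluded by contract (`lo_offset >= 0`) to
#' eliminate reverberation artifacts. Pixels with no voxel in the band are
#' `NA` (background).
#'
#' @param volume enveloped [pa_volume()].
#' @param sphere estimated [sphere_params()].
#' @param band a [radial_band()] with `lo_offset >= 0`.
#' @return numeric matrix `(nx, ny)`; `NA` = background. Attribute
#'   `"spacing"` carries the pixel spacing.
#' @export
band_projection <- function(volume, sphere, band) {
  stopifnot(inherits(volume, "pa_volume"), inherits(sphere, "sphere_params"),
            inherits(band, "radial_band"))
  if (band$lo < 0)
    stop(paste("band lo_offset < 0: signals below the estimated surface are",
               "excluded to eliminate reverberation artifacts"))
  d <- dim(volume$data)
  d2 <- voxel_dist2(d, volume$spacing,
                    c(sphere[["x"]], sphere[["y"]], sphere[["z"]]))
  lo <- sphere[["r"]] + band$lo
  hi <- sphere[["r"]] + band$hi
  inband <- d2 > lo^2 & (if (is.finite(hi)) d2 < hi^2 else TRUE)
  masked <- volume$data
  masked[!inband] <- -Inf
  m <- matrix(masked, nrow = d[1] * d[2], ncol = d[3])
  mx <- do.call(pmax, as.data.frame(m))
  mx[!is.finite(mx)] <- NA_real_
  out <- matrix(mx, d[1], d[2])
  attr(out, "spacing") <- volume$spacing[1:2]
  out
}
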
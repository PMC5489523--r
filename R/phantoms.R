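#' Specification of a synthetic eye phantom
#'
#' Describes a spherical-shell "eye" whose vessel signal lies in radial bands
#' around a known ground-truth sphere: an on-surface band emulating
#' iris/choroidal/retinal vessels and a supra-surface band emulating limbal
#' and episcleral vessels (or corneal new vessels). Vessels are great-circle
#' arcs on the offset sphere dilated to tubes. An optional fraction of
#' "outlier" voxels — clutter standing in for hemorrhage and reverberation —
#' is placed uniformly at random outside the bands, at vessel amplitude.
#'
#' The default grid (128 x 128 x 96 voxels at 25 um isotropic spacing) spans
#' 3.2 x 3.2 x 2.4 mm, the scale of a downsized anterior-segment scan, so the
#' default initial sampling ranges of [initial_ranges()] apply unchanged.
#'
#' @param grid_shape voxel counts `(nx, ny, nz)`.
#' @param voxel_spacing `(dx, dy, dz)` um, all > 0.
#' @param true_sphere ground-truth [sphere_params()], um.
#' @param vessel_bands list of bands, each a list with fields `lo`, `hi`
#'   (radial offsets from the true half-diameter, um, `lo < hi`), `n_arcs`,
#'   `tube_radius` (um) and optionally `arc_extent` (radians, default full
#'   circle).
#' @param signal_amplitude vessel amplitude (unitless).
#' @param noise_sigma additive Gaussian noise s.d. on amplitude.
#' @param outlier_fraction fraction of all signal voxels that are uniformly
#'   placed outliers; `0 <= f < 1`.
#' @param carrier_freq optional RF carrier, MHz (applied by [modulate_rf()]).
#' @param sampling_rate depth-axis sampling rate, MHz.
#' @param seed RNG seed; generation is bit-reproducible under a fixed seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 96L),
                         voxel_spacing = c(25, 25, 25),
                         true_sphere = sphere_params(1450, 1700, 2400, 1750),
                         vessel_bands = list(
                           list(lo = 0, hi = 80, n_arcs = 10L,
                                tube_radius = 30),
                           list(lo = 120, hi = 150, n_arcs = 6L,
                                tube_radius = 30)),
                         signal_amplitude = 1, noise_sigma = 0.1,
                         outlier_fraction = 0,
                         carrier_freq = NULL, sampling_rate = 500,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("grid_shape must be three voxel counts >= 4")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("voxel spacings must be positive")
  stopifnot(inherits(true_sphere, "sphere_params"))
  for (b in vessel_bands) {
    if (!(b$lo < b$hi)) stop("vessel band must have lo < hi")
    if (b$tube_radius <= 0) stop("tube_radius must be positive")
  }
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  if (!is.null(carrier_freq) && sampling_rate <= 2 * carrier_freq)
    stop("sampling_rate must exceed twice the carrier frequency")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing = as.numeric(voxel_spacing),
                 true_sphere = true_sphere, vessel_bands = vessel_bands,
                 signal_amplitude = signal_amplitude,
                 noise_sigma = noise_sigma,
                 outlier_fraction = outlier_fraction,
                 carrier_freq = carrier_freq, sampling_rate = sampling_rate,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic eye volume with known ground truth
#'
#' Rasterizes each vessel band as great-circle arcs on the sphere of radius
#' `r_true + (lo + hi)/2`, dilated to tubes of the band's `tube_radius` and
#' clipped to the band's radial extent, so in the noise-free case every
#' non-outlier vessel voxel's distance from the true center lies inside its
#' declared band. Arc normals are drawn near the scan plane (tilt within
#' +/- 30 degrees) so the arcs cross the imaged upper cap of the eye.
#' Amplitude is `signal_amplitude` plus Gaussian noise at vessel/outlier
#' voxels and noise alone in the background.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([pa_volume()]), `ground_truth`
#'   ([sphere_params()]), `band_labels` (integer array; 0 background, k =
#'   band index), `outlier_mask` (logical array) and `arcs` (the drawn arc
#'   geometry: band, normal, radius, tube radius, extent — so tests can
#'   re-rasterize the geometry independently).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape; sp <- spec$voxel_spacing
  gt <- spec$true_sphere
  ext <- d * sp
  # the shell must intersect the grid: compare the voxel-center distance
  # range attainable in the box with the outermost band shell
  ctr0 <- c(gt[["x"]], gt[["y"]], gt[["z"]])
  corner_d <- sqrt(sum(pmax(abs(ctr0), abs(ctr0 - ext))^2))
  min_d <- sqrt(sum(pmax(pmax(0 - ctr0, ctr0 - ext), 0)^2))
  offs <- unlist(lapply(spec$vessel_bands, function(b) c(b$lo, b$hi)))
  if (gt[["r"]] + max(offs) < min_d || gt[["r"]] + min(offs) > corner_d)
    stop("ground-truth sphere shell does not intersect the phantom grid")

  with_seed(spec$seed, {
    ctr <- c(gt[["x"]], gt[["y"]], gt[["z"]])
    radial <- sqrt(voxel_dist2(d, sp, ctr))
    labels <- array(0L, dim = d)
    arcs <- list()
    xs <- axis_centers(d[1], sp[1])
    ys <- axis_centers(d[2], sp[2])
    zs <- axis_centers(d[3], sp[3])
    for (k in seq_along(spec$vessel_bands)) {
      b <- spec$vessel_bands[[k]]
      r_mid <- gt[["r"]] + (b$lo + b$hi) / 2
      # voxels whose radial offset can possibly be inside the dilated band
      cand <- which(radial >= gt[["r"]] + b$lo & radial <= gt[["r"]] + b$hi)
      if (length(cand) == 0L) next
      ai <- arrayInd(cand, d)
      p <- cbind(xs[ai[, 1]] - ctr[1], ys[ai[, 2]] - ctr[2],
                 zs[ai[, 3]] - ctr[3])
      hit <- rep(FALSE, length(cand))
      extent <- if (is.null(b$arc_extent)) 2 * pi else b$arc_extent
      for (a in seq_len(b$n_arcs)) {
        az <- stats::runif(1, 0, 2 * pi)
        tilt <- stats::runif(1, -pi / 6, pi / 6)
        nrm <- c(cos(az) * cos(tilt), sin(az) * cos(tilt), sin(tilt))
        arcs[[length(arcs) + 1L]] <- list(band = k, normal = nrm,
                                          radius = r_mid,
                                          tube_radius = b$tube_radius,
                                          extent = extent)
        hit <- hit | circle_within(p, nrm, r_mid, b$tube_radius, extent)
      }
      sel <- cand[hit & labels[cand] == 0L]
      labels[sel] <- k
    }
    n_band <- sum(labels > 0L)
    outlier <- array(FALSE, dim = d)
    if (spec$outlier_fraction > 0 && n_band > 0L) {
      f <- spec$outlier_fraction
      n_out <- round(f / (1 - f) * n_band)
      free <- which(labels == 0L)
      outlier[sample(free, min(n_out, length(free)))] <- TRUE
    }
    data <- array(stats::rnorm(prod(d), 0, spec$noise_sigma), dim = d)
    data[labels > 0L | outlier] <- data[labels > 0L | outlier] +
      spec$signal_amplitude
    # the phantom stands in for enveloped data, which is nonnegative:
    # rectify (half-normal background; vessel amplitudes virtually unclipped)
    data <- pmax(data, 0)
    list(volume = pa_volume(data, sp, sampling_rate = spec$sampling_rate),
         ground_truth = gt, band_labels = labels, outlier_mask = outlier,
         arcs = arcs)
  })
}

# TRUE for points (rows of p, coordinates relative to the sphere center)
# within `tube` of the circle of radius rho and unit normal nrm. Distance to
# a full circle is closed-form: with w_n the out-of-plane and w_r the
# in-plane components, d = sqrt((w_r - rho)^2 + w_n^2). For partial arcs the
# in-plane azimuth must additionally fall inside the extent.
circle_within <- function(p, nrm, rho, tube, extent = 2 * pi) {
  wn <- p %*% nrm
  wr2 <- pmax(rowSums(p^2) - wn^2, 0)
  wr <- sqrt(wr2)
  d2 <- (wr - rho)^2 + wn^2
  ok <- d2 <= tube^2
  if (extent < 2 * pi && any(ok)) {
    # in-plane basis
    u <- if (abs(nrm[3]) < 0.9) c(-nrm[2], nrm[1], 0) else c(1, 0, 0)
    u <- u - sum(u * nrm) * nrm
    u <- u / sqrt(sum(u^2))
    v <- c(nrm[2] * u[3] - nrm[3] * u[2],
           nrm[3] * u[1] - nrm[1] * u[3],
           nrm[1] * u[2] - nrm[2] * u[1])
    ang <- atan2(p %*% v, p %*% u)
    ok <- ok & (ang >= -extent / 2 & ang <= extent / 2)
  }
  as.vector(ok)
}

#' Impose an RF carrier on an amplitude volume
#'
#' Multiplies each A-line's amplitude profile by a sinusoidal carrier so the
#' band-pass + Hilbert-envelope preprocessing chain can be exercised: the
#' envelope of the output recovers the input amplitude away from edges.
#'
#' @param volume amplitude [pa_volume()].
#' @param carrier_freq carrier frequency, MHz.
#' @param sampling_rate depth-axis sampling rate, MHz; must exceed twice the
#'   carrier (Nyquist).
#' @return RF [pa_volume()] carrying `sampling_rate`.
#' @export
modulate_rf <- function(volume, carrier_freq, sampling_rate) {
  stopifnot(inherits(volume, "pa_volume"))
  if (sampling_rate <= 2 * carrier_freq)
    stop("Nyquist violation: sampling_rate must exceed 2 x carrier_freq")
  nz <- dim(volume$data)[3]
  t_us <- (seq_len(nz) - 1) / sampling_rate          # us
  carrier <- sin(2 * pi * carrier_freq * t_us)       # MHz * us = cycles
  dat <- sweep(volume$data, 3, carrier, `*`)
  pa_volume(dat, volume$spacing, sampling_rate = sampling_rate)
}
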
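# Cosine slope map and slope-corrected neovascular area.

# Analytic on-sphere depth maps over the projected disk of the upper
# hemisphere: D_c = z' - sqrt(r^2 - rho^2), D_s = 0.
analytic_sphere_maps <- function(sp, n, spacing) {
  px <- (seq_len(n) - 0.5) * spacing
  py <- (seq_len(n) - 0.5) * spacing
  rho2 <- outer((px - sp[["x"]])^2, (py - sp[["y"]])^2, "+")
  inside <- rho2 < sp[["r"]]^2
  vals <- matrix(NA_real_, n, n)
  vals[inside] <- sp[["z"]] - sqrt(sp[["r"]]^2 - rho2[inside])
  D_c <- depth_map(vals, !inside, "conventional", c(spacing, spacing))
  list(D_c = D_c, D_s = surface_depth_map(D_c, sp), inside = inside)
}

test_that("cosine map is the surface-normal cosine", {
  sp <- sphere_params(1000, 1000, 2000, 800)
  m <- analytic_sphere_maps(sp, 100, 20)
  C <- cosine_map(m$D_c, m$D_s, sp)
  # near-apex pixel: C ~ 1 (normal parallel to depth axis)
  apex <- which.min(abs(m$D_c$values - (sp[["z"]] - sp[["r"]])))
  expect_equal(C[apex], 1, tolerance = 1e-3)
  # a pixel exactly on the sphere axis with on-sphere signal: C = 1 exactly
  vals <- matrix(sp[["z"]] - sp[["r"]], 1, 1)
  Dc1 <- depth_map(vals, matrix(FALSE, 1, 1), "conventional", c(2000, 2000))
  Ds1 <- surface_depth_map(Dc1, sp)   # pixel center (1000, 1000)
  expect_identical(cosine_map(Dc1, Ds1, sp)[1, 1], 1)
  # polar angle 60 degrees: C = cos(60) = 0.5
  rho_60 <- sp[["r"]] * sin(pi / 3)
  px <- (seq_len(100) - 0.5) * 20
  rho <- sqrt(outer((px - 1000)^2, (px - 1000)^2, "+"))
  band60 <- which(abs(rho - rho_60) < 2 & m$inside)
  expect_gt(length(band60), 0)
  expect_equal(C[band60], rep(0.5, length(band60)), tolerance = 0.01)
  expect_true(all(C[m$inside] <= 1 + 1e-12))
})

test_that("phantom on-sphere cosines match the geometric oracle exactly", {
  spec <- small_phantom_spec(seed = 53, noise_sigma = 0)
  ph <- generate_phantom(spec)
  gt <- ph$ground_truth
  D_c <- conventional_depth_map(ph$volume, threshold_rule("absolute", 0.5))
  D_s <- surface_depth_map(D_c, gt)
  C <- cosine_map(D_c, D_s, gt)
  sel <- !D_c$background_mask
  # oracle from ground-truth geometry: (z' - z_signal) / dist_to_center
  g <- grid_centers(dim(ph$volume$data), ph$volume$spacing)
  idx <- which(sel, arr.ind = TRUE)
  for (q in seq_len(min(nrow(idx), 200))) {
    i <- idx[q, 1]; j <- idx[q, 2]
    z_sig <- D_c$values[i, j]
    dist <- sqrt((g$x[i] - gt[["x"]])^2 + (g$y[j] - gt[["y"]])^2 +
                 (z_sig - gt[["z"]])^2)
    expect_equal(C[i, j], (gt[["z"]] - z_sig) / dist, tolerance = 1e-12)
  }
})

test_that("segment_cnv is the supra-surface mask restricted to the ROI", {
  set.seed(81)
  vals <- matrix(runif(400, -50, 400), 20, 20)
  D_s <- depth_map(vals, matrix(FALSE, 20, 20), "surface_based", c(25, 25))
  roi <- matrix(0L, 20, 20); roi[1:10, ] <- 1L
  B <- segment_cnv(D_s, radial_band(180, Inf), roi)
  oracle <- supra_surface_mask(D_s, radial_band(180, Inf)) * roi
  expect_identical(B, oracle)
  expect_true(all(B[11:20, ] == 0))
  expect_warning(segment_cnv(D_s, radial_band(180, Inf),
                             matrix(0L, 20, 20)), "empty ROI")
  expect_error(segment_cnv(D_s, radial_band(180, Inf), matrix(1L, 3, 3)),
               "aligned")
})

test_that("phantom CNV arcs at 200 um are segmented exactly", {
  spec <- small_phantom_spec(seed = 59, noise_sigma = 0,
                             vessel_bands = list(
                               list(lo = 190, hi = 210, n_arcs = 4L,
                                    tube_radius = 40)))
  ph <- generate_phantom(spec)
  D_c <- conventional_depth_map(ph$volume, threshold_rule("absolute", 0.5))
  D_s <- surface_depth_map(D_c, ph$ground_truth)
  roi <- matrix(1L, nrow(D_s$values), ncol(D_s$values))
  B <- segment_cnv(D_s, radial_band(180, Inf), roi)
  cnv_pixels <- apply(ph$band_labels == 1L, c(1, 2), any)
  expect_equal(B == 1L, cnv_pixels)
})

test_that("corrected area approaches the analytic hemisphere area", {
  sp <- sphere_params(1000, 1000, 2000, 800)
  m <- analytic_sphere_maps(sp, 400, 5)   # 5 um pixels over a 2 mm disk
  C <- cosine_map(m$D_c, m$D_s, sp)
  B <- matrix(1L, 400, 400)
  px_mm2 <- 5 * 5 * 1e-6
  res <- cnv_area(B, C, px_mm2, c_floor = 0)
  hemi <- 2 * pi * (0.8)^2   # mm^2
  expect_equal(res$area, hemi, tolerance = 0.03)
  # projected disk area is pi r^2: the correction enlarges it
  expect_gt(res$area, pi * 0.8^2)
  expect_gte(res$area, res$n_pixels * px_mm2)
})

test_that("corrected area of a spherical cap matches the closed form", {
  sp <- sphere_params(1000, 1000, 2000, 800)
  m <- analytic_sphere_maps(sp, 400, 5)
  C <- cosine_map(m$D_c, m$D_s, sp)
  px <- (seq_len(400) - 0.5) * 5
  rho <- sqrt(outer((px - 1000)^2, (px - 1000)^2, "+"))
  for (theta in c(pi / 6, pi / 3)) {
    B <- matrix(0L, 400, 400)
    B[rho < sp[["r"]] * sin(theta)] <- 1L
    res <- cnv_area(B, C, 25e-6, c_floor = 0)
    expect_equal(res$area, 2 * pi * 0.8^2 * (1 - cos(theta)),
                 tolerance = 0.03)
  }
})

test_that("flat apex cap area reduces to pixel count times pixel area", {
  sp <- sphere_params(1000, 1000, 2000, 800)
  m <- analytic_sphere_maps(sp, 400, 5)
  C <- cosine_map(m$D_c, m$D_s, sp)
  px <- (seq_len(400) - 0.5) * 5
  rho <- sqrt(outer((px - 1000)^2, (px - 1000)^2, "+"))
  B <- matrix(0L, 400, 400)
  B[rho < 40] <- 1L           # tiny cap: C ~ 1 throughout
  res <- cnv_area(B, C, 25e-6)
  expect_equal(res$area, sum(B) * 25e-6, tolerance = 0.005)
})

test_that("area is additive over disjoint segmentations", {
  sp <- sphere_params(1000, 1000, 2000, 800)
  m <- analytic_sphere_maps(sp, 100, 20)
  C <- cosine_map(m$D_c, m$D_s, sp)
  set.seed(91)
  B_all <- matrix(as.integer(m$inside & runif(10000) < 0.5), 100, 100)
  split <- matrix(rbinom(10000, 1, 0.5), 100, 100)
  B1 <- B_all * split
  B2 <- B_all * (1L - split)
  a <- cnv_area(B_all, C, 4e-4, c_floor = 0)
  a1 <- cnv_area(B1, C, 4e-4, c_floor = 0)
  a2 <- cnv_area(B2, C, 4e-4, c_floor = 0)
  expect_equal(a$area, a1$area + a2$area, tolerance = 1e-12)
  expect_equal(a$n_pixels, a1$n_pixels + a2$n_pixels)
})

test_that("invalid cosines are excluded and counted, never summed", {
  C <- matrix(c(1, 0.5, 0.05, -0.2, NA, 0.8), 2, 3)
  B <- matrix(1L, 2, 3)
  res <- cnv_area(B, C, 1e-4, c_floor = 0.1)
  expect_equal(res$n_pixels, 3)
  expect_equal(res$n_excluded, 3)          # 0.05, -0.2 and NA
  expect_equal(res$area, 1e-4 * (1 / 1 + 1 / 0.5 + 1 / 0.8))
  expect_equal(res$cosine_stats[["min"]], 0.5)
})
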
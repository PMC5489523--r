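# Shared fixtures and independent oracles. All fixtures are generated in
# code; "small" phantoms keep the physical extent of the default stated
# world (3.2 x 3.2 x 2.4 mm) on a coarser 50 um grid so the default initial
# sampling ranges remain valid while tests stay fast.

small_phantom_spec <- function(seed = 1L, noise_sigma = 0.1,
                               outlier_fraction = 0,
                               vessel_bands = list(
                                 list(lo = 0, hi = 80, n_arcs = 10L,
                                      tube_radius = 40),
                                 list(lo = 120, hi = 150, n_arcs = 6L,
                                      tube_radius = 40))) {
  phantom_spec(grid_shape = c(64L, 64L, 48L),
               voxel_spacing = c(50, 50, 50),
               vessel_bands = vessel_bands,
               noise_sigma = noise_sigma,
               outlier_fraction = outlier_fraction,
               seed = seed)
}

# Brute-force matching score: explicit triple loop over every voxel,
# implementing the shell-mask case split and score sum directly.
# Independent of the package's scoring path (no shared code).
brute_score <- function(P, sp, dr_plus, dr_minus) {
  d <- dim(P$data)
  s <- 0L
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        if (P$data[i, j, k] == 1L) {
          dist <- sqrt(((i - 0.5) * P$spacing[1] - sp[["x"]])^2 +
                       ((j - 0.5) * P$spacing[2] - sp[["y"]])^2 +
                       ((k - 0.5) * P$spacing[3] - sp[["z"]])^2)
          if (dist > sp[["r"]] && dist < sp[["r"]] + dr_plus) {
            s <- s + 1L
          } else if (dist < sp[["r"]] && dist > sp[["r"]] - dr_minus) {
            s <- s - 1L
          }
        }
      }
    }
  }
  s
}

# Physical voxel-center coordinates of a grid, as three vectors.
grid_centers <- function(dims, spacing) {
  list(x = (seq_len(dims[1]) - 0.5) * spacing[1],
       y = (seq_len(dims[2]) - 0.5) * spacing[2],
       z = (seq_len(dims[3]) - 0.5) * spacing[3])
}

# Array of voxel-center distances from a point (independent of the
# package's internal helper).
dist_array <- function(dims, spacing, center) {
  g <- grid_centers(dims, spacing)
  sqrt(outer(outer((g$x - center[1])^2, (g$y - center[2])^2, "+"),
             (g$z - center[3])^2, "+"))
}

# Random small binary volume + random sphere for score equivalence checks.
random_score_case <- function(max_dim = 32L) {
  d <- sample(6:max_dim, 3, replace = TRUE)
  sp <- runif(3, 20, 60)
  P <- pa_binary_volume(array(rbinom(prod(d), 1, 0.1), dim = d), sp)
  ext <- d * sp
  sphere <- sphere_params(runif(1, 0, ext[1]), runif(1, 0, ext[2]),
                          runif(1, 0, ext[3]),
                          runif(1, 0.2, 1.2) * mean(ext))
  list(P = P, sphere = sphere,
       dr_plus = runif(1, 50, 300), dr_minus = runif(1, 50, 300))
}

# Dense-point re-rasterization of the phantom's arc geometry (single-band
# specs): marks every voxel within tube_radius of a sampled arc point and
# inside the band's radial extent. Serves as the geometric occupancy oracle.
rasterize_arcs_oracle <- function(phantom, spec) {
  stopifnot(length(spec$vessel_bands) == 1L)
  d <- spec$grid_shape
  sp <- spec$voxel_spacing
  gt <- phantom$ground_truth
  ctr <- c(gt[["x"]], gt[["y"]], gt[["z"]])
  g <- grid_centers(d, sp)
  radial <- dist_array(d, sp, ctr)
  marked <- array(FALSE, dim = d)
  for (arc in phantom$arcs) {
    b <- spec$vessel_bands[[arc$band]]
    nrm <- arc$normal
    u <- c(-nrm[2], nrm[1], 0)
    if (sqrt(sum(u^2)) < 1e-8) u <- c(1, 0, 0)
    u <- u - sum(u * nrm) * nrm
    u <- u / sqrt(sum(u^2))
    v <- c(nrm[2] * u[3] - nrm[3] * u[2],
           nrm[3] * u[1] - nrm[1] * u[3],
           nrm[1] * u[2] - nrm[2] * u[1])
    step <- min(sp) / (4 * arc$radius)        # point spacing << voxel
    ts <- seq(-arc$extent / 2, arc$extent / 2, by = step)
    pts <- ctr + arc$radius * (outer(u, cos(ts)) + outer(v, sin(ts)))
    for (q in seq_len(ncol(pts))) {
      p <- pts[, q]
      ii <- which(abs(g$x - p[1]) <= arc$tube_radius)
      jj <- which(abs(g$y - p[2]) <= arc$tube_radius)
      kk <- which(abs(g$z - p[3]) <= arc$tube_radius)
      if (!length(ii) || !length(jj) || !length(kk)) next
      dd <- outer(outer((g$x[ii] - p[1])^2, (g$y[jj] - p[2])^2, "+"),
                  (g$z[kk] - p[3])^2, "+")
      hit <- which(dd <= arc$tube_radius^2, arr.ind = TRUE)
      if (nrow(hit)) {
        marked[cbind(ii[hit[, 1]], jj[hit[, 2]], kk[hit[, 3]])] <- TRUE
      }
    }
  }
  # clip the tube to the band's radial extent, as the generator does
  b <- spec$vessel_bands[[1]]
  marked & radial >= gt[["r"]] + b$lo & radial <= gt[["r"]] + b$hi
}
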
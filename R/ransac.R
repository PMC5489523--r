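#' Sphere parameters (eyeball center and half-diameter)
#'
#' @param x,y,z center coordinates, um, in the physical frame
#'   (voxel index times spacing, origin at the volume corner).
#' @param r half-diameter (radius), um; must be > 0.
#' @return An object of class `sphere_params` (named numeric of length 4).
#' @export
sphere_params <- function(x, y, z, r) {
  v <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         r = as.numeric(r))
  if (anyNA(v) || !all(is.finite(v))) stop("sphere parameters must be finite")
  if (v[["r"]] <= 0) stop("half-diameter `r` must be positive")
  structure(v, class = "sphere_params")
}

#' @export
print.sphere_params <- function(x, ...) {
  cat(sprintf("<sphere_params> center (%.1f, %.1f, %.1f) um, half-diameter %.1f um\n",
              x[["x"]], x[["y"]], x[["z"]], x[["r"]]))
  invisible(x)
}

#' Uniform sampling box for the RANSAC search
#'
#' Each of the four parameters is drawn uniformly on
#' `[center - half_width, center + half_width]`.
#'
#' @param centers named or positional numeric length-4 `(c_x, c_y, c_z, c_r)`,
#'   um.
#' @param half_widths numeric length-4 `(d_x, d_y, d_z, d_r)`, um, all >= 0.
#' @return An object of class `sampling_ranges`.
#' @export
sampling_ranges <- function(centers, half_widths) {
  centers <- as.numeric(centers); half_widths <- as.numeric(half_widths)
  if (length(centers) != 4L || length(half_widths) != 4L)
    stop("centers and half_widths must each have length 4 (x, y, z, r)")
  if (any(half_widths < 0)) stop("half_widths must be >= 0")
  structure(list(centers = stats::setNames(centers, c("x", "y", "z", "r")),
                 half_widths = stats::setNames(half_widths,
                                               c("x", "y", "z", "r"))),
            class = "sampling_ranges")
}

#' Default initial sampling ranges
#'
#' The lateral centers default to half the imaged extent (the eye is imaged
#' at the image center); the axial center to 2300 um (typical eye position
#' given the system's focal depth) and the half-diameter center to 1700 um
#' (typical mouse eye). Half-widths default to (500, 500, 500, 250) um.
#'
#' @param P a [pa_binary_volume()] or [pa_volume()] fixing the lateral extent.
#' @param c_z,c_r,half_widths overrides, um.
#' @return A [sampling_ranges()].
#' @export
initial_ranges <- function(P, c_z = 2300, c_r = 1700,
                           half_widths = c(500, 500, 500, 250)) {
  d <- dim(P$data)
  sampling_ranges(c(d[1] * P$spacing[1] / 2, d[2] * P$spacing[2] / 2,
                    c_z, c_r),
                  half_widths)
}

#' RANSAC matching configuration
#'
#' Defaults follow the published procedure: 4000 parameter sets per repeat,
#' top 5 retained, positive/negative zone thicknesses 150 um, range-renewal
#' scaling gamma = 2 with minimum-range constant b = 25 um (0.025 mm), and
#' termination once the best set is maintained for 3 repeats.
#'
#' @param n_sets parameter sets sampled per repeat.
#' @param k_top retained best sets used to renew the ranges.
#' @param dr_plus,dr_minus positive/negative zone thicknesses, um.
#' @param gamma scaling factor on the top-k standard deviation.
#' @param b minimum-range constant, um.
#' @param stability_repeats consecutive repeats the incumbent must persist.
#' @param max_repeats safety cap; hitting it flags non-convergence.
#' @param seed optional RNG seed for reproducible estimation.
#' @return An object of class `match_config`.
#' @export
match_config <- function(n_sets = 4000L, k_top = 5L,
                         dr_plus = 150, dr_minus = 150,
                         gamma = 2, b = 25,
                         stability_repeats = 3L, max_repeats = 50L,
                         seed = NULL) {
  n_sets <- as.integer(n_sets); k_top <- as.integer(k_top)
  if (n_sets < k_top || k_top < 1L) stop("need n_sets >= k_top >= 1")
  if (dr_plus <= 0 || dr_minus <= 0) stop("zone thicknesses must be positive")
  if (gamma < 0 || b < 0) stop("gamma and b must be nonnegative")
  if (gamma == 0 && b == 0) stop("gamma and b cannot both be zero")
  structure(list(n_sets = n_sets, k_top = k_top, dr_plus = dr_plus,
                 dr_minus = dr_minus, gamma = gamma, b = b,
                 stability_repeats = as.integer(stability_repeats),
                 max_repeats = as.integer(max_repeats), seed = seed),
            class = "match_config")
}

#' Draw candidate sphere parameter sets (Step 2)
#'
#' Each coordinate of each set is drawn independently and uniformly on
#' `[center - half_width, center + half_width]`.
#'
#' @param ranges a [sampling_ranges()].
#' @param n_sets number of sets to draw.
#' @param seed optional seed; the caller's RNG state is restored afterwards.
#' @return numeric matrix `n_sets x 4` with columns x, y, z, r (um).
#' @export
sample_parameters <- function(ranges, n_sets, seed = NULL) {
  stopifnot(inherits(ranges, "sampling_ranges"))
  with_seed(seed, {
    m <- vapply(1:4, function(i) {
      stats::runif(n_sets, ranges$centers[i] - ranges$half_widths[i],
                   ranges$centers[i] + ranges$half_widths[i])
    }, numeric(n_sets))
    if (n_sets == 1L) m <- matrix(m, nrow = 1L)
    colnames(m) <- c("x", "y", "z", "r")
    m
  })
}

#' Matching score of candidate spheres (Steps 3, Eqs. of the shell mask)
#'
#' Scores one or many candidate spheres against the binary volume: each
#' foreground voxel contributes +1 when its center-to-center distance from
#' the candidate center lies strictly inside the positive zone
#' `(r, r + dr_plus)`, -1 strictly inside the negative zone
#' `(r - dr_minus, r)`, and 0 otherwise (including exactly on a boundary).
#' Distances are Euclidean in physical um from voxel centers.
#'
#' @param P a [pa_binary_volume()].
#' @param params a [sphere_params()] or an `n x 4` matrix of candidates.
#' @param dr_plus,dr_minus zone thicknesses, um.
#' @return integer score (single candidate) or integer vector (matrix input).
#' @export
match_score <- function(P, params, dr_plus = 150, dr_minus = 150) {
  stopifnot(inherits(P, "pa_binary_volume"))
  pts <- ones_coords(P)
  single <- inherits(params, "sphere_params") ||
    (is.numeric(params) && is.null(dim(params)))
  pm <- if (single) matrix(unclass(params), nrow = 1L) else as.matrix(params)
  if (ncol(pm) != 4L) stop("candidate parameters must have 4 columns")
  if (nrow(pts) == 0L)
    return(if (single) 0L else integer(nrow(pm)))
  s <- score_spheres_cpp(pts, pm, dr_plus, dr_minus)
  if (single) s[1L] else s
}

#' Extract the k best-scoring parameter sets (Step 3)
#'
#' Ties are broken by earliest sampling index, making the selection
#' deterministic.
#'
#' @param params `n x 4` candidate matrix.
#' @param scores integer scores, one per row of `params`.
#' @param k number of sets to keep; `k <= n`.
#' @return list with `params` (`k x 4` matrix, best first) and `scores`.
#' @export
top_k <- function(params, scores, k) {
  n <- nrow(params)
  if (length(scores) != n) stop("one score per parameter set required")
  if (k > n) stop("k exceeds the number of candidates")
  ord <- order(-scores, seq_len(n))[seq_len(k)]
  list(params = params[ord, , drop = FALSE], scores = scores[ord])
}

#' Renew the sampling ranges from the retained top sets (Step 4)
#'
#' Per coordinate, the new center is the mean of the retained values and the
#' new half-width is `gamma * std + b`, where `std` is the population
#' standard deviation (divide by k) of the retained values.
#'
#' @param top `k x 4` matrix of retained parameter sets.
#' @param gamma scaling factor.
#' @param b minimum-range constant, um.
#' @return A [sampling_ranges()].
#' @export
renew_ranges <- function(top, gamma = 2, b = 25) {
  top <- as.matrix(top)
  if (nrow(top) < 1L || ncol(top) != 4L) stop("need a k x 4 matrix, k >= 1")
  ctr <- colMeans(top)
  sds <- apply(top, 2, pop_sd)
  sampling_ranges(ctr, gamma * sds + b)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Estimate the eye surface by iterative RANSAC (Steps 2--5)
#'
#' Repeats sample -> score -> top-k -> range renewal. The best-ever candidate
#' (incumbent) is carried across repeats and entered into each repeat's
#' candidate pool ahead of the fresh draws, so its score never decreases and
#' the tie rule favours it. The loop terminates once the incumbent is
#' maintained (ranked first) for `stability_repeats` consecutive repeats, or
#' at `max_repeats` with `converged = FALSE`.
#'
#' @param P a [pa_binary_volume()] with at least one foreground voxel.
#' @param initial initial [sampling_ranges()]; defaults to [initial_ranges()].
#' @param cfg a [match_config()].
#' @return An object of class `surface_estimate`: fields `best`
#'   ([sphere_params()]), `score`, `repeats_used`, `converged`, `history`
#'   (data.frame of per-repeat top-k sets and scores) and `ranges_history`.
#' @export
estimate_surface <- function(P, initial = initial_ranges(P),
                             cfg = match_config()) {
  stopifnot(inherits(P, "pa_binary_volume"), inherits(cfg, "match_config"))
  pts <- ones_coords(P)
  if (nrow(pts) == 0L) stop("binary volume has no foreground voxels")
  with_seed(cfg$seed, {
    ranges <- initial
    incumbent <- NULL
    incumbent_score <- -Inf
    streak <- 0L
    hist <- vector("list", cfg$max_repeats)
    ranges_hist <- vector("list", cfg$max_repeats)
    repeats <- 0L
    converged <- FALSE
    while (repeats < cfg$max_repeats) {
      repeats <- repeats + 1L
      ranges_hist[[repeats]] <- ranges
      fresh <- sample_parameters(ranges, cfg$n_sets)
      pool <- if (is.null(incumbent)) fresh else rbind(incumbent, fresh)
      scores <- score_spheres_cpp(pts, pool, cfg$dr_plus, cfg$dr_minus)
      tk <- top_k(pool, scores, cfg$k_top)
      new_best <- tk$params[1L, ]
      maintained <- !is.null(incumbent) && all(new_best == incumbent)
      streak <- if (maintained) streak + 1L else 0L
      incumbent <- new_best
      incumbent_score <- tk$scores[1L]
      hist[[repeats]] <- data.frame(repeat_index = repeats,
                                    rank = seq_len(cfg$k_top),
                                    x = tk$params[, 1], y = tk$params[, 2],
                                    z = tk$params[, 3], r = tk$params[, 4],
                                    score = tk$scores)
      if (streak >= cfg$stability_repeats) {
        converged <- TRUE
        break
      }
      ranges <- renew_ranges(tk$params, cfg$gamma, cfg$b)
    }
    structure(list(
      best = sphere_params(incumbent[1], incumbent[2], incumbent[3],
                           incumbent[4]),
      score = as.integer(incumbent_score),
      repeats_used = repeats,
      converged = converged,
      history = do.call(rbind, hist[seq_len(repeats)]),
      ranges_history = ranges_hist[seq_len(repeats)]
    ), class = "surface_estimate")
  })
}

#' @export
print.surface_estimate <- function(x, ...) {
  cat(sprintf(
    "<surface_estimate> center (%.2f, %.2f, %.2f) um, half-diameter %.2f um\n",
    x$best[["x"]], x$best[["y"]], x$best[["z"]], x$best[["r"]]))
  cat(sprintf("  score %d after %d repeats (%s)\n", x$score, x$repeats_used,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
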
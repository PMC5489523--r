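# RANSAC core: sampling, shell-mask scoring, top-k, range renewal and the
# iterative estimator.

test_that("sample_parameters draws uniformly inside the box", {
  rg <- sampling_ranges(c(1600, 1600, 2300, 1700), c(0, 0, 0, 0))
  m <- sample_parameters(rg, 10, seed = 1)
  expect_true(all(m == matrix(c(1600, 1600, 2300, 1700), 10, 4,
                              byrow = TRUE)))

  rg2 <- sampling_ranges(c(1600, 1600, 2300, 1700), c(500, 500, 500, 250))
  m2 <- sample_parameters(rg2, 4000, seed = 2)
  expect_equal(dim(m2), c(4000L, 4L))
  for (i in 1:4)
    expect_true(all(abs(m2[, i] - rg2$centers[i]) <= rg2$half_widths[i]))

  # coverage: 1e5 draws with half-width 500 um span >= 95% of the interval
  big <- sample_parameters(rg2, 1e5, seed = 3)
  for (i in 1:4) {
    span <- diff(range(big[, i]))
    expect_gte(span, 0.95 * 2 * rg2$half_widths[i])
  }

  # reproducible under seed
  expect_identical(sample_parameters(rg2, 100, seed = 9),
                   sample_parameters(rg2, 100, seed = 9))
})

test_that("match_score implements the shell-mask case split", {
  empty <- pa_binary_volume(array(0L, c(8, 8, 8)), c(50, 50, 50))
  sp <- sphere_params(200, 200, 200, 150)
  expect_identical(match_score(empty, sp), 0L)

  # one voxel at a controlled distance from the center: put the center on
  # the voxel-center axis so the distance is exact
  place_one <- function(dist) {
    P <- array(0L, c(64, 8, 8))
    P[1, 1, 1] <- 1L   # center at (12.5, 12.5, 12.5) for spacing 25
    pa_binary_volume(P, c(25, 25, 25))
  }
  P1 <- place_one()
  score_at <- function(r, offset)
    match_score(P1, sphere_params(12.5 + r + offset, 12.5, 12.5, r),
                dr_plus = 150, dr_minus = 150)
  expect_identical(score_at(400, 75), 1L)    # r + 75: positive zone
  expect_identical(score_at(400, -75), -1L)  # r - 75: negative zone
  expect_identical(score_at(400, 200), 0L)   # beyond r + 150
  expect_identical(score_at(400, 0), 0L)     # exactly on the surface
})

test_that("match_score equals the brute-force oracle on random cases", {
  set.seed(31)
  for (case in 1:10) {
    cs <- random_score_case(max_dim = 16L)
    expect_identical(
      match_score(cs$P, cs$sphere, cs$dr_plus, cs$dr_minus),
      brute_score(cs$P, cs$sphere, cs$dr_plus, cs$dr_minus))
  }
})

test_that("batch scoring equals single-sphere scoring", {
  set.seed(32)
  cs <- random_score_case(max_dim = 12L)
  params <- sample_parameters(
    sampling_ranges(c(300, 300, 300, 400), c(200, 200, 200, 200)), 20,
    seed = 5)
  batch <- match_score(cs$P, params, 150, 150)
  singles <- vapply(seq_len(nrow(params)), function(i)
    match_score(cs$P, sphere_params(params[i, 1], params[i, 2],
                                    params[i, 3], params[i, 4]), 150, 150),
    integer(1))
  expect_identical(batch, singles)
})

test_that("score is antisymmetric under zone swap + surface reflection", {
  P <- array(0L, c(64, 8, 8))
  P[1, 1, 1] <- 1L
  Pb <- pa_binary_volume(P, c(25, 25, 25))
  for (delta in c(30, 75, 140)) {
    outside <- sphere_params(12.5 + 400 + delta, 12.5, 12.5, 400)
    inside <- sphere_params(12.5 + 400 - delta, 12.5, 12.5, 400)
    s_out <- match_score(Pb, outside, dr_plus = 150, dr_minus = 100)
    s_in <- match_score(Pb, inside, dr_plus = 100, dr_minus = 150)
    expect_identical(s_out, -s_in)
  }
})

test_that("widening the positive zone never lowers an all-positive score", {
  set.seed(33)
  d <- c(16, 16, 16); spc <- c(40, 40, 40)
  sp <- sphere_params(320, 320, 320, 150)
  dist <- dist_array(d, spc, c(320, 320, 320))
  # foreground strictly outside the sphere only
  P <- pa_binary_volume(array(as.integer(dist > 160 & runif(prod(d)) < 0.3),
                              dim = d), spc)
  prev <- -Inf
  for (drp in c(50, 100, 200, 400)) {
    s <- match_score(P, sp, dr_plus = drp, dr_minus = 50)
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("top_k keeps the highest scores with first-index tie-breaking", {
  params <- matrix(seq_len(40), 10, 4)
  same <- rep(5L, 10)
  tk <- top_k(params, same, 3)
  expect_identical(tk$params, params[1:3, ])

  set.seed(41)
  sc <- sample.int(50, 100, replace = TRUE)
  pm <- matrix(rnorm(400), 100, 4)
  tk5 <- top_k(pm, sc, 5)
  ord <- order(-sc, seq_along(sc))[1:5]   # sort-then-slice oracle
  expect_identical(tk5$params, pm[ord, ])
  expect_identical(tk5$scores, sc[ord])

  expect_identical(top_k(pm, sc, 1)$scores, max(sc))
  expect_error(top_k(pm, sc, 101), "exceeds")
})

test_that("renew_ranges centers on the mean with gamma*std + b half-width", {
  five <- matrix(rep(c(1000, 2000, 3000, 400), each = 5), 5, 4)
  rg <- renew_ranges(five, gamma = 2, b = 25)
  expect_equal(unname(rg$centers), c(1000, 2000, 3000, 400))
  expect_equal(unname(rg$half_widths), rep(25, 4))

  spread <- matrix(c(1000, 1100, 1200, 1300, 1400), 5, 4)
  rg0 <- renew_ranges(spread, gamma = 0, b = 25)
  expect_equal(unname(rg0$half_widths), rep(25, 4))

  # closed form with population std: sqrt(mean((x - 1200)^2)) = sqrt(20000)
  rg2 <- renew_ranges(spread, gamma = 2, b = 25)
  expect_equal(unname(rg2$centers), rep(1200, 4))
  expect_equal(unname(rg2$half_widths), rep(2 * sqrt(20000) + 25, 4))
})

test_that("estimate_surface recovers a noiseless phantom sphere", {
  for (seed in c(1, 2)) {
    spec <- small_phantom_spec(seed = seed, noise_sigma = 0)
    ph <- generate_phantom(spec)
    P <- binarize(ph$volume, threshold_rule("absolute", 0.5))
    est <- estimate_surface(P, cfg = match_config(seed = seed))
    expect_true(est$converged)
    err <- abs(unclass(est$best) - unclass(ph$ground_truth))
    expect_true(all(err <= 2 * spec$voxel_spacing[1]))
    # contract: reported score is reproducible on the same volume
    expect_identical(est$score, match_score(P, est$best, 150, 150))
    # incumbent retention: best score never decreases across repeats
    best_per_repeat <- tapply(est$history$score, est$history$repeat_index,
                              max)
    expect_true(all(diff(best_per_repeat) >= 0))
    # sampling boxes shrink once the renewal width drops below the initial
    widths <- vapply(est$ranges_history, function(r) max(r$half_widths),
                     numeric(1))
    expect_lt(widths[length(widths)], widths[1])
  }
})

test_that("a pure positive-zone volume attains ~the analytic maximum", {
  d <- c(48, 48, 36); spc <- c(60, 60, 60)
  sp <- sphere_params(1450, 1700, 2400, 1750)
  dist <- dist_array(d, spc, c(1450, 1700, 2400))
  P <- pa_binary_volume(array(as.integer(dist > 1750 & dist < 1900),
                              dim = d), spc)
  n_ones <- sum(P$data)
  est <- estimate_surface(P, cfg = match_config(seed = 4))
  # the analytic maximum is the count of 1-voxels; with the published
  # sampling constants (b = 25 um minimum box) the stochastic polish
  # reliably reaches ~98-99% of it, not 99%+ (see decisions ledger)
  expect_gte(est$score, 0.97 * n_ones)
  expect_lte(est$score, n_ones)
})

test_that("estimate_surface flags non-convergence and rejects empty input", {
  spec <- small_phantom_spec(seed = 6, noise_sigma = 0)
  ph <- generate_phantom(spec)
  P <- binarize(ph$volume, threshold_rule("absolute", 0.5))
  est <- estimate_surface(P, cfg = match_config(seed = 1, max_repeats = 2))
  expect_false(est$converged)
  expect_equal(est$repeats_used, 2L)

  empty <- pa_binary_volume(array(0L, c(4, 4, 4)), c(50, 50, 50))
  expect_error(estimate_surface(empty), "no foreground")
})

test_that("RANSAC stays within 2 voxels under 20% outlier clutter", {
  spec <- small_phantom_spec(seed = 17, noise_sigma = 0,
                             outlier_fraction = 0.2)
  ph <- generate_phantom(spec)
  P <- binarize(ph$volume, threshold_rule("absolute", 0.5))
  est <- estimate_surface(P, cfg = match_config(seed = 17))
  err <- abs(unclass(est$best) - unclass(ph$ground_truth))
  expect_true(all(err <= 2 * spec$voxel_spacing[1]))
})

test_that("configuration invariants are enforced", {
  expect_error(match_config(n_sets = 3, k_top = 5), "n_sets >= k_top")
  expect_error(match_config(dr_plus = 0), "positive")
  expect_error(sampling_ranges(c(1, 2, 3, 4), c(-1, 0, 0, 0)), ">= 0")
  expect_error(sphere_params(0, 0, 0, -5), "positive")
})
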
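#' Zero-phase band-pass filter along the depth axis
#'
#' Applies a per-A-line zero-phase band-pass to raw RF data, centered on the
#' ultrasound transducer frequency. The filter is realised in the frequency
#' domain as the magnitude response of a Butterworth band-pass (the product of
#' an order-`order` low-pass at `f_center + bandwidth/2` and high-pass at
#' `f_center - bandwidth/2`); a purely real transfer function, so the filter
#' introduces no phase shift and no depth bias in the subsequent depth maps.
#' DC is removed exactly.
#'
#' @param volume a [pa_volume()] carrying `sampling_rate` (MHz).
#' @param f_center passband center frequency, MHz. Default 50 (transducer
#'   center frequency).
#' @param bandwidth full passband width, MHz. Default 50 (transducer
#'   bandwidth), i.e. passband 25--75 MHz.
#' @param order Butterworth order of each edge. Default 4.
#' @return A filtered [pa_volume()].
#' @export
bandpass <- function(volume, f_center = 50, bandwidth = 50, order = 4L) {
  stopifnot(inherits(volume, "pa_volume"))
  fs <- volume$sampling_rate
  if (is.null(fs))
    stop("band-pass filtering raw RF data requires `sampling_rate` metadata")
  f_lo <- f_center - bandwidth / 2
  f_hi <- f_center + bandwidth / 2
  if (f_lo <= 0 || f_hi >= fs / 2)
    stop(sprintf("passband (%g, %g) MHz must lie inside (0, Nyquist = %g) MHz",
                 f_lo, f_hi, fs / 2))
  d <- dim(volume$data)
  nz <- d[3]
  m <- matrix(volume$data, nrow = prod(d[1:2]), ncol = nz)
  # absolute FFT bin frequencies, folded about Nyquist
  k <- 0:(nz - 1)
  f <- pmin(k, nz - k) * fs / nz
  g <- butterworth_bandpass_gain(f, f_lo, f_hi, order)
  ft <- stats::mvfft(t(m))
  out <- Re(stats::mvfft(ft * g, inverse = TRUE)) / nz
  pa_volume(array(t(out), dim = d), volume$spacing, sampling_rate = fs)
}

# Magnitude response of the zero-phase Butterworth band-pass at frequencies f
# (all in MHz). Exported so the frequency response can be inspected directly.
#' Band-pass gain of the preprocessing filter
#'
#' The designed frequency response of [bandpass()] evaluated at frequencies
#' `f` (MHz): Butterworth low-pass x high-pass magnitudes. `f = 0` maps to
#' gain 0 (DC removal).
#' @param f frequencies, MHz (vector).
#' @param f_lo,f_hi band edges, MHz.
#' @param order Butterworth order.
#' @return gains in `[0, 1]`.
#' @export
butterworth_bandpass_gain <- function(f, f_lo, f_hi, order = 4L) {
  g <- numeric(length(f))
  nz <- f > 0
  g[nz] <- 1 / sqrt(1 + (f[nz] / f_hi)^(2 * order)) /
    sqrt(1 + (f_lo / f[nz])^(2 * order))
  g
}

#' Hilbert envelope along the depth axis
#'
#' Per-A-line magnitude of the analytic signal (Hilbert transform), yielding
#' the nonnegative amplitude envelope of the RF trace.
#'
#' @param volume a [pa_volume()].
#' @return A [pa_volume()] of nonnegative envelope amplitudes.
#' @export
envelope <- function(volume) {
  stopifnot(inherits(volume, "pa_volume"))
  d <- dim(volume$data)
  nz <- d[3]
  m <- t(matrix(volume$data, nrow = prod(d[1:2]), ncol = nz))
  h <- analytic_weights(nz)
  ft <- stats::mvfft(m) * h
  env <- Mod(stats::mvfft(ft, inverse = TRUE)) / nz
  pa_volume(array(t(env), dim = d), volume$spacing,
            sampling_rate = volume$sampling_rate)
}

# FFT weights producing the analytic signal (positive frequencies doubled).
analytic_weights <- function(n) {
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

#' Downsize a volume by per-axis block maxima
#'
#' Reduces each axis by an integer factor, taking the block maximum
#' (max-pooling). The maximum, rather than the mean, preserves thin bright
#' vessels. Trailing voxels that do not fill a complete block are truncated.
#' Spacing is multiplied by the factors so physical coordinates are preserved.
#'
#' @param volume a [pa_volume()].
#' @param factors integer length-3 reduction factors, each >= 1.
#' @return The downsized [pa_volume()].
#' @export
downsample <- function(volume, factors) {
  stopifnot(inherits(volume, "pa_volume"))
  factors <- as.integer(factors)
  if (length(factors) != 3L || any(is.na(factors)) || any(factors < 1L))
    stop("`factors` must be three integers >= 1")
  dat <- volume$data
  for (ax in 1:3) {
    f <- factors[ax]
    if (f == 1L) next
    n_out <- dim(dat)[ax] %/% f
    if (n_out < 1L) stop("downsampling factor exceeds axis length")
    keep <- seq_len(n_out * f)
    dat <- index_axis(dat, ax, keep)
    out <- index_axis(dat, ax, seq(1L, by = f, length.out = n_out))
    for (off in seq_len(f - 1L)) {
      out <- pmax(out, index_axis(dat, ax, seq(1L + off, by = f,
                                               length.out = n_out)))
    }
    dat <- out
  }
  pa_volume(dat, volume$spacing * factors, sampling_rate = NULL)
}

# Subset a 3D array along one axis, keeping dimensions.
index_axis <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Threshold rules for binarization and background masking
#'
#' Three rules are supported: `"fraction_of_max"` (threshold =
#' `value * max(data)`, the default with `value = 0.25`), `"absolute"`
#' (threshold = `value`), and `"otsu"` (between-class variance maximisation
#' over a 256-bin histogram; `value` ignored).
#'
#' @param method one of `"fraction_of_max"`, `"absolute"`, `"otsu"`.
#' @param value rule parameter (fraction in `[0, 1]` or absolute amplitude).
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(method = c("fraction_of_max", "absolute", "otsu"),
                           value = 0.25) {
  method <- match.arg(method)
  if (method == "fraction_of_max" && (value < 0 || value > 1))
    stop("fraction-of-max `value` must be in [0, 1]")
  structure(list(method = method, value = value), class = "threshold_rule")
}

# Resolve a threshold_rule to a numeric threshold for the given data.
compute_threshold <- function(rule, data) {
  stopifnot(inherits(rule, "threshold_rule"))
  switch(rule$method,
         fraction_of_max = rule$value * max(data),
         absolute = rule$value,
         otsu = otsu_threshold(data))
}

# Otsu's method on a 256-bin histogram; returns the amplitude threshold.
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Binarize an enveloped volume into the occupancy field P(x, y, z)
#'
#' Voxels with amplitude strictly above the threshold become 1 (vessel),
#' the rest 0 (background).
#'
#' @param volume an enveloped (nonnegative) [pa_volume()].
#' @param rule a [threshold_rule()]. Default: fraction 0.25 of the volume
#'   maximum.
#' @return A [pa_binary_volume()].
#' @export
binarize <- function(volume, rule = threshold_rule()) {
  stopifnot(inherits(volume, "pa_volume"))
  thr <- compute_threshold(rule, volume$data)
  if (rule$method == "fraction_of_max" && max(volume$data) == 0)
    warning("all-zero volume under a relative threshold rule: empty mask")
  pa_binary_volume(volume$data > thr, volume$spacing)
}

#' Full preprocessing chain (Step 1)
#'
#' Band-pass (RF input only), Hilbert envelope, block-max downsizing and
#' binarization, producing the binary field scored by [estimate_surface()].
#'
#' @param volume input [pa_volume()]; raw RF if `rf = TRUE`, pre-enveloped
#'   amplitude otherwise.
#' @param rf whether the input is raw RF needing band-pass + envelope.
#' @param f_center,bandwidth,order band-pass parameters (see [bandpass()]).
#' @param factors downsampling factors (see [downsample()]).
#' @param rule binarization [threshold_rule()].
#' @return list with elements `enveloped` ([pa_volume()], full resolution),
#'   `downsized` ([pa_volume()]) and `binary` ([pa_binary_volume()]).
#' @export
preprocess_volume <- function(volume, rf = FALSE,
                              f_center = 50, bandwidth = 50, order = 4L,
                              factors = c(1L, 1L, 1L),
                              rule = threshold_rule()) {
  env <- if (rf) envelope(bandpass(volume, f_center, bandwidth, order))
         else volume
  if (any(env$data < 0))
    stop("binarization input must be an enveloped (nonnegative) volume")
  ds <- downsample(env, factors)
  list(enveloped = env, downsized = ds, binary = binarize(ds, rule))
}
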
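#' Write a volume as raw binary plus JSON sidecar
#'
#' The data file holds the array in column-major order (x fastest, z slowest)
#' as IEEE floats; the sidecar records shape, dtype, endianness, voxel
#' spacing and (when present) the sampling rate, so the pair round-trips
#' bit-exactly through [read_volume()].
#'
#' @param volume a [pa_volume()] or [pa_binary_volume()].
#' @param prefix output path prefix; writes `<prefix>.raw` and
#'   `<prefix>.json`.
#' @param dtype `"float64"` (default, lossless) or `"float32"`.
#' @param endian `"little"` (default) or `"big"`.
#' @return `prefix`, invisibly.
#' @export
write_volume <- function(volume, prefix, dtype = c("float64", "float32"),
                         endian = c("little", "big")) {
  dtype <- match.arg(dtype); endian <- match.arg(endian)
  binary <- inherits(volume, "pa_binary_volume")
  if (!binary) stopifnot(inherits(volume, "pa_volume"))
  size <- if (dtype == "float64") 8L else 4L
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume$data), con, size = size, endian = endian)
  meta <- list(shape = dim(volume$data), dtype = dtype, endianness = endian,
               spacing_um = volume$spacing,
               binary = binary)
  if (!binary && !is.null(volume$sampling_rate))
    meta$sampling_rate_mhz <- volume$sampling_rate
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a volume from raw binary plus JSON sidecar
#'
#' @param prefix path prefix as written by [write_volume()], or explicit
#'   paths via `raw_path`/`sidecar_path`.
#' @param raw_path,sidecar_path explicit file paths (override `prefix`).
#' @return a [pa_volume()] or [pa_binary_volume()] per the sidecar's
#'   `binary` flag.
#' @export
read_volume <- function(prefix = NULL, raw_path = NULL, sidecar_path = NULL) {
  if (is.null(raw_path)) raw_path <- paste0(prefix, ".raw")
  if (is.null(sidecar_path)) sidecar_path <- paste0(prefix, ".json")
  if (!file.exists(raw_path)) stop("raw data file not found: ", raw_path)
  if (!file.exists(sidecar_path)) stop("sidecar not found: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("shape", "dtype", "endianness", "spacing_um"))
    if (is.null(meta[[field]]))
      stop("sidecar is missing required field `", field, "`")
  shape <- as.integer(meta$shape)
  if (length(shape) != 3L) stop("sidecar `shape` must have 3 entries")
  size <- switch(meta$dtype, float64 = 8L, float32 = 4L,
                 stop("unsupported dtype: ", meta$dtype))
  n <- prod(shape)
  actual <- file.size(raw_path)
  if (actual != n * size)
    stop(sprintf("raw file holds %d bytes but sidecar declares %d x %d bytes",
                 actual, n, size))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = size,
                  endian = meta$endianness)
  arr <- array(vals, dim = shape)
  if (isTRUE(meta$binary)) {
    pa_binary_volume(arr, meta$spacing_um)
  } else {
    pa_volume(arr, meta$spacing_um,
              sampling_rate = meta$sampling_rate_mhz)
  }
}

#' Write a 2D map (depth map, projection, mask) as raw + JSON sidecar
#'
#' Background/`NA` pixels are stored as IEEE NaN.
#'
#' @param values numeric matrix.
#' @param prefix output path prefix.
#' @param spacing pixel spacing `(dx, dy)` um.
#' @param kind free-text kind recorded in the sidecar.
#' @return `prefix`, invisibly.
#' @export
write_map <- function(values, prefix, spacing, kind = "map") {
  stopifnot(is.matrix(values))
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = 8L, endian = "little")
  jsonlite::write_json(list(shape = dim(values), dtype = "float64",
                            endianness = "little", spacing_um = spacing,
                            kind = kind),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a 2D map written by [write_map()]
#'
#' @param prefix path prefix.
#' @return numeric matrix with attributes `spacing` and `kind`.
#' @export
read_map <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".raw"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(meta$shape), size = 8L,
                  endian = meta$endianness)
  out <- matrix(vals, meta$shape[1], meta$shape[2])
  attr(out, "spacing") <- meta$spacing_um
  attr(out, "kind") <- meta$kind
  out
}

#' Write a phantom (volume, ground truth, labels) to disk
#'
#' Volume and band labels go out as raw + sidecar pairs; the spec and ground
#' truth as one JSON sidecar, so downstream results can be validated against
#' the generating geometry.
#'
#' @param phantom result of [generate_phantom()].
#' @param spec the generating [phantom_spec()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_phantom <- function(phantom, spec, prefix) {
  write_volume(phantom$volume, prefix)
  write_volume(pa_binary_volume(phantom$band_labels > 0L,
                                phantom$volume$spacing),
               paste0(prefix, "_labels"))
  gt <- phantom$ground_truth
  meta <- list(
    ground_truth = list(x = gt[["x"]], y = gt[["y"]], z = gt[["z"]],
                        r = gt[["r"]]),
    spec = list(grid_shape = spec$grid_shape,
                voxel_spacing = spec$voxel_spacing,
                vessel_bands = spec$vessel_bands,
                signal_amplitude = spec$signal_amplitude,
                noise_sigma = spec$noise_sigma,
                outlier_fraction = spec$outlier_fraction,
                sampling_rate = spec$sampling_rate,
                seed = spec$seed))
  jsonlite::write_json(meta, paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
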
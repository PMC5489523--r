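#' Build and validate a pipeline run configuration
#'
#' Assembles the full configuration for [run_pipeline()] and validates it
#' before any computation. Every default matches the published value where
#' one exists (band-pass 25--75 MHz; 4000 sets / top-5 / 150 um zones /
#' gamma 2 / b 25 um / 3-repeat stability; initial ranges per
#' [initial_ranges()]; display range (-50, 150) um; supra-surface band
#' (120, Inf) um; on-surface band (0, 80) um; CNV band (180, Inf) um).
#'
#' @param input path prefix of a raw + JSON-sidecar volume, or `NULL` to
#'   simulate `phantom` instead.
#' @param phantom a [phantom_spec()] used when `input` is `NULL`.
#' @param rf whether the input volume is raw RF (band-pass + envelope run).
#' @param f_center,bandwidth,filter_order band-pass parameters, MHz.
#' @param downsample_factors integer length-3 block-max factors.
#' @param threshold binarization rule: list with `method`, `value`.
#' @param background depth-map background rule: list with `method`, `value`.
#' @param ransac list of [match_config()] overrides.
#' @param initial optional list with `centers`, `half_widths` (um) to
#'   override [initial_ranges()].
#' @param display_range depth-encoding display range `(lo, hi)` um.
#' @param bands named list of isolation bands, each `c(lo, hi)` um offsets.
#'   On-surface projection bands must have `lo >= 0` (reverberation rule).
#' @param cnv list: `enabled`, `band` (`c(lo, hi)`), `roi` (path prefix of a
#'   0/1 map or `NULL` for the whole image), `c_floor`.
#' @param out_dir output directory.
#' @param seed run seed controlling phantom generation and estimation.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(input = NULL, phantom = phantom_spec(),
                       rf = FALSE, f_center = 50, bandwidth = 50,
                       filter_order = 4L,
                       downsample_factors = c(1L, 1L, 1L),
                       threshold = list(method = "fraction_of_max",
                                        value = 0.25),
                       background = list(method = "fraction_of_max",
                                         value = 0.1),
                       ransac = list(),
                       initial = NULL,
                       display_range = c(-50, 150),
                       bands = list(supra_surface = c(120, Inf),
                                    on_surface = c(0, 80)),
                       cnv = list(enabled = FALSE, band = c(180, Inf),
                                  roi = NULL, c_floor = 0.1),
                       out_dir = tempfile("ocusurf_run_"),
                       seed = 1L) {
  if (is.null(input) && is.null(phantom))
    stop("config needs either an `input` volume or a `phantom` spec")
  if (!is.null(input) && !is.character(input))
    stop("`input` must be a path prefix")
  stopifnot(is.list(threshold), !is.null(threshold$method))
  rule <- do.call(threshold_rule, threshold)       # validates
  bg <- do.call(threshold_rule, background)
  cfg_mc <- do.call(match_config, ransac)
  if (length(display_range) != 2L || display_range[1] >= display_range[2])
    stop("display_range must be (lo, hi) with lo < hi")
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || !(b[1] < b[2]))
      stop("band `", nm, "` must be c(lo, hi) with lo < hi")
    if (b[1] < 0)
      stop("band `", nm, "` has lo_offset < 0: sub-surface signal is ",
           "excluded to eliminate reverberation artifacts")
  }
  if (isTRUE(cnv$enabled)) {
    if (length(cnv$band) != 2L || cnv$band[1] < 0)
      stop("cnv band must be c(lo, hi) with lo >= 0")
    if (is.null(cnv$c_floor)) cnv$c_floor <- 0.1
  }
  structure(list(input = input, phantom = phantom, rf = rf,
                 f_center = f_center, bandwidth = bandwidth,
                 filter_order = filter_order,
                 downsample_factors = as.integer(downsample_factors),
                 threshold = rule, background = bg,
                 match_config = cfg_mc, initial = initial,
                 display_range = display_range, bands = bands, cnv = cnv,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full estimation pipeline
#'
#' Preprocess -> RANSAC surface estimation -> depth maps -> band isolation
#' -> (optional) corneal neovascular area, writing every artifact plus a
#' provenance record to `cfg$out_dir`. With a fixed seed the run is
#' end-to-end reproducible: `estimate.json` is byte-identical across runs.
#'
#' @param cfg a [run_config()].
#' @return invisible list of the in-memory results (`phantom`, `binary`,
#'   `estimate`, `D_c`, `D_s`, `projections`, `cnv`), with `$files` naming
#'   the artifacts written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)
  files <- character(0)

  # --- input -------------------------------------------------------------
  phantom <- NULL
  if (!is.null(cfg$input)) {
    vol <- read_volume(cfg$input)
  } else {
    spec <- cfg$phantom
    spec$seed <- cfg$seed
    phantom <- generate_phantom(spec)
    vol <- phantom$volume
    if (!is.null(spec$carrier_freq))
      vol <- modulate_rf(vol, spec$carrier_freq, spec$sampling_rate)
  }

  # --- preprocess (Step 1) ------------------------------------------------
  pp <- preprocess_volume(vol, rf = cfg$rf, f_center = cfg$f_center,
                          bandwidth = cfg$bandwidth,
                          order = cfg$filter_order,
                          factors = cfg$downsample_factors,
                          rule = cfg$threshold)

  # --- estimation (Steps 2-5) ----------------------------------------------
  mc <- cfg$match_config
  mc$seed <- cfg$seed
  init <- if (is.null(cfg$initial)) initial_ranges(pp$binary)
          else sampling_ranges(cfg$initial$centers, cfg$initial$half_widths)
  est <- estimate_surface(pp$binary, init, mc)

  est_json <- list(
    center_um = list(x = est$best[["x"]], y = est$best[["y"]],
                     z = est$best[["z"]]),
    half_diameter_um = est$best[["r"]],
    score = est$score, repeats = est$repeats_used,
    converged = est$converged, seed = cfg$seed,
    config = list(n_sets = mc$n_sets, k_top = mc$k_top,
                  dr_plus = mc$dr_plus, dr_minus = mc$dr_minus,
                  gamma = mc$gamma, b = mc$b,
                  stability_repeats = mc$stability_repeats,
                  initial_centers = unname(init$centers),
                  initial_half_widths = unname(init$half_widths)))
  jsonlite::write_json(est_json, out("estimate.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(est$history, out("history.csv"), row.names = FALSE)
  files <- c(files, out("estimate.json"), out("history.csv"))

  # --- depth maps (Step 6A) -----------------------------------------------
  D_c <- conventional_depth_map(pp$downsized, cfg$background)
  D_s <- surface_depth_map(D_c, est$best)
  write_map(D_c$values, out("depth_conventional"), D_c$spacing,
            "conventional")
  write_map(D_s$values, out("depth_surface_based"), D_s$spacing,
            "surface_based")
  files <- c(files, out("depth_conventional.raw"),
             out("depth_surface_based.raw"))
  if (requireNamespace("png", quietly = TRUE)) {
    write_png_image(render_depth_encoded(D_s,
                                         display_range = cfg$display_range),
                    out("depth_surface_based.png"))
    files <- c(files, out("depth_surface_based.png"))
  }

  # --- isolation (Steps 6B/6C) --------------------------------------------
  projections <- list()
  for (nm in names(cfg$bands)) {
    b <- cfg$bands[[nm]]
    proj <- band_projection(pp$downsized, est$best, radial_band(b[1], b[2]))
    projections[[nm]] <- proj
    write_map(proj, out(paste0("band_", nm)), attr(proj, "spacing"),
              paste0("band_projection_", nm))
    files <- c(files, out(paste0("band_", nm, ".raw")))
  }

  # --- CNV area ------------------------------------------------------------
  cnv_res <- NULL
  if (isTRUE(cfg$cnv$enabled)) {
    roi <- if (is.null(cfg$cnv$roi)) {
      matrix(1L, nrow(D_s$values), ncol(D_s$values))
    } else {
      m <- read_map(cfg$cnv$roi)
      (m != 0) * 1L
    }
    B <- segment_cnv(D_s, radial_band(cfg$cnv$band[1], cfg$cnv$band[2]), roi)
    C <- cosine_map(D_c, D_s, est$best)
    px_mm2 <- prod(D_s$spacing) * 1e-6
    cnv_res <- cnv_area(B, C, px_mm2, c_floor = cfg$cnv$c_floor)
    jsonlite::write_json(list(area_mm2 = cnv_res$area,
                              pixel_area_mm2 = cnv_res$pixel_area,
                              n_pixels = cnv_res$n_pixels,
                              n_excluded = cnv_res$n_excluded),
                         out("cnv_area.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, out("cnv_area.json"))
  }

  # --- provenance -----------------------------------------------------------
  prov <- list(package = "ocusurf",
               version = as.character(utils::packageVersion("ocusurf")),
               seed = cfg$seed,
               input = if (is.null(cfg$input)) "simulated phantom"
                       else cfg$input,
               config = est_json$config,
               downsample_factors = cfg$downsample_factors,
               threshold = unclass(cfg$threshold),
               bands = cfg$bands)
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, out("provenance.json"))

  invisible(list(phantom = phantom, binary = pp$binary, estimate = est,
                 D_c = D_c, D_s = D_s, projections = projections,
                 cnv = cnv_res, files = files))
}
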
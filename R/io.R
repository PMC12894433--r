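# File I/O: 16-bit TIFF fields, truth/record CSVs, calibration and config
# files. All text formats are plain CSV/JSON so runs are auditable.

#' Write a field image as 16-bit TIFF
#'
#' Values are clamped to \[0, 65535\] and rounded.
#'
#' @param image Numeric matrix.
#' @param path Output file.
#' @export
write_field_tiff <- function(image, path) {
  img <- pmin(pmax(round(image), 0), 65535)
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a 16-bit TIFF field
#'
#' @param path TIFF file (single image).
#' @return Numeric matrix of raw counts.
#' @export
read_field_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(img)) img <- img[[1]]
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' Write / read a calibration curve file
#'
#' The file stores the calibration points plus fit settings as JSON; the
#' model is re-fitted on read, so the round trip is exact.
#'
#' @param curve A `calibration_curve`.
#' @param path File path.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  payload <- list(points = curve$points, through_origin = curve$through_origin,
                  ci_level = curve$ci_level, condition = curve$condition,
                  slope = curve$slope, intercept = curve$intercept,
                  r_squared = curve$r_squared, residual_sd = curve$residual_sd)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @return `read_calibration` returns a `calibration_curve`.
#' @export
read_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_calibration(p$points$intensity, p$points$size_bp,
                  through_origin = p$through_origin,
                  ci_level = p$ci_level, condition = p$condition)
}

#' Run configuration
#'
#' Merges user settings over the package defaults and validates the keys.
#' Every run echoes its full configuration into the output directory.
#'
#' @param ... Named settings overriding defaults, or a single named list.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    populations = list(list(size_bp = 2686, fraction = 1 / 3,
                            intensity_cv = 0.05, coloc_rate = 0),
                       list(size_bp = 5562, fraction = 1 / 3,
                            intensity_cv = 0.05, coloc_rate = 0),
                       list(size_bp = 12920, fraction = 1 / 3,
                            intensity_cv = 0.05, coloc_rate = 0)),
    imaging = list(),          # overrides for imaging_config()
    n_fields = 10,
    molecules_per_field = 100,
    seed = 1L,
    qc = list(focus_min = 1e-6, max_saturated = 0.01,
              saturation_level = 65535),
    segmentation = list(window = 31, k = 3, min_area = 4,
                        clear_border = TRUE, close_size = 3, grow = 3),
    denoise_method = "median",
    binwidth = NULL,
    coloc = list(pcc_min = 0.25, p_max = 0.05),
    k_populations = 2,
    condition = "default",
    through_origin = FALSE,
    ci_level = 0.99,
    normalization = "fields",
    min_molecules = 20
  )
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file of settings.
#' @export
read_run_config <- function(path) {
  run_config(jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE))
}

write_config_echo <- function(cfg, out_dir) {
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

config_populations <- function(cfg) {
  lapply(cfg$populations, function(p)
    population_spec(p$size_bp, p$fraction,
                    intensity_cv = if (is.null(p$intensity_cv)) 0.05 else p$intensity_cv,
                    coloc_rate = if (is.null(p$coloc_rate)) 0 else p$coloc_rate))
}

config_imaging <- function(cfg) do.call(imaging_config, cfg$imaging)
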
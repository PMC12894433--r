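#' Quality-control check for one field
#'
#' Automated surrogate for manual inspection: a field passes if it is
#' sufficiently sharp (variance-of-Laplacian focus score, normalised by the
#' squared mean intensity so the score is invariant to exposure) and not
#' saturated. Thresholds default to permissive; an explicit exclude list
#' supports manual overrides.
#'
#' @param image Numeric matrix (channel-1 raster).
#' @param field_id Identifier echoed into the report.
#' @param focus_min Minimum focus score to pass.
#' @param max_saturated Maximum tolerated fraction of saturated pixels.
#' @param saturation_level Pixel value treated as saturated (16-bit default).
#' @param exclude Logical; force-fail this field (manual override).
#' @return A one-row data.frame: `field_id`, `passed`, `focus_score`,
#'   `saturated_fraction`, `artifact_flags` (semicolon-joined).
#' @export
qc_field <- function(image, field_id = NA, focus_min = 1e-6,
                     max_saturated = 0.01, saturation_level = 65535,
                     exclude = FALSE) {
  if (!is.matrix(image) || !is.numeric(image)) stopf("image must be a numeric matrix")
  flags <- character()
  if (any(!is.finite(image))) stopf("image contains non-finite values")
  m <- mean(image)
  if (m <= 0 || stats::var(as.vector(image)) == 0) {
    focus <- 0
    flags <- c(flags, "constant")
  } else {
    lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
    resp <- EBImage::filter2(image, lap, boundary = "replicate")
    focus <- stats::var(as.vector(resp)) / m^2
  }
  sat <- mean(image >= saturation_level)
  if (sat > max_saturated) flags <- c(flags, "saturation")
  if (focus < focus_min) flags <- c(flags, "out_of_focus")
  if (exclude) flags <- c(flags, "manual_exclude")
  data.frame(field_id = field_id, passed = length(flags) == 0,
             focus_score = focus, saturated_fraction = sat,
             artifact_flags = paste(flags, collapse = ";"))
}

#' Estimate the illumination shading field from the data
#'
#' Retrospective shading estimation: the per-pixel median across fields is
#' heavily Gaussian-smoothed (puncta are sparse and diffraction-limited, so
#' the median across fields is dominated by background, and the smoothing
#' removes what little spot signal leaks through). The result is rescaled
#' to mean 1 and floored at a small positive value.
#'
#' @param fields A list of numeric matrices (channel-1 images), all the
#'   same shape, or a single matrix.
#' @param smooth_sigma Gaussian smoothing SD in pixels.
#' @return A numeric matrix of class `shading_field`, strictly positive,
#'   mean 1.
#' @export
estimate_shading <- function(fields, smooth_sigma = 25) {
  if (is.matrix(fields)) fields <- list(fields)
  if (length(fields) == 0) stopf("need at least one field")
  shp <- dim(fields[[1]])
  for (f in fields)
    if (!identical(dim(f), shp)) stopf("all fields must have the same shape")
  if (length(fields) == 1) {
    med <- fields[[1]]
  } else {
    stack <- array(unlist(fields), dim = c(shp, length(fields)))
    med <- apply(stack, c(1, 2), stats::median)
  }
  # the Gaussian kernel (radius 2 * ceiling(3 sigma) + 1) must fit inside
  # the field; clamp the smoothing accordingly for small images
  sigma_max <- max((min(shp) - 3) / 6.5, 0.5)
  sm <- EBImage::gblur(med, sigma = min(smooth_sigma, sigma_max),
                       boundary = "replicate")
  sm <- pmax(EBImage::imageData(sm), 1e-6)
  out <- sm / mean(sm)
  class(out) <- c("shading_field", class(out))
  out
}

#' Correct an image for uneven illumination
#'
#' Elementwise division by a mean-1 multiplicative shading field.
#'
#' @param image Numeric matrix.
#' @param shading A `shading_field` (or any positive matrix of equal shape).
#' @return The corrected image.
#' @export
correct_shading <- function(image, shading) {
  if (!identical(dim(image), dim(shading))) stopf("shape mismatch")
  if (any(shading <= 0)) stopf("shading field must be strictly positive")
  image / unclass(shading)
}

#' Denoise an image
#'
#' @param image Numeric matrix.
#' @param method One of "median" (3x3 by default, robust to hot pixels),
#'   "gaussian", or "none".
#' @param size Median filter radius in pixels (window is 2*size+1).
#' @param sigma Gaussian SD in pixels; 0 is the identity.
#' @return The filtered image (same shape).
#' @export
denoise <- function(image, method = c("median", "gaussian", "none"),
                    size = 1, sigma = 1) {
  method <- match.arg(method)
  check_matrix(image)
  if (method == "none") return(image)
  if (method == "gaussian") {
    if (sigma == 0) return(image)
    return(EBImage::gblur(image, sigma = sigma, boundary = "replicate"))
  }
  # EBImage's median filter operates on [0, 1]-ranged data
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)
  scaled <- (image - lo) / (hi - lo)
  out <- EBImage::medianFilter(scaled, size = size)
  EBImage::imageData(out) * (hi - lo) + lo
}
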
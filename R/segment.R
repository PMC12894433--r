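#' Edge-based puncta mask
#'
#' Detects puncta from gradient structure: Sobel gradient magnitude,
#' automatic (Otsu) threshold on the gradient, morphological closing to
#' join edge fragments into contours, and hole filling to recover spot
#' interiors. Deterministic.
#'
#' @param image Preprocessed channel-1 matrix.
#' @param close_size Diameter of the disc used for closing, pixels (odd).
#' @return A logical matrix mask.
#' @export
edge_mask <- function(image, close_size = 3) {
  check_matrix(image)
  if (diff(range(image)) == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::imageData(EBImage::filter2(image, sx, boundary = "replicate"))
  gy <- EBImage::imageData(EBImage::filter2(image, t(sx), boundary = "replicate"))
  grad <- sqrt(gx^2 + gy^2)
  gmax <- max(grad)
  if (gmax == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  thr <- EBImage::otsu(EBImage::Image(grad / gmax), range = c(0, 1))
  mask <- grad / gmax > thr
  brush <- EBImage::makeBrush(close_size, shape = "disc")
  mask <- EBImage::closing(EBImage::Image(mask * 1), brush)
  mask <- EBImage::fillHull(mask)
  EBImage::imageData(mask) > 0
}

#' Local adaptive threshold mask
#'
#' Thresholding against robust moving-window statistics: a pixel is
#' foreground when it exceeds the window median by `k` robust SDs
#' (1.4826 x the window median absolute deviation). Robust statistics keep
#' the threshold anchored to the local background even when the window
#' contains bright puncta, and tolerate residual shading that defeats a
#' single global threshold.
#'
#' @param image Preprocessed channel-1 matrix.
#' @param window Odd window side length in pixels.
#' @param k Threshold offset in robust SDs.
#' @return A logical matrix mask.
#' @export
local_mask <- function(image, window = 31, k = 3) {
  check_matrix(image)
  if (window %% 2 == 0) window <- window + 1
  if (window > min(dim(image))) stopf("window (%d) larger than image", window)
  med <- moving_median(image, window)
  mad <- moving_median(abs(image - med), window)
  image > med + k * 1.4826 * mad
}

# Moving median via EBImage's constant-time median filter (operates on
# [0, 1]-scaled data; values are quantised to 16 bits of the data range).
moving_median <- function(image, window) {
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)
  scaled <- (image - lo) / (hi - lo)
  out <- EBImage::medianFilter(scaled, size = (window - 1) %/% 2)
  EBImage::imageData(out) * (hi - lo) + lo
}

#' Merge edge and local masks
#'
#' Pixelwise union (maximising recall), then removal of connected
#' components smaller than `min_area` and, optionally, components touching
#' the image border (their integrated intensity is truncated and would bias
#' sizing).
#'
#' @param edge,local Logical matrices of equal shape.
#' @param min_area Minimum component area in pixels.
#' @param clear_border Drop components touching the image border.
#' @return A logical matrix mask.
#' @export
merge_masks <- function(edge, local, min_area = 4, clear_border = TRUE) {
  if (!identical(dim(edge), dim(local))) stopf("mask shape mismatch")
  mask <- edge | local
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  areas <- tabulate(lab[lab > 0])
  drop <- which(areas < min_area)
  if (clear_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0])
  }
  if (length(drop)) mask[lab %in% drop] <- FALSE
  mask
}

# Annulus of background pixels around one component: dilate the component
# by `gap` then by `gap + width`; the ring between the two, minus all
# labelled foreground, is the local background support.
component_annulus <- function(lab, id, gap = 2, width = 4) {
  idx <- which(lab == id, arr.ind = TRUE)
  pad <- gap + width + 1
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(lab), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(lab), max(idx[, 2]) + pad)
  sub <- lab[r0:r1, c0:c1]
  comp <- EBImage::Image((sub == id) * 1)
  inner <- EBImage::dilate(comp, EBImage::makeBrush(2 * gap + 1, "disc"))
  outer <- EBImage::dilate(comp, EBImage::makeBrush(2 * (gap + width) + 1, "disc"))
  ring <- EBImage::imageData(outer) > 0 & !(EBImage::imageData(inner) > 0) & sub == 0
  list(ring = ring, r0 = r0, c0 = c0, r1 = r1, c1 = c1)
}

#' Label a mask and measure background-adjusted puncta intensities
#'
#' Connected components of the mask become molecule records. Per record:
#' the raw integrated intensity is the pixel sum over the component; the
#' local background per pixel is the median of an annulus around the
#' component (2 px gap, 4 px wide, excluding all labelled foreground); the
#' adjusted intensity is `raw - area * background`. Components whose
#' annulus is empty are dropped and counted in the `n_dropped` attribute.
#'
#' @param image Numeric matrix the intensities are measured on.
#' @param mask Logical matrix from [merge_masks()].
#' @param field_id Identifier echoed into every record.
#' @param grow Radius (pixels) by which components are dilated before
#'   measurement, so that the PSF tails outside the threshold mask are
#'   integrated (3 px captures > 99.9 percent of a 1.3 px-sigma spot).
#'   Components closer than twice this merge into one record.
#' @return A data.frame of puncta records: `molecule_id`, `field_id`,
#'   `area`, `centroid_row`, `centroid_col`, `raw_integrated`,
#'   `local_background_per_px`, `adjusted_intensity`, plus a `pixels`
#'   list-column of linear pixel indices (used by the colocalization gate).
#'   Columns `ch2_pcc`, `ch2_pvalue`, `colocalized` are initialised to NA.
#' @export
label_and_measure <- function(image, mask, field_id = NA, grow = 3) {
  check_matrix(image)
  if (!identical(dim(image), dim(mask))) stopf("image/mask shape mismatch")
  empty <- data.frame(molecule_id = integer(), field_id = integer(),
                      area = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), raw_integrated = numeric(),
                      local_background_per_px = numeric(),
                      adjusted_intensity = numeric(), ch2_pcc = numeric(),
                      ch2_pvalue = numeric(), colocalized = logical())
  if (!any(mask)) {
    empty$pixels <- list()
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  if (grow > 0) {
    # Records are seeded from smoothed intensity maxima inside the mask
    # (maxima closer than ~5 px collapse into one seed), then each seed
    # grows into the dilated mask aperture by nearest-seed assignment.
    # Touching masks of puncta separated by more than ~6 PSF sigma thus
    # stay separate records; truly overlapping molecules still yield a
    # single bright record (no declumping).
    sm <- EBImage::imageData(EBImage::gblur(image, sigma = 1.2, boundary = "replicate"))
    pad <- function(m, dr, dc) {
      nr <- nrow(m); nc <- ncol(m)
      m[pmin(pmax(seq_len(nr) + dr, 1), nr), pmin(pmax(seq_len(nc) + dc, 1), nc)]
    }
    nbmax <- pad(sm, 1, 0)
    for (s in list(c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(1, -1),
                   c(-1, 1), c(-1, -1)))
      nbmax <- pmax(nbmax, pad(sm, s[1], s[2]))
    maxima <- (sm >= nbmax) & mask
    grown <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(mask * 1), EBImage::makeBrush(2 * grow + 1, "disc"))) > 0
    seed_mask <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(maxima * 1), EBImage::makeBrush(5, "disc"))) > 0
    seeds <- EBImage::bwlabel(EBImage::Image((seed_mask & grown) * 1))
    lab <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(sm / max(sm)), seeds,
      mask = EBImage::Image(grown * 1), lambda = 1e8))
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  }
  ids <- which(lab > 0)
  labs <- lab[ids]
  n <- max(labs)
  area <- tabulate(labs, n)
  rows <- ((ids - 1) %% nrow(lab)) + 1
  cols <- ((ids - 1) %/% nrow(lab)) + 1
  raw <- as.vector(rowsum(image[ids], labs))
  bg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ann <- component_annulus(lab, i)
    vals <- image[ann$r0:ann$r1, ann$c0:ann$c1][ann$ring]
    if (length(vals)) bg[i] <- stats::median(vals)
  }
  # intensity-weighted centroids on the background-subtracted signal
  w <- pmax(image[ids] - bg[labs], 0) + 1e-12
  wsum <- as.vector(rowsum(w, labs))
  cr <- as.vector(rowsum(rows * w, labs)) / wsum
  cc <- as.vector(rowsum(cols * w, labs)) / wsum
  keep <- !is.na(bg)
  pixels <- split(ids, labs)
  out <- data.frame(molecule_id = seq_len(n), field_id = field_id,
                    area = area, centroid_row = cr, centroid_col = cc,
                    raw_integrated = raw, local_background_per_px = bg,
                    adjusted_intensity = raw - area * bg,
                    ch2_pcc = NA_real_, ch2_pvalue = NA_real_,
                    colocalized = NA)
  out$pixels <- pixels
  out <- out[keep, , drop = FALSE]
  out$molecule_id <- seq_len(nrow(out))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Full segmentation of one field
#'
#' Convenience wrapper: edge mask + local mask, merged, then measured.
#'
#' @inheritParams label_and_measure
#' @inheritParams local_mask
#' @inheritParams merge_masks
#' @param close_size Closing disc diameter for the edge mask.
#' @return See [label_and_measure()].
#' @export
segment_field <- function(image, field_id = NA, window = 31, k = 3,
                          min_area = 4, clear_border = TRUE, close_size = 3,
                          grow = 3) {
  m <- merge_masks(edge_mask(image, close_size = close_size),
                   local_mask(image, window = window, k = k),
                   min_area = min_area, clear_border = clear_border)
  label_and_measure(image, m, field_id = field_id, grow = grow)
}
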
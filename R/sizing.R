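#' Build a molecule-intensity histogram
#'
#' @param intensities Numeric vector of background-adjusted intensities.
#' @param binwidth Fixed bin width in a.u.; if `NULL`, the number of bins
#'   defaults to `2 sqrt(n)` (at least 10). The square-root rule is chosen
#'   over variance-based rules (Freedman-Diaconis, Scott) because molecule
#'   intensity distributions are multimodal: their large overall spread
#'   makes variance-based widths too coarse to resolve individual
#'   populations.
#' @param range Numeric (lo, hi); values outside are counted, logged in the
#'   `n_outside` field, and excluded. Defaults to the data range.
#' @param source Sample/condition tag carried through the analysis.
#' @param n_fields Number of imaged fields the molecules came from (used by
#'   background normalisation in [subtract_background()]).
#' @return An object of class `intensity_histogram`: list with `bin_edges`,
#'   `counts`, `mids`, `n_total`, `n_outside`, `source`, `n_fields`.
#' @export
build_histogram <- function(intensities, binwidth = NULL, range = NULL,
                            source = NA_character_, n_fields = NA_integer_) {
  intensities <- intensities[is.finite(intensities)]
  if (length(intensities) == 0) stopf("no finite intensities to histogram")
  if (is.null(range)) range <- base::range(intensities)
  inside <- intensities >= range[1] & intensities <= range[2]
  n_outside <- sum(!inside)
  x <- intensities[inside]
  if (length(x) == 0) stopf("all intensities fall outside the requested range")
  if (is.null(binwidth)) {
    nb <- max(10, ceiling(2 * sqrt(length(x))))
    binwidth <- diff(range) / nb
  }
  if (binwidth <= 0) stopf("binwidth must be > 0")
  edges <- seq(range[1], range[2] + binwidth, by = binwidth)
  counts <- as.vector(table(cut(x, edges, include.lowest = TRUE, right = FALSE)))
  structure(list(bin_edges = edges, counts = counts,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 n_total = length(x), n_outside = n_outside,
                 source = source, n_fields = n_fields),
            class = "intensity_histogram")
}

#' Find histogram peaks
#'
#' Local maxima of the counts exceeding a prominence threshold (the least
#' descent separating the peak from higher ground), ordered by position.
#'
#' @param hist An `intensity_histogram`.
#' @param min_prominence Minimum prominence in counts; the default
#'   `max(3, 0.05 * max(counts), 2 * sqrt(max(counts)))` scales with both
#'   the histogram height and its counting noise, so Poisson bin-to-bin
#'   fluctuations do not register as populations.
#' @param smooth Width (bins) of a moving-average smoother applied before
#'   peak picking; 1 disables smoothing.
#' @return A data.frame with `bin` (index), `position` (bin mid, a.u.) and
#'   `height` (counts); zero rows when no peak qualifies.
#' @export
find_peaks <- function(hist, min_prominence = NULL, smooth = 1) {
  stopifnot(inherits(hist, "intensity_histogram"))
  y <- as.numeric(hist$counts)
  if (length(y) < 3) stopf("histogram needs at least 3 bins")
  if (smooth > 1) {
    kk <- rep(1 / smooth, smooth)
    y <- stats::filter(y, kk, sides = 2)
    y[is.na(y)] <- hist$counts[is.na(y)]
    y <- as.numeric(y)
  }
  if (is.null(min_prominence))
    min_prominence <- max(3, 0.05 * max(y), 2 * sqrt(max(y)))
  n <- length(y)
  cand <- which(vapply(seq(2, n - 1), function(i)
    y[i] > y[i - 1] && y[i] >= y[i + 1], logical(1))) + 1
  if (length(cand) == 0)
    return(data.frame(bin = integer(), position = numeric(), height = numeric()))
  prom <- vapply(cand, function(i) {
    # walk out each side until a bin higher than the peak; the prominence
    # is the peak height minus the higher of the two valley minima
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    hl <- which(left > y[i]); hr <- which(right > y[i])
    vl <- if (length(hl)) min(left[seq(max(hl), i - 1)]) else min(left)
    vr <- if (length(hr)) min(right[seq_len(min(hr))]) else min(right)
    y[i] - max(vl, vr)
  }, numeric(1))
  keep <- prom >= min_prominence
  out <- data.frame(bin = cand[keep], position = hist$mids[cand[keep]],
                    height = hist$counts[cand[keep]])
  out[order(out$position), , drop = FALSE]
}

#' Initial Gaussian estimate from a histogram peak
#'
#' Measures the full width at half maximum around the peak by linear
#' interpolation of the half-height crossings and converts it to a
#' standard deviation via `sigma = FWHM / (2 sqrt(2 ln 2))`. If either
#' half-height crossing runs off the histogram edge the peak is reported
#' as unresolved.
#'
#' @param hist An `intensity_histogram`.
#' @param peak One row of [find_peaks()] output (or a list with `bin`).
#' @return A list `mu`, `sigma`, `amplitude`, `resolved`. When
#'   `resolved = FALSE` the estimates are `NA`.
#' @export
init_gaussian <- function(hist, peak) {
  stopifnot(inherits(hist, "intensity_histogram"))
  i <- peak$bin[1]
  y <- as.numeric(hist$counts)
  x <- hist$mids
  h <- y[i]
  half <- h / 2
  unresolved <- list(mu = NA_real_, sigma = NA_real_, amplitude = NA_real_,
                     resolved = FALSE)
  # walk left
  l <- i
  while (l > 1 && y[l] > half) l <- l - 1
  if (y[l] > half) return(unresolved)
  # walk right
  r <- i
  n <- length(y)
  while (r < n && y[r] > half) r <- r + 1
  if (y[r] > half) return(unresolved)
  xl <- x[l] + (x[l + 1] - x[l]) * (half - y[l]) / (y[l + 1] - y[l])
  xr <- x[r - 1] + (x[r] - x[r - 1]) * (y[r - 1] - half) / (y[r - 1] - y[r])
  fwhm <- xr - xl
  if (!is.finite(fwhm) || fwhm <= 0) return(unresolved)
  list(mu = x[i], sigma = fwhm_to_sigma(fwhm), amplitude = h, resolved = TRUE)
}

#' @rdname init_gaussian
#' @param fwhm Full width at half maximum.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Fit one Gaussian population to a windowed intensity subset
#'
#' Restricts the molecules to the window `mu0 +/- window_sigmas * sigma0`
#' given by the initial estimate, bins them, and least-squares fits a
#' Gaussian `A exp(-(x - mu)^2 / (2 sigma^2))` to the binned counts
#' (Levenberg-Marquardt). Windowing keeps neighbouring populations from
#' biasing the fit.
#'
#' @param intensities All molecule intensities of the sample.
#' @param init Output of [init_gaussian()] (must be resolved).
#' @param binwidth Bin width used for the fit; default the seeding
#'   histogram's width via `hist`, or `sigma0 / 2`.
#' @param hist Optional `intensity_histogram` the peak came from (its
#'   binning is reused).
#' @param window_sigmas Half-width of the fit window in units of `sigma0`.
#' @param min_molecules Minimum molecules required inside the window.
#' @return An object of class `population_fit`: `mean`, `sd`, `amplitude`,
#'   `n_molecules`, `fit_window`, `size_bp` and `size_error` (NA until
#'   calibrated).
#' @export
fit_population <- function(intensities, init, binwidth = NULL, hist = NULL,
                           window_sigmas = 2, min_molecules = 20) {
  if (!isTRUE(init$resolved)) stopf("initial estimate is unresolved")
  lo <- init$mu - window_sigmas * init$sigma
  hi <- init$mu + window_sigmas * init$sigma
  x <- intensities[is.finite(intensities) & intensities >= lo & intensities <= hi]
  if (length(x) < min_molecules)
    stopf("only %d molecules in fit window [%.3g, %.3g] (need >= %d)",
          length(x), lo, hi, min_molecules)
  if (is.null(binwidth))
    binwidth <- if (!is.null(hist)) diff(hist$bin_edges[1:2]) else init$sigma / 2
  edges <- seq(lo, hi + binwidth, by = binwidth)
  counts <- as.vector(table(cut(x, edges, include.lowest = TRUE, right = FALSE)))
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  df <- data.frame(x = mids, y = counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)), data = df,
                      start = list(A = init$amplitude, mu = init$mu,
                                   sigma = init$sigma),
                      lower = c(0, lo, binwidth / 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stopf("Gaussian fit failed: %s", conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(mean = unname(co["mu"]), sd = unname(co["sigma"]),
                 amplitude = unname(co["A"]), n_molecules = length(x),
                 fit_window = c(lo, hi), size_bp = NA_real_,
                 size_error = NA_real_),
            class = "population_fit")
}

#' Fit the intensity-to-size calibration line
#'
#' Ordinary least squares of known DNA size (bp) on population mean
#' intensity (a.u.). The curve is condition-specific: staining ratio and
#' buffer shift the intensity per base pair, so a curve must only be
#' applied to samples prepared under its own condition.
#'
#' @param mean_intensity Population mean intensities, a.u.
#' @param size_bp Known plasmid sizes, bp.
#' @param through_origin Force a zero intercept.
#' @param ci_level Level for prediction intervals (default 0.99).
#' @param condition Mandatory condition tag (buffer / dye-ratio label).
#' @return An object of class `calibration_curve` with `slope` (bp per
#'   a.u.), `intercept` (bp), `r_squared`, `residual_sd` (bp), `n_points`,
#'   `condition`, `through_origin`, `ci_level`, the fitted `model`, and the
#'   input `points`. `r_squared` is always computed about the mean of the
#'   sizes (also for the through-origin fit, so the two variants are
#'   comparable and forcing the origin can only lower it).
#' @export
fit_calibration <- function(mean_intensity, size_bp, through_origin = FALSE,
                            ci_level = 0.99, condition = "default") {
  if (is.na(condition) || !nzchar(condition)) stopf("condition tag is mandatory")
  n <- length(mean_intensity)
  if (length(size_bp) != n) stopf("mean_intensity and size_bp lengths differ")
  if (n < 2 && !through_origin) stopf("need >= 2 calibration points")
  if (n < 1) stopf("need >= 1 calibration point")
  if (stats::var(mean_intensity) == 0 && n > 1) stopf("degenerate calibration: all intensities equal")
  d <- data.frame(intensity = mean_intensity, size_bp = size_bp)
  model <- if (through_origin) stats::lm(size_bp ~ 0 + intensity, data = d)
           else stats::lm(size_bp ~ intensity, data = d)
  co <- stats::coef(model)
  ss_res <- sum(stats::residuals(model)^2)
  ss_tot <- sum((size_bp - mean(size_bp))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  df_res <- n - if (through_origin) 1 else 2
  resid_sd <- if (df_res > 0) sqrt(ss_res / df_res) else NA_real_
  structure(list(slope = unname(co[["intensity"]]),
                 intercept = if (through_origin) 0 else unname(co[["(Intercept)"]]),
                 r_squared = r2,
                 residual_sd = resid_sd,
                 n_points = n, condition = condition,
                 through_origin = through_origin, ci_level = ci_level,
                 model = model, points = d),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Intensity-to-size calibration [%s]\n", x$condition))
  cat(sprintf("  size_bp = %.6g * intensity %+.6g   (R^2 = %.4f, n = %d%s)\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              if (x$through_origin) ", through origin" else ""))
  invisible(x)
}

#' Convert intensity to DNA size with an error bound
#'
#' Inverts the calibration: `size = slope * intensity + intercept`. The
#' reported error is the half-width of the regression prediction interval
#' at the curve's `ci_level`, which widens with distance from the
#' calibration centroid and represents the per-molecule size estimation
#' error band.
#'
#' @param curve A `calibration_curve`.
#' @param intensity Numeric vector of intensities (a.u.), e.g. population
#'   means.
#' @param condition Condition tag of the sample; a mismatch with the
#'   curve's tag triggers a warning (curves do not transfer between
#'   staining conditions).
#' @return A data.frame: `intensity`, `size_bp`, `size_error` (+/- bp),
#'   `extrapolated` (outside the calibrated intensity range), `valid`
#'   (FALSE when the predicted size is negative).
#' @export
intensity_to_size <- function(curve, intensity, condition = curve$condition) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!identical(condition, curve$condition))
    warning(sprintf(paste0("calibration condition '%s' does not match sample ",
                           "condition '%s'; sizes may carry a bias"),
                    curve$condition, condition), call. = FALSE)
  nd <- data.frame(intensity = intensity)
  pr <- stats::predict(curve$model, newdata = nd, interval = "prediction",
                       level = curve$ci_level)
  rng <- range(curve$points$intensity)
  extrap <- intensity < rng[1] | intensity > rng[2]
  size <- pr[, "fit"]
  valid <- size >= 0
  if (any(!valid))
    warning("negative predicted size flagged invalid", call. = FALSE)
  data.frame(intensity = intensity, size_bp = size,
             size_error = (pr[, "upr"] - pr[, "lwr"]) / 2,
             extrapolated = extrap, valid = valid)
}

#' Fit all populations of a sample and calibrate
#'
#' Convenience driver used by the calibration workflow: histogram, peak
#' finding, FWHM seeding, windowed Gaussian fits.
#'
#' @inheritParams build_histogram
#' @inheritParams find_peaks
#' @inheritParams fit_population
#' @param n_peaks Optional expected number of populations; if more peaks
#'   are found, the `n_peaks` most prominent are kept; fewer is an error.
#' @return A list of `population_fit` objects, ordered by mean.
#' @export
fit_all_populations <- function(intensities, binwidth = NULL,
                                min_prominence = NULL, smooth = 3,
                                n_peaks = NULL, window_sigmas = 2,
                                min_molecules = 20) {
  h <- build_histogram(intensities, binwidth = binwidth)
  pk <- find_peaks(h, min_prominence = min_prominence, smooth = smooth)
  if (!is.null(n_peaks)) {
    if (nrow(pk) < n_peaks)
      stopf("found %d peaks, expected %d", nrow(pk), n_peaks)
    pk <- pk[order(-pk$height), , drop = FALSE][seq_len(n_peaks), , drop = FALSE]
    pk <- pk[order(pk$position), , drop = FALSE]
  }
  fits <- list()
  for (j in seq_len(nrow(pk))) {
    init <- init_gaussian(h, pk[j, ])
    if (!init$resolved) stopf("peak at %.4g a.u. is unresolved", pk$position[j])
    fits[[j]] <- fit_population(intensities, init, hist = h,
                                window_sigmas = window_sigmas,
                                min_molecules = min_molecules)
  }
  fits[order(vapply(fits, `[[`, numeric(1), "mean"))]
}
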
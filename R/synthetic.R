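#' Define a DNA population for simulation
#'
#' A population is a set of circular DNA molecules of one size whose
#' integrated YOYO-1 intensity is, on average, proportional to length in
#' base pairs. Mixtures of populations (e.g. a three-plasmid calibration
#' ladder, or a monomer/dimer vector mixture) are expressed as lists of
#' `population_spec` objects whose fractions sum to 1.
#'
#' @param size_bp DNA length in base pairs (positive integer).
#' @param fraction Proportion of molecules belonging to this population,
#'   in \[0, 1\].
#' @param intensity_cv Relative standard deviation of the integrated
#'   intensity (dimensionless, >= 0). Lumps staining stoichiometry,
#'   photophysics and residual measurement spread.
#' @param coloc_rate Probability that a molecule of this population carries
#'   a channel-2 (dCas9) spot, in \[0, 1\].
#' @return An object of class `population_spec`.
#' @examples
#' calib <- list(
#'   population_spec(2686, 1/3), population_spec(5562, 1/3),
#'   population_spec(12920, 1/3))
#' @export
population_spec <- function(size_bp, fraction, intensity_cv = 0.05, coloc_rate = 0) {
  if (!is_scalar_number(size_bp) || size_bp <= 0 || size_bp != round(size_bp))
    stopf("size_bp must be a positive integer, got %s", format(size_bp))
  if (!is_scalar_number(fraction) || fraction < 0 || fraction > 1)
    stopf("fraction must be in [0, 1]")
  if (!is_scalar_number(intensity_cv) || intensity_cv < 0)
    stopf("intensity_cv must be >= 0, got %s", format(intensity_cv))
  if (!is_scalar_number(coloc_rate) || coloc_rate < 0 || coloc_rate > 1)
    stopf("coloc_rate must be in [0, 1]")
  structure(list(size_bp = as.integer(size_bp), fraction = fraction,
                 intensity_cv = intensity_cv, coloc_rate = coloc_rate),
            class = "population_spec")
}

check_populations <- function(populations) {
  if (length(populations) == 0) stopf("population list is empty")
  if (inherits(populations, "population_spec")) populations <- list(populations)
  ok <- vapply(populations, inherits, logical(1), "population_spec")
  if (!all(ok)) stopf("all elements must be population_spec objects")
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stopf("population fractions must sum to 1 (got %.6f)", sum(fr))
  populations
}

#' Imaging configuration for the synthetic field generator
#'
#' Parameters of the simulated microscope/camera. Defaults emulate a
#' single-molecule EMCCD acquisition of surface-deposited DNA: a 512x512
#' field covering 1.5e4 um^2 (field area inferred from a stated maximal
#' deposition regime of 1 molecule per 15 um^2 with ~1000 molecules per
#' field; no camera pixel size is stated, so the pixel area here is a
#' derived, configurable default), an isotropic Gaussian PSF, smooth
#' radial vignetting, gain-scaled Poisson shot noise plus Gaussian read
#' noise, and spurious channel-2 spots modelling transiently bound dCas9.
#'
#' @param field_shape Integer vector (rows, cols) in pixels.
#' @param pixel_area Area of one pixel in um^2.
#' @param psf_sigma PSF standard deviation in pixels (> 0).
#' @param intensity_per_bp Expected integrated channel-1 intensity per base
#'   pair, arbitrary units.
#' @param ch2_spot_intensity Integrated intensity of one channel-2 spot, a.u.
#' @param shading_amplitude Relative illumination falloff centre-to-corner,
#'   in \[0, 1).
#' @param background_level Mean background per pixel, a.u.
#' @param read_noise_sd Gaussian read noise SD per pixel, a.u.
#' @param em_gain_factor Multiplicative gain applied to Poisson shot noise
#'   (0 disables shot noise; EMCCD excess noise is approximated by scaling).
#' @param false_ch2_density Expected number of unattached channel-2 spots
#'   per field (uniformly placed).
#' @param seed Integer seed recorded with the config.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(field_shape = c(512L, 512L),
                           pixel_area = 1.5e4 / (512 * 512),
                           psf_sigma = 1.3,
                           intensity_per_bp = 2,
                           ch2_spot_intensity = 3000,
                           shading_amplitude = 0.15,
                           background_level = 100,
                           read_noise_sd = 10,
                           em_gain_factor = 2,
                           false_ch2_density = 10,
                           seed = 1L) {
  if (length(field_shape) != 2 || any(field_shape < 1) ||
      any(field_shape != round(field_shape)))
    stopf("field_shape must be two positive integers")
  if (!is_scalar_number(psf_sigma) || psf_sigma <= 0) stopf("psf_sigma must be > 0")
  for (nm in c("pixel_area", "intensity_per_bp", "ch2_spot_intensity",
               "background_level", "read_noise_sd", "em_gain_factor",
               "false_ch2_density")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0) stopf("%s must be >= 0", nm)
  }
  if (shading_amplitude < 0 || shading_amplitude >= 1)
    stopf("shading_amplitude must be in [0, 1)")
  structure(list(field_shape = as.integer(field_shape), pixel_area = pixel_area,
                 psf_sigma = psf_sigma, intensity_per_bp = intensity_per_bp,
                 ch2_spot_intensity = ch2_spot_intensity,
                 shading_amplitude = shading_amplitude,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 em_gain_factor = em_gain_factor,
                 false_ch2_density = false_ch2_density,
                 seed = as.integer(seed)),
            class = "imaging_config")
}

#' Simulate a per-molecule intensity table with ground truth
#'
#' Draws molecule counts per population from a multinomial in the mixture
#' fractions, then per-population integrated intensities from
#' Normal(mean = size_bp * intensity_per_bp, sd = cv * mean), truncated at
#' zero. Channel-2 occupancy is Bernoulli(coloc_rate) per molecule. The
#' same seed always yields the same table.
#'
#' @param populations List of [population_spec()] (fractions summing to 1).
#' @param n_molecules Total number of molecules (>= 1).
#' @param seed Integer seed.
#' @param intensity_per_bp Expected intensity per base pair, a.u.
#' @return A data.frame with columns `molecule_id`, `intensity`, `size_bp`,
#'   `true_intensity`, `has_ch2`, `population_index`.
#' @export
gen_intensity_table <- function(populations, n_molecules, seed = 1L,
                                intensity_per_bp = 2) {
  populations <- check_populations(populations)
  if (!is_scalar_number(n_molecules) || n_molecules < 1)
    stopf("n_molecules must be >= 1")
  n_molecules <- as.integer(n_molecules)
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, n_molecules, fr))
    idx <- rep.int(seq_along(populations), counts)
    size_bp <- vapply(populations, `[[`, integer(1), "size_bp")[idx]
    cv <- vapply(populations, `[[`, numeric(1), "intensity_cv")[idx]
    rate <- vapply(populations, `[[`, numeric(1), "coloc_rate")[idx]
    mu <- size_bp * intensity_per_bp
    intensity <- pmax(stats::rnorm(n_molecules, mu, cv * mu), 0)
    has_ch2 <- stats::runif(n_molecules) < rate
    data.frame(molecule_id = seq_len(n_molecules), intensity = intensity,
               size_bp = size_bp, true_intensity = mu, has_ch2 = has_ch2,
               population_index = idx)
  })
}

# Pixel-integrated isotropic Gaussian spot added in place into `img`.
# The spot integral over the whole plane equals `intensity`; rendering is
# restricted to +/- 6 sigma (truncated mass < 1e-8).
add_spot <- function(img, row, col, intensity, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  half <- ceiling(6 * sigma)
  r0 <- max(1L, floor(row) - half); r1 <- min(nr, ceiling(row) + half)
  c0 <- max(1L, floor(col) - half); c1 <- min(nc, ceiling(col) + half)
  if (r0 > r1 || c0 > c1) return(img)
  # pixel i covers [i - 0.5, i + 0.5]; integrate the Gaussian over each pixel
  pr <- diff(stats::pnorm(seq(r0 - 0.5, r1 + 0.5), mean = row, sd = sigma))
  pc <- diff(stats::pnorm(seq(c0 - 0.5, c1 + 0.5), mean = col, sd = sigma))
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + intensity * (pr %o% pc)
  img
}

# Smooth radial vignette: 1 at centre, (1 - amplitude) at the farthest corner.
vignette_field <- function(shape, amplitude) {
  nr <- shape[1]; nc <- shape[2]
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  d2 <- outer((seq_len(nr) - rc)^2, (seq_len(nc) - cc)^2, `+`)
  1 - amplitude * d2 / max(d2)
}

apply_camera_noise <- function(img, config) {
  n <- length(img)
  out <- img
  if (config$em_gain_factor > 0) {
    g <- config$em_gain_factor
    out <- g * stats::rpois(n, img / g)
    dim(out) <- dim(img)
  }
  if (config$read_noise_sd > 0) {
    out <- out + stats::rnorm(n, 0, config$read_noise_sd)
    dim(out) <- dim(img)
  }
  out
}

#' Render one synthetic two-channel field
#'
#' Channel 1 is a shading-modulated background plus one pixel-integrated 2-D
#' Gaussian spot per molecule (integral equal to the molecule's true
#' intensity), degraded by gain-scaled Poisson shot noise and Gaussian read
#' noise. Channel 2 carries spots at the positions of molecules with
#' channel-2 occupancy, plus a Poisson number of unattached false spots.
#'
#' @param truths Either a data.frame of ground truth molecules (columns
#'   `size_bp`, `true_intensity` or `intensity`, `has_ch2`; positions are
#'   drawn uniformly if absent) or a list of [population_spec()] together
#'   with `n_molecules`.
#' @param config An [imaging_config()].
#' @param n_molecules Number of molecules when `truths` is a spec list.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with elements `ch1`, `ch2` (numeric matrices) and `truth`
#'   (data.frame with per-molecule ground truth incl. sub-pixel positions
#'   and an `overlapped` flag for molecules within 2 PSF sigma of another).
#' @export
gen_field <- function(truths, config = imaging_config(), n_molecules = NULL,
                      seed = config$seed) {
  stopifnot(inherits(config, "imaging_config"))
  with_seed(seed, {
    if (!is.data.frame(truths)) {
      populations <- check_populations(truths)
      if (is.null(n_molecules)) stopf("n_molecules required with population specs")
      if (n_molecules == 0) {
        truths <- data.frame(molecule_id = integer(), intensity = numeric(),
                             size_bp = integer(), true_intensity = numeric(),
                             has_ch2 = logical(), population_index = integer())
      } else {
        truths <- gen_intensity_table(populations, n_molecules, seed = NULL,
                                      intensity_per_bp = config$intensity_per_bp)
        # in image space the pre-noise spot integral is the drawn intensity
        truths$true_intensity <- truths$intensity
      }
    } else if (!"true_intensity" %in% names(truths)) {
      truths$true_intensity <- truths$intensity
    }
    nr <- config$field_shape[1]; nc <- config$field_shape[2]
    n <- nrow(truths)
    if (is.null(truths$row) || is.null(truths$col)) {
      truths$row <- stats::runif(n, 0.5, nr + 0.5)
      truths$col <- stats::runif(n, 0.5, nc + 0.5)
    }
    if (is.null(truths$has_ch2)) truths$has_ch2 <- rep(FALSE, n)
    truths$molecule_id <- seq_len(n)

    ch1 <- matrix(config$background_level, nr, nc)
    for (i in seq_len(n))
      ch1 <- add_spot(ch1, truths$row[i], truths$col[i],
                      truths$true_intensity[i], config$psf_sigma)
    shading <- vignette_field(c(nr, nc), config$shading_amplitude)
    ch1 <- ch1 * shading

    ch2 <- matrix(config$background_level, nr, nc)
    for (i in which(truths$has_ch2))
      ch2 <- add_spot(ch2, truths$row[i], truths$col[i],
                      config$ch2_spot_intensity, config$psf_sigma)
    n_false <- stats::rpois(1, config$false_ch2_density)
    if (n_false > 0) {
      fr <- stats::runif(n_false, 0.5, nr + 0.5)
      fc <- stats::runif(n_false, 0.5, nc + 0.5)
      for (i in seq_len(n_false))
        ch2 <- add_spot(ch2, fr[i], fc[i], config$ch2_spot_intensity,
                        config$psf_sigma)
    }
    ch2 <- ch2 * shading

    ch1 <- apply_camera_noise(ch1, config)
    ch2 <- apply_camera_noise(ch2, config)

    # molecules closer than 6 PSF sigma are not resolvable as separate
    # puncta (no declumping downstream); flag them in the truth
    truths$overlapped <- rep(FALSE, n)
    if (n > 1) {
      d <- as.matrix(stats::dist(cbind(truths$row, truths$col)))
      diag(d) <- Inf
      truths$overlapped <- apply(d, 1, min) < 6 * config$psf_sigma
    }
    list(ch1 = ch1, ch2 = ch2, truth = truths)
  })
}

#' Simulate a multi-field experiment with a truth manifest
#'
#' Generates `n_fields` independent fields from one seed stream. Per-field
#' molecule counts are Poisson around `molecules_per_field`, and population
#' membership is multinomial in the mixture fractions.
#'
#' @param populations List of [population_spec()].
#' @param config An [imaging_config()].
#' @param n_fields Number of fields (>= 1).
#' @param molecules_per_field Expected molecules per field. The default 100
#'   keeps overlaps rare; set to `1.5e4 / 15` (= 1000) to emulate the
#'   maximal deposition regime of 1 molecule per 15 um^2.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with `fields` (list of `gen_field()` outputs) and
#'   `manifest` (one row per molecule with a `field_id` column).
#' @export
gen_experiment <- function(populations, config = imaging_config(),
                           n_fields = 10, molecules_per_field = 100,
                           seed = config$seed) {
  if (!is_scalar_number(n_fields) || n_fields < 1) stopf("n_fields must be >= 1")
  populations <- check_populations(populations)
  with_seed(seed, {
    fields <- vector("list", n_fields)
    manifests <- vector("list", n_fields)
    for (f in seq_len(n_fields)) {
      n <- stats::rpois(1, molecules_per_field)
      if (n == 0) {
        truth <- data.frame(molecule_id = integer(), intensity = numeric(),
                            size_bp = integer(), true_intensity = numeric(),
                            has_ch2 = logical(), population_index = integer())
      } else {
        truth <- gen_intensity_table(populations, n, seed = NULL,
                                     intensity_per_bp = config$intensity_per_bp)
        truth$true_intensity <- truth$intensity
      }
      fields[[f]] <- gen_field(truth, config, seed = NULL)
      m <- fields[[f]]$truth
      if (nrow(m)) m$field_id <- f
      manifests[[f]] <- m
    }
    manifest <- do.call(rbind, manifests[vapply(manifests, nrow, 1L) > 0])
    if (is.null(manifest)) manifest <- data.frame()
    list(fields = fields, manifest = manifest, n_fields = n_fields)
  })
}
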
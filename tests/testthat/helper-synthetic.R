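# Shared fixtures: all synthetic, built in code.

# The three-plasmid calibration ladder used throughout.
calib_populations <- function(cv = 0.05) {
  list(population_spec(2686, 1 / 3, cv),
       population_spec(5562, 1 / 3, cv),
       population_spec(12920, 1 / 3, cv))
}

# Imaging with every stochastic/optical nuisance switched off.
clean_config <- function(shape = c(64, 64), ...) {
  imaging_config(field_shape = shape, shading_amplitude = 0,
                 background_level = 100, read_noise_sd = 0,
                 em_gain_factor = 0, false_ch2_density = 0, ...)
}

# Default noisy imaging on a smaller field for speed.
noisy_config <- function(shape = c(256, 256), ...) {
  imaging_config(field_shape = shape, ...)
}

# Shading-correct with the generator's own vignette (normalised to mean 1,
# as estimate_shading would); returns the corrected image and the global
# illumination factor linking corrected to true intensities.
correct_with_truth <- function(image, config) {
  v <- punctasizer:::vignette_field(dim(image), config$shading_amplitude)
  sh <- v / mean(v)
  class(sh) <- c("shading_field", class(sh))
  list(image = correct_shading(image, sh), factor = mean(v))
}

# Brute-force exact 1-D k-means: enumerate all contiguous partitions of
# the sorted values and minimise total within-cluster SS.
brute_kmeans_1d <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ss <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(splits))) {
    b <- c(0, splits[, j], n)
    tot <- sum(vapply(seq_len(k), function(q) ss(x[(b[q] + 1):b[q + 1]]),
                      numeric(1)))
    if (tot < best) best <- tot
  }
  best
}
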
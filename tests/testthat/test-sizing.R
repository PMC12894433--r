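test_that("histogram construction conserves counts", {
  h <- build_histogram(rep(42, 100), binwidth = 1)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(max(h$counts), 100)

  set.seed(61)
  x <- rnorm(5000, 100, 20)
  h2 <- build_histogram(x)
  expect_equal(sum(h2$counts), length(x))
  expect_equal(h2$n_outside, 0)

  h3 <- build_histogram(x, range = c(80, 120))
  expect_equal(sum(h3$counts) + h3$n_outside, length(x))
  expect_error(build_histogram(numeric()), "no finite")
})

test_that("automatic binning resolves a three-population mixture", {
  tab <- gen_intensity_table(calib_populations(), 3000, seed = 62)
  h <- build_histogram(tab$intensity)
  pk <- find_peaks(h, smooth = 3)
  expect_gte(nrow(pk), 3)
})

test_that("peak finding reports positions near the population means", {
  tab <- gen_intensity_table(calib_populations(), 3000, seed = 63,
                             intensity_per_bp = 2)
  h <- build_histogram(tab$intensity)
  pk <- find_peaks(h, smooth = 3)
  pk <- pk[order(-pk$height), ][1:3, ]
  pk <- pk[order(pk$position), ]
  truth <- c(2686, 5562, 12920) * 2
  expect_equal(nrow(pk), 3)
  expect_true(all(abs(pk$position - truth) / truth < 0.05))

  # a monotone histogram has no interior peak
  mono <- build_histogram(rep(1:10, times = 10:1), binwidth = 1)
  expect_equal(nrow(find_peaks(mono, min_prominence = 3)), 0)
})

test_that("close populations may merge and are then not double-counted", {
  pops <- list(population_spec(5000, 0.5, 0.04),
               population_spec(5400, 0.5, 0.04))  # < 1 FWHM apart
  tab <- gen_intensity_table(pops, 4000, seed = 64)
  h <- build_histogram(tab$intensity)
  pk <- find_peaks(h, smooth = 3)
  expect_lte(nrow(pk), 2)
})

test_that("FWHM seeding matches the analytic conversion", {
  expect_equal(fwhm_to_sigma(23.548), 10, tolerance = 1e-4)
  # discretised Gaussian, mu = 100, sigma = 10
  mids <- seq(50, 150, by = 2)
  counts <- round(1000 * exp(-(mids - 100)^2 / (2 * 100)))
  h <- structure(list(bin_edges = c(mids - 1, max(mids) + 1), counts = counts,
                      mids = mids, n_total = sum(counts), n_outside = 0,
                      source = NA, n_fields = NA),
                 class = "intensity_histogram")
  init <- init_gaussian(h, list(bin = which.max(counts)))
  expect_true(init$resolved)
  expect_equal(init$mu, 100)
  expect_lt(abs(init$sigma - 10) / 10, 0.1)

  # peak on the histogram edge: no right half-height crossing
  mids2 <- 1:20
  htrunc <- structure(list(bin_edges = c(mids2 - 0.5, 20.5),
                           counts = seq(10, 200, by = 10), mids = mids2,
                           n_total = sum(seq(10, 200, by = 10)),
                           n_outside = 0, source = NA, n_fields = NA),
                      class = "intensity_histogram")
  init2 <- init_gaussian(htrunc, list(bin = 20))
  expect_false(init2$resolved)
})

test_that("windowed Gaussian fit recovers population parameters", {
  set.seed(65)
  x <- rnorm(5000, 1000, 80)
  h <- build_histogram(x)
  pk <- find_peaks(h, smooth = 3)
  init <- init_gaussian(h, pk[which.max(pk$height), ])
  fit <- fit_population(x, init, hist = h)
  expect_lt(abs(fit$mean - 1000), 2 * 80 / sqrt(5000) * 3)
  expect_lt(abs(fit$sd - 80) / 80, 0.1)
  expect_lte(fit$n_molecules, 5000)

  # a second population outside the window leaves the fit unchanged within 1%
  x2 <- c(x, rnorm(3000, 2000, 80))
  h2 <- build_histogram(x2)
  pk2 <- find_peaks(h2, smooth = 3)
  init2 <- init_gaussian(h2, pk2[1, ])
  fit2 <- fit_population(x2, init2, hist = h2)
  expect_lt(abs(fit2$mean - fit$mean) / fit$mean, 0.01)

  expect_error(fit_population(x[1:10], init, hist = h), "need >= 20")
})

test_that("calibration regression matches the normal-equations oracle", {
  # exact line
  cal <- fit_calibration(c(1, 2, 3), c(10, 20, 30), condition = "c1")
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$slope, 10)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)

  set.seed(66)
  for (i in 1:10) {
    x <- runif(5, 1, 100)
    y <- runif(5, 1, 1e4)
    cal <- fit_calibration(x, y, condition = "c1")
    # normal equations by hand
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    expect_lt(abs(cal$slope - slope) / abs(slope), 1e-10)
    expect_lt(abs(cal$intercept - intercept) / abs(intercept), 1e-10)
    # through-origin never improves R^2 relative to the free fit
    cal0 <- fit_calibration(x, y, through_origin = TRUE, condition = "c1")
    expect_lte(cal0$r_squared, cal$r_squared + 1e-12)
    expect_equal(cal0$intercept, 0)
  }
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3), condition = "c1"),
               "degenerate")
  expect_error(fit_calibration(1:3, c(1, 2, 3) * 100, condition = ""),
               "condition")
})

test_that("size conversion propagates prediction error", {
  set.seed(67)
  x <- c(5000, 11000, 26000) + rnorm(3, 0, 100)
  cal <- fit_calibration(x, c(2686, 5562, 12920), condition = "c1")
  # in-sample: recovered size within the residual scatter
  pred <- intensity_to_size(cal, x[2])
  expect_lt(abs(pred$size_bp - 5562), 3 * max(cal$residual_sd, 1))
  # error half-width grows monotonically away from the calibration centroid
  centre <- mean(x)
  probes <- centre + c(0, 4000, 8000, 16000)
  hw <- intensity_to_size(cal, probes)$size_error
  expect_true(all(diff(hw) > 0))
  # negative predicted size flagged
  expect_warning(neg <- intensity_to_size(cal, -20000), "negative")
  expect_false(neg$valid)
  expect_true(neg$extrapolated)
  # cross-condition application warns
  expect_warning(intensity_to_size(cal, x[1], condition = "other"),
                 "condition")
})

test_that("fitted width grows with size while relative width stays fixed", {
  cv <- 0.06
  sizes <- c(2686, 5562, 12920)
  fits <- lapply(sizes, function(s) {
    tab <- gen_intensity_table(list(population_spec(s, 1, cv)), 4000,
                               seed = s)
    fit_all_populations(tab$intensity, n_peaks = 1)[[1]]
  })
  sds <- vapply(fits, `[[`, numeric(1), "sd")
  mus <- vapply(fits, `[[`, numeric(1), "mean")
  expect_true(all(diff(sds) > 0))                 # absolute error grows
  rel <- sds / mus
  expect_lt(max(rel) - min(rel), 0.25 * cv)       # relative error constant
})
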
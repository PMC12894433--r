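# Workflow drivers, exercised on small synthetic datasets written to a
# temporary directory.

small_cfg <- function(...) {
  run_config(n_fields = 2, molecules_per_field = 60,
             imaging = list(field_shape = c(256L, 256L)), seed = 5, ...)
}

test_that("simulate writes a complete, reproducible dataset", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- small_cfg()
  man1 <- cmd_simulate(cfg, d1)
  man2 <- cmd_simulate(cfg, d2)
  tifs <- list.files(d1, pattern = "\\.tif$")
  expect_length(tifs, 2 * cfg$n_fields)
  truth <- read.csv(file.path(d1, "truth.csv"))
  expect_equal(nrow(truth), nrow(man1))
  expect_true(file.exists(file.path(d1, "config_echo.json")))
  # same seed -> byte-identical images
  for (f in tifs)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  expect_error(run_config(nonsense_key = 1), "unknown config key")
})

test_that("config echo reproduces the run bit-for-bit", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cmd_simulate(small_cfg(), d1)
  cfg2 <- read_run_config(file.path(d1, "config_echo.json"))
  cmd_simulate(cfg2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "truth.csv"))),
                   unname(tools::md5sum(file.path(d2, "truth.csv"))))
})

test_that("calibration workflow produces a reusable curve file", {
  d <- withr::local_tempdir()
  out <- withr::local_tempdir()
  # table input: the sizing layers run without the imaging layers
  tab <- gen_intensity_table(calib_populations(), 2000, seed = 7)
  tab$adjusted_intensity <- tab$intensity
  tab$field_id <- rep(1:4, length.out = nrow(tab))
  csv <- file.path(d, "intensities.csv")
  write.csv(tab, csv, row.names = FALSE)
  curve <- cmd_calibrate(csv, c(2686, 5562, 12920), run_config(), out)
  expect_gte(curve$r_squared, 0.99)
  expect_true(file.exists(file.path(out, "calibration.json")))
  rt <- read_calibration(file.path(out, "calibration.json"))
  expect_equal(rt$slope, curve$slope, tolerance = 1e-12)
  expect_equal(rt$r_squared, curve$r_squared, tolerance = 1e-12)

  # through-origin flag is honoured in the stored curve
  out0 <- withr::local_tempdir()
  curve0 <- cmd_calibrate(csv, c(2686, 5562, 12920),
                          run_config(through_origin = TRUE), out0)
  expect_equal(curve0$intercept, 0)
  expect_equal(read_calibration(file.path(out0, "calibration.json"))$intercept, 0)
})

test_that("a missing calibration population is reported by size", {
  d <- withr::local_tempdir(); out <- withr::local_tempdir()
  two <- list(population_spec(2686, 0.5), population_spec(5562, 0.5))
  tab <- gen_intensity_table(two, 2000, seed = 8)
  tab$adjusted_intensity <- tab$intensity
  csv <- file.path(d, "intensities.csv")
  write.csv(tab, csv, row.names = FALSE)
  expect_error(cmd_calibrate(csv, c(2686, 5562, 12920), run_config(), out),
               "12920")
})

test_that("analysis workflow calls populations from intensity tables", {
  d <- withr::local_tempdir(); out <- withr::local_tempdir()
  calout <- withr::local_tempdir()
  ctab <- gen_intensity_table(calib_populations(), 3000, seed = 9)
  ctab$adjusted_intensity <- ctab$intensity
  write.csv(ctab, file.path(d, "cal.csv"), row.names = FALSE)
  cmd_calibrate(file.path(d, "cal.csv"), c(2686, 5562, 12920),
                run_config(), calout)

  bgpop <- list(population_spec(4000, 0.6, 0.6),
                population_spec(9000, 0.4, 0.5))
  tpop <- c(lapply(bgpop, function(p) { p$fraction <- p$fraction * 0.9; p }),
            list(population_spec(2684, 0.1 * 0.9, 0.05),
                 population_spec(5368, 0.1 * 0.1, 0.05)))
  bg <- gen_intensity_table(bgpop, 8000, seed = 10)
  tg <- gen_intensity_table(tpop, 8000, seed = 11)
  for (nm in c("bg", "tg")) {
    tt <- get(nm)
    tt$adjusted_intensity <- tt$intensity
    tt$field_id <- rep(1:8, length.out = nrow(tt))
    write.csv(tt, file.path(d, paste0(nm, ".csv")), row.names = FALSE)
  }
  res <- cmd_analyze(file.path(d, "tg.csv"), file.path(d, "bg.csv"),
                     file.path(calout, "calibration.json"),
                     run_config(k_populations = 2), out)
  expect_true(file.exists(file.path(out, "difference_histogram.csv")))
  expect_true(file.exists(file.path(out, "population_calls.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_equal(nrow(res$calls), 2)
  expect_equal(sum(res$calls$abundance), 1)
  # monomer population called near its true size
  expect_lt(abs(res$calls$size_bp[1] - 2684) / 2684, 0.25)

  # background vs background: near-empty report, no crash
  out2 <- withr::local_tempdir()
  res2 <- cmd_analyze(file.path(d, "bg.csv"), file.path(d, "bg.csv"),
                      file.path(calout, "calibration.json"),
                      run_config(k_populations = 2), out2)
  expect_lt(res2$summary$surviving_fraction, 0.02)
})
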
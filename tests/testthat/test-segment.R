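test_that("edge mask isolates bright spots and ignores flat images", {
  cfg <- clean_config(shape = c(64, 64))
  tr <- data.frame(intensity = 8000, size_bp = 4000L, has_ch2 = FALSE,
                   row = 32, col = 30)
  img <- gen_field(tr, cfg, seed = 1)$ch1
  m <- edge_mask(img)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
  expect_equal(max(lab), 1)
  expect_equal(as.numeric(lab[32, 30]), 1)

  expect_false(any(edge_mask(matrix(7, 32, 32))))

  # two spots farther apart than 6 sigma resolve into two components
  tr2 <- data.frame(intensity = c(8000, 8000), size_bp = 4000L,
                    has_ch2 = FALSE, row = c(25, 25 + ceiling(6 * cfg$psf_sigma) + 2),
                    col = c(32, 32))
  img2 <- gen_field(tr2, cfg, seed = 1)$ch1
  lab2 <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(edge_mask(img2) * 1)))
  expect_equal(max(lab2), 2)
})

test_that("local threshold recovers dim spots on a shaded background", {
  # dim spot on a strongly shaded background: brighter than its local
  # surround but darker than the vignette's bright centre, so any single
  # global threshold either misses it or floods the centre
  set.seed(41)
  nr <- 256
  shade <- punctasizer:::vignette_field(c(nr, nr), 0.3) * 150
  img <- shade + matrix(rnorm(nr * nr, 0, 1), nr, nr)
  spot <- 30 * exp(-(outer((1:nr - 20)^2, (1:nr - 236)^2, `+`)) / (2 * 1.3^2))
  img <- img + spot
  expect_lt(max(img[10:30, 226:246]), max(shade))
  m <- local_mask(img, window = 31, k = 3)
  expect_true(any(m[18:22, 234:238]))
  expect_error(local_mask(img, window = 301), "larger than image")
  expect_false(any(local_mask(matrix(5, 48, 48))))
})

test_that("pure-noise foreground fraction is controlled at k = 5", {
  set.seed(42)
  img <- matrix(rnorm(256 * 256, 100, 5), 256, 256)
  expect_lt(mean(local_mask(img, window = 31, k = 5)), 0.001)
})

test_that("mask merging is a union with area and border filters", {
  a <- matrix(FALSE, 32, 32); b <- a
  a[10:13, 10:13] <- TRUE           # only in edge mask
  b[20:23, 20:23] <- TRUE           # only in local mask
  b[5, 5] <- TRUE                   # 1-px speckle
  b[1, 15:18] <- TRUE               # border-touching
  m <- merge_masks(a, b, min_area = 4, clear_border = TRUE)
  expect_true(all(m[10:13, 10:13]))     # union keeps either source
  expect_true(all(m[20:23, 20:23]))
  expect_false(m[5, 5])                 # speckle removed
  expect_false(any(m[1, ]))             # border component removed
  expect_identical(merge_masks(a, a, min_area = 4), merge_masks(a, a, min_area = 4))
  expect_error(merge_masks(a, matrix(FALSE, 10, 10)), "mismatch")
})

test_that("adjusted intensity equals the spot integral on clean data", {
  cfg <- clean_config(shape = c(64, 64))
  tr <- data.frame(intensity = 10000, size_bp = 5000L, has_ch2 = FALSE,
                   row = 32.3, col = 30.7)
  img <- gen_field(tr, cfg, seed = 1)$ch1
  rec <- segment_field(img)
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$adjusted_intensity - 10000) / 10000, 0.005)

  empty <- label_and_measure(img, matrix(FALSE, 64, 64))
  expect_equal(nrow(empty), 0)
})

test_that("adjusted intensity is offset-invariant and linear", {
  cfg <- noisy_config(shape = c(256, 256), shading_amplitude = 0)
  fl <- gen_field(calib_populations(), cfg, n_molecules = 40, seed = 51)
  rec1 <- segment_field(fl$ch1)
  rec2 <- segment_field(fl$ch1 + 500)      # constant offset
  expect_equal(nrow(rec1), nrow(rec2))
  expect_lt(median(abs(rec2$adjusted_intensity - rec1$adjusted_intensity) /
                     rec1$adjusted_intensity), 0.01)

  # doubling every molecule's intensity doubles the measurements
  tr2 <- fl$truth
  tr2$true_intensity <- tr2$true_intensity * 2
  fl2 <- gen_field(tr2, cfg, seed = 51)
  rec3 <- segment_field(fl2$ch1)
  expect_lt(abs(median(rec3$adjusted_intensity) /
                  median(rec1$adjusted_intensity) - 2) / 2, 0.02)

  # determinism
  expect_identical(segment_field(fl$ch1), segment_field(fl$ch1))
})

test_that("a dense field is recovered against generator truth", {
  cfg <- imaging_config()   # 512 x 512, full noise and shading
  fl <- gen_field(calib_populations(), cfg, n_molecules = 500, seed = 7)
  cw <- correct_with_truth(fl$ch1, cfg)
  det <- denoise(cw$image, "median")
  mask <- merge_masks(edge_mask(det), local_mask(det))
  rec <- label_and_measure(cw$image, mask)
  tru <- fl$truth
  resolvable <- !tru$overlapped &
    tru$row > 10 & tru$row < 503 & tru$col > 10 & tru$col < 503
  d2 <- outer(tru$row, rec$centroid_row, `-`)^2 +
    outer(tru$col, rec$centroid_col, `-`)^2
  nearest <- apply(d2, 1, which.min)
  matched <- apply(d2, 1, min) < 4 & resolvable    # within 2 px
  expect_gte(sum(matched) / sum(resolvable), 0.95)
  relerr <- abs(rec$adjusted_intensity[nearest][matched] / cw$factor -
                  tru$true_intensity[matched]) / tru$true_intensity[matched]
  expect_lt(median(relerr), 0.05)
})
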
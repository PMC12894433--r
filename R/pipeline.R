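# The three workflows: simulate, calibrate, analyze. Each is a thin driver
# over the stage functions; everything it writes is CSV/JSON/TIFF plus a
# config echo so a run can be reproduced from its output directory.

#' Simulate a synthetic experiment to disk
#'
#' Writes per-field 16-bit TIFFs (`field_###_ch1.tif`, `field_###_ch2.tif`),
#' a ground-truth manifest `truth.csv`, and `config_echo.json`.
#'
#' @param config A [run_config()] (or named list of overrides).
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, the truth manifest.
#' @export
cmd_simulate <- function(config = run_config(), out_dir, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_cfg <- config_imaging(cfg)
  exp <- gen_experiment(config_populations(cfg), img_cfg,
                        n_fields = cfg$n_fields,
                        molecules_per_field = cfg$molecules_per_field,
                        seed = cfg$seed)
  for (f in seq_along(exp$fields)) {
    write_field_tiff(exp$fields[[f]]$ch1,
                     file.path(out_dir, sprintf("field_%03d_ch1.tif", f)))
    write_field_tiff(exp$fields[[f]]$ch2,
                     file.path(out_dir, sprintf("field_%03d_ch2.tif", f)))
  }
  man <- exp$manifest
  keep <- intersect(c("molecule_id", "field_id", "row", "col", "size_bp",
                      "true_intensity", "has_ch2", "population_index",
                      "overlapped"), names(man))
  utils::write.csv(man[, keep], file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  write_config_echo(cfg, out_dir)
  invisible(man)
}

# Load a sample: a directory of *_ch1.tif (+ optional *_ch2.tif) fields,
# or a CSV intensity table (column adjusted_intensity or intensity).
load_sample <- function(path) {
  if (dir.exists(path)) {
    ch1 <- sort(list.files(path, pattern = "_ch1\\.tif$", full.names = TRUE))
    if (length(ch1) == 0) stopf("no *_ch1.tif fields in %s", path)
    ch2 <- sub("_ch1\\.tif$", "_ch2.tif", ch1)
    list(kind = "images", ch1_paths = ch1,
         ch2_paths = if (all(file.exists(ch2))) ch2 else NULL)
  } else if (file.exists(path)) {
    tab <- utils::read.csv(path)
    col <- intersect(c("adjusted_intensity", "intensity"), names(tab))
    if (length(col) == 0)
      stopf("%s has neither an adjusted_intensity nor an intensity column", path)
    tab$adjusted_intensity <- tab[[col[1]]]
    if (is.null(tab$field_id)) tab$field_id <- 1L
    list(kind = "table", records = tab)
  } else stopf("input %s does not exist", path)
}

# Run QC + preprocessing + segmentation (+ optional colocalization) over
# the fields of one sample; returns row-bound puncta records.
process_fields <- function(sample, cfg, coloc = FALSE) {
  if (sample$kind == "table") {
    rec <- sample$records
    attr(rec, "n_fields") <- length(unique(rec$field_id))
    return(rec)
  }
  imgs <- lapply(sample$ch1_paths, read_field_tiff)
  qc <- do.call(rbind, lapply(seq_along(imgs), function(i)
    qc_field(imgs[[i]], field_id = i, focus_min = cfg$qc$focus_min,
             max_saturated = cfg$qc$max_saturated,
             saturation_level = cfg$qc$saturation_level)))
  pass <- which(qc$passed)
  if (length(pass) == 0) stopf("no field passed QC")
  shading <- estimate_shading(imgs[pass])
  seg <- cfg$segmentation
  records <- vector("list", length(pass))
  for (j in seq_along(pass)) {
    i <- pass[j]
    corr <- correct_shading(imgs[[i]], shading)
    det <- denoise(corr, cfg$denoise_method)
    mask <- merge_masks(edge_mask(det, close_size = seg$close_size),
                        local_mask(det, window = seg$window, k = seg$k),
                        min_area = seg$min_area,
                        clear_border = seg$clear_border)
    rec <- label_and_measure(corr, mask, field_id = i, grow = seg$grow)
    if (coloc && nrow(rec) > 0) {
      if (is.null(sample$ch2_paths)) stopf("colocalization requested but no *_ch2.tif fields found")
      ch2 <- correct_shading(read_field_tiff(sample$ch2_paths[i]), shading)
      rec <- classify_records(rec, corr, ch2,
                              coloc_thresholds(cfg$coloc$pcc_min,
                                               cfg$coloc$p_max))
    }
    records[[j]] <- rec
  }
  out <- do.call(rbind, records)
  attr(out, "qc") <- qc
  attr(out, "n_fields") <- length(pass)
  out
}

# Given fitted population means and the expected plasmid sizes, pick the
# assignment of peaks to sizes most consistent with one proportionality
# constant; returns indices into `sizes` (NA rows = absent populations).
match_peaks_to_sizes <- function(peak_means, sizes) {
  np <- length(peak_means); ns <- length(sizes)
  if (np > ns) return(NULL)
  combs <- utils::combn(ns, np)
  best <- NULL; best_cost <- Inf
  for (j in seq_len(ncol(combs))) {
    sel <- combs[, j]
    sc <- log(peak_means) - log(sizes[sel])  # peaks and sizes both sorted
    cost <- stats::var(sc)
    if (is.na(cost)) cost <- 0
    if (cost < best_cost) { best_cost <- cost; best <- sel }
  }
  best
}

#' Calibration workflow
#'
#' Runs preprocess -> segment -> population fitting on a calibration
#' sample of known plasmid sizes, regresses size on population mean
#' intensity, and writes the calibration file plus per-population and
#' histogram tables.
#'
#' @param input Directory of field TIFFs, or CSV intensity table.
#' @param known_sizes_bp Known plasmid sizes present in the sample (>= 2).
#' @param config A [run_config()] or named list of overrides.
#' @param out_dir Output directory.
#' @return The `calibration_curve`, invisibly.
#' @export
cmd_calibrate <- function(input, known_sizes_bp, config = run_config(),
                          out_dir) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (length(known_sizes_bp) < 2) stopf("need >= 2 known sizes")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- sort(known_sizes_bp)
  records <- process_fields(load_sample(input), cfg)
  x <- records$adjusted_intensity
  h <- build_histogram(x[x > 0], binwidth = cfg$binwidth)
  pk <- find_peaks(h, smooth = 3)
  if (nrow(pk) > length(sizes)) {
    pk <- pk[order(-pk$height), , drop = FALSE][seq_along(sizes), , drop = FALSE]
    pk <- pk[order(pk$position), , drop = FALSE]
  }
  fits <- lapply(seq_len(nrow(pk)), function(j) {
    init <- init_gaussian(h, pk[j, ])
    if (!init$resolved) stopf("peak at %.4g a.u. is unresolved", pk$position[j])
    fit_population(x, init, hist = h, min_molecules = cfg$min_molecules)
  })
  means <- vapply(fits, `[[`, numeric(1), "mean")
  sel <- match_peaks_to_sizes(means, sizes)
  if (is.null(sel) || length(sel) < length(sizes)) {
    absent <- if (is.null(sel)) sizes else sizes[-sel]
    stopf("no population resolved for known size(s): %s bp",
          paste(absent, collapse = ", "))
  }
  curve <- fit_calibration(means, sizes[sel],
                           through_origin = cfg$through_origin,
                           ci_level = cfg$ci_level,
                           condition = cfg$condition)
  write_calibration(curve, file.path(out_dir, "calibration.json"))
  pop <- data.frame(size_bp = sizes[sel], mean_intensity = means,
                    sd_intensity = vapply(fits, `[[`, numeric(1), "sd"),
                    n_molecules = vapply(fits, `[[`, numeric(1), "n_molecules"))
  utils::write.csv(pop, file.path(out_dir, "populations.csv"), row.names = FALSE)
  utils::write.csv(data.frame(bin_lo = h$bin_edges[-length(h$bin_edges)],
                              bin_hi = h$bin_edges[-1], count = h$counts),
                   file.path(out_dir, "histogram.csv"), row.names = FALSE)
  write_config_echo(cfg, out_dir)
  invisible(curve)
}

#' Analysis workflow
#'
#' Full pipeline on a target and a background sample: segmentation
#' (optionally gated to the dCas9-colocalized fraction), shared-binning
#' intensity histograms, background subtraction, and population calling
#' by exact 1-D k-means mapped through the calibration curve.
#'
#' @param target,background Directories of field TIFFs, or CSV tables.
#' @param curve_file Calibration file from [cmd_calibrate()].
#' @param config A [run_config()] or named list of overrides.
#' @param out_dir Output directory.
#' @param coloc Gate the target molecules to the colocalized fraction.
#' @return Invisibly, a list with `calls`, `diff`, `records`, `summary`.
#' @export
cmd_analyze <- function(target, background, curve_file,
                        config = run_config(), out_dir, coloc = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curve <- read_calibration(curve_file)
  if (!identical(curve$condition, cfg$condition))
    warning(sprintf("calibration condition '%s' != run condition '%s'",
                    curve$condition, cfg$condition), call. = FALSE)
  trec <- process_fields(load_sample(target), cfg, coloc = coloc)
  brec <- process_fields(load_sample(background), cfg, coloc = coloc)
  tx <- trec$adjusted_intensity
  bx <- brec$adjusted_intensity
  if (coloc) tx <- tx[which(trec$colocalized)]
  rng <- range(c(tx[tx > 0], bx[bx > 0]))
  th <- build_histogram(tx[tx > 0], binwidth = cfg$binwidth, range = rng,
                        source = "target", n_fields = attr(trec, "n_fields"))
  bh <- build_histogram(bx[bx > 0], binwidth = diff(th$bin_edges[1:2]),
                        range = rng, source = "background",
                        n_fields = attr(brec, "n_fields"))
  dh <- subtract_background(th, bh, normalization = cfg$normalization)
  res <- tryCatch(residual_sample(dh), error = function(e) numeric(0))
  calls <- NULL
  if (length(res) >= cfg$k_populations && length(unique(res)) >= cfg$k_populations)
    calls <- call_populations(res, cfg$k_populations, curve,
                              condition = cfg$condition)
  molcols <- setdiff(names(trec), "pixels")
  utils::write.csv(trec[, molcols], file.path(out_dir, "molecules_target.csv"),
                   row.names = FALSE)
  utils::write.csv(brec[, molcols],
                   file.path(out_dir, "molecules_background.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(bin_lo = dh$bin_edges[-length(dh$bin_edges)],
                              bin_hi = dh$bin_edges[-1],
                              target = th$counts, background = bh$counts,
                              residual = dh$residual),
                   file.path(out_dir, "difference_histogram.csv"),
                   row.names = FALSE)
  if (!is.null(calls))
    utils::write.csv(as.data.frame(calls),
                     file.path(out_dir, "population_calls.csv"),
                     row.names = FALSE)
  summ <- list(n_target = length(tx), n_background = length(bx),
               surviving_fraction = dh$surviving_fraction,
               clipped_mass = dh$clipped_mass, scale = dh$scale,
               k = cfg$k_populations,
               populations = if (is.null(calls)) list() else calls)
  if (coloc) {
    cs <- coloc_summary(rbind(cbind(trec[, molcols], sample_id = "target"),
                              cbind(brec[, molcols], sample_id = "background")))
    summ$coloc <- cs$per_sample
    utils::write.csv(cs$per_sample, file.path(out_dir, "coloc_summary.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_config_echo(cfg, out_dir)
  invisible(list(calls = calls, diff = dh, records = trec, summary = summ))
}
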
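#' Colocalization thresholds
#'
#' A molecule is called colocalized when the Pearson correlation between
#' the two channels over its pixels exceeds `pcc_min` with a one-sided
#' p-value below `p_max`.
#'
#' @param pcc_min Minimum Pearson correlation (default 0.25).
#' @param p_max Maximum p-value (default 0.05).
#' @return An object of class `coloc_thresholds`.
#' @export
coloc_thresholds <- function(pcc_min = 0.25, p_max = 0.05) {
  if (pcc_min < -1 || pcc_min > 1) stopf("pcc_min must be in [-1, 1]")
  if (p_max <= 0 || p_max > 1) stopf("p_max must be in (0, 1]")
  structure(list(pcc_min = pcc_min, p_max = p_max), class = "coloc_thresholds")
}

#' Pearson correlation of two pixel vectors
#'
#' @param ch1_values,ch2_values Equal-length numeric vectors (n >= 3).
#' @return The correlation in \[-1, 1\], or `NA` when either vector is
#'   constant (undefined correlation; treated downstream as
#'   non-colocalized).
#' @export
pixel_pcc <- function(ch1_values, ch2_values) {
  n <- length(ch1_values)
  if (length(ch2_values) != n) stopf("channel vectors differ in length")
  if (n < 3) stopf("need at least 3 pixels")
  dx <- ch1_values - mean(ch1_values)
  dy <- ch2_values - mean(ch2_values)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / (sx * sy)
}

#' One-sided p-value for a positive Pearson correlation
#'
#' Parametric transform under the null of zero correlation:
#' `t = r sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom,
#' tested one-sided for positive correlation.
#'
#' @param pcc Correlation coefficient.
#' @param n Number of pixel pairs (>= 3).
#' @return The p-value in \[0, 1\] (`NA` for `NA` input).
#' @export
pcc_pvalue <- function(pcc, n) {
  if (n < 3) stopf("need n >= 3")
  if (is.na(pcc)) return(NA_real_)
  if (pcc >= 1) return(0)
  if (pcc <= -1) return(1)
  t <- pcc * sqrt((n - 2) / (1 - pcc^2))
  stats::pt(t, df = n - 2, lower.tail = FALSE)
}

#' Classify puncta records as dCas9-colocalized
#'
#' For each record, the Pearson correlation between the channel-1 and
#' channel-2 intensities is computed over the record's pixels, optionally
#' dilated by 1 px to tolerate sub-pixel channel offsets and PSF bleed.
#' A record is colocalized when `pcc > pcc_min` and `p < p_max`; an
#' undefined correlation (flat channel-2 patch, i.e. no dCas9 signal)
#' classifies as non-colocalized.
#'
#' @param records Puncta records from [label_and_measure()] (the `pixels`
#'   list-column is required).
#' @param ch1,ch2 The two channel images the records were detected on.
#' @param thresholds A [coloc_thresholds()].
#' @param dilate Logical; include a 1-px dilation of each record's pixel
#'   set (set `FALSE` for the exact mask).
#' @return `records` with `ch2_pcc`, `ch2_pvalue`, `colocalized` filled in.
#' @export
classify_records <- function(records, ch1, ch2,
                             thresholds = coloc_thresholds(), dilate = TRUE) {
  stopifnot(inherits(thresholds, "coloc_thresholds"))
  if (!identical(dim(ch1), dim(ch2))) stopf("channel shape mismatch")
  nr <- nrow(ch1); nc <- ncol(ch1)
  for (i in seq_len(nrow(records))) {
    px <- records$pixels[[i]]
    if (max(px) > nr * nc) stopf("record pixels outside image domain")
    if (dilate) px <- dilate_indices(px, nr, nc)
    r <- pixel_pcc(ch1[px], ch2[px])
    p <- pcc_pvalue(r, length(px))
    records$ch2_pcc[i] <- r
    records$ch2_pvalue[i] <- p
    records$colocalized[i] <- !is.na(r) && !is.na(p) &&
      r > thresholds$pcc_min && p < thresholds$p_max
  }
  records
}

# 1-px 8-neighbourhood dilation of a set of linear pixel indices.
dilate_indices <- function(px, nr, nc) {
  r <- ((px - 1) %% nr) + 1
  c <- ((px - 1) %/% nr) + 1
  r2 <- as.vector(outer(r, rep(c(-1L, 0L, 1L), 3), `+`))
  c2 <- as.vector(outer(c, rep(c(-1L, 0L, 1L), each = 3), `+`))
  ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
  sort(unique((c2[ok] - 1L) * nr + r2[ok]))
}

#' Summarise colocalization degree per sample
#'
#' @param records Classified puncta records (possibly several samples
#'   row-bound together).
#' @param sample Vector identifying the sample of each record (defaults to
#'   `records$sample_id`, else one sample).
#' @return A list with `per_sample` (data.frame: sample, n, n_colocalized,
#'   degree_pct) and `mean_pct` / `sd_pct` across samples.
#' @export
coloc_summary <- function(records, sample = NULL) {
  if (nrow(records) == 0) stopf("no records")
  if (is.null(sample))
    sample <- if (!is.null(records$sample_id)) records$sample_id else
      rep("sample", nrow(records))
  cl <- records$colocalized
  if (anyNA(cl)) stopf("records are not classified yet")
  agg <- stats::aggregate(cl, by = list(sample = sample),
                          FUN = function(z) c(n = length(z), k = sum(z)))
  per <- data.frame(sample = agg$sample, n = agg$x[, "n"],
                    n_colocalized = agg$x[, "k"],
                    degree_pct = 100 * agg$x[, "k"] / agg$x[, "n"])
  list(per_sample = per, mean_pct = mean(per$degree_pct),
       sd_pct = stats::sd(per$degree_pct))
}
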
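#' Subtract a background-sample histogram from a target histogram
#'
#' The background sample (e.g. a mock-transduced control) is assumed to
#' represent everything in the target sample that is not of interest; its
#' counts are rescaled, subtracted binwise, and negative residuals are
#' clipped to zero (counts cannot be negative). The clipped mass and the
#' fraction of target molecules surviving subtraction are reported.
#'
#' @param target_hist,bg_hist `intensity_histogram`s with identical bin
#'   edges.
#' @param normalization How to rescale the background counts before
#'   subtraction: `"fields"` (equal analyzed molecules per imaged field —
#'   fields are the sampling unit; requires `n_fields` on both
#'   histograms), `"total"` (equal total molecule counts), `"none"`, or a
#'   numeric scale factor.
#' @param noise_floor Per-bin significance gate in shot-noise SDs: a
#'   residual bin is kept only if it exceeds
#'   `noise_floor * sqrt(target + scale^2 * bg)` (counting noise of the
#'   difference). Without it, Poisson fluctuations in bins where the two
#'   samples agree leak a few percent of spurious positive mass through
#'   the clipping. 0 disables the gate; gated mass is included in
#'   `clipped_mass`.
#' @return An object of class `difference_histogram`: `bin_edges`, `mids`,
#'   `residual` (clipped counts), `scale`, `clipped_mass`,
#'   `surviving_fraction` (of target molecules), `target_source`,
#'   `bg_source`.
#' @export
subtract_background <- function(target_hist, bg_hist, normalization = "fields",
                                noise_floor = 2) {
  stopifnot(inherits(target_hist, "intensity_histogram"),
            inherits(bg_hist, "intensity_histogram"))
  if (length(target_hist$bin_edges) != length(bg_hist$bin_edges) ||
      max(abs(target_hist$bin_edges - bg_hist$bin_edges)) > 1e-9)
    stopf("histogram binning mismatch between target and background")
  scale <- if (is.numeric(normalization)) {
    normalization
  } else if (normalization == "fields") {
    if (is.na(target_hist$n_fields) || is.na(bg_hist$n_fields))
      stopf("normalization 'fields' needs n_fields on both histograms")
    as.numeric(target_hist$n_fields) / bg_hist$n_fields
  } else if (normalization == "total") {
    target_hist$n_total / bg_hist$n_total
  } else if (normalization == "none") {
    1
  } else stopf("unknown normalization '%s'", normalization)
  diffc <- target_hist$counts - scale * bg_hist$counts
  residual <- pmax(diffc, 0)
  if (noise_floor > 0) {
    sd_diff <- sqrt(target_hist$counts + scale^2 * bg_hist$counts)
    residual[diffc < noise_floor * sd_diff] <- 0
  }
  structure(list(bin_edges = target_hist$bin_edges, mids = target_hist$mids,
                 residual = residual, scale = scale,
                 clipped_mass = -sum(diffc[diffc < 0]) +
                   sum(pmax(diffc, 0)[residual == 0]),
                 surviving_fraction = sum(residual) / target_hist$n_total,
                 target_source = target_hist$source,
                 bg_source = bg_hist$source),
            class = "difference_histogram")
}

#' Realize a difference histogram as representative intensities
#'
#' Bridges the binwise residual to molecule-level clustering: each bin
#' contributes `round(residual)` copies of its bin-centre intensity.
#'
#' @param diff A `difference_histogram`.
#' @return Numeric vector of length `sum(round(residual))`.
#' @export
residual_sample <- function(diff) {
  stopifnot(inherits(diff, "difference_histogram"))
  counts <- round(diff$residual)
  if (sum(counts) == 0) stopf("residual histogram has no mass")
  rep(diff$mids, counts)
}

#' Exact 1-D k-means
#'
#' Globally optimal k-means partition of a numeric vector. In one
#' dimension the optimal clusters are contiguous in sorted order, so the
#' optimum is found by dynamic programming over weighted unique values
#' (no seeding, no restarts: the result is deterministic and exact).
#'
#' @param values Numeric vector (n >= k).
#' @param k Number of clusters (>= 1).
#' @param weights Optional non-negative weights (counts) per value.
#' @return An object of class `kmeans1d`: `cluster` (assignment per input
#'   value, ordered clusters), `centers` (cluster means, increasing),
#'   `size` (weighted member counts), `withinss` (per cluster),
#'   `tot_withinss`.
#' @export
kmeans_1d <- function(values, k, weights = NULL) {
  n <- length(values)
  if (k < 1) stopf("k must be >= 1")
  if (n < k) stopf("k = %d exceeds number of values (%d)", k, n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) stopf("bad weights")
  ord <- order(values)
  # collapse duplicates to weighted unique values
  ux <- unique(values[ord])
  uw <- as.vector(rowsum(weights[ord], match(values[ord], ux)))
  m <- length(ux)
  if (m < k) stopf("k = %d exceeds number of distinct values (%d)", k, m)
  cw <- cumsum(uw)
  cwx <- cumsum(uw * ux)
  cwx2 <- cumsum(uw * ux^2)
  D <- matrix(Inf, k, m)
  B <- matrix(0L, k, m)
  cost1 <- cwx2 - cwx^2 / cw
  D[1, ] <- cost1
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:m) {
        i <- (q - 1):(j - 1)   # last split point: cluster q covers (i, j]
        w <- cw[j] - cw[i]
        sx <- cwx[j] - cwx[i]
        sx2 <- cwx2[j] - cwx2[i]
        cand <- D[q - 1, i] + (sx2 - sx^2 / w)
        b <- which.min(cand)
        D[q, j] <- cand[b]
        B[q, j] <- i[b]
      }
    }
  }
  # backtrack cluster boundaries
  bounds <- integer(k + 1)
  bounds[k + 1] <- m
  if (k > 1) for (q in k:2) bounds[q] <- B[q, bounds[q + 1]]
  bounds[1] <- 0
  assign_u <- integer(m)
  centers <- numeric(k); size <- numeric(k); wss <- numeric(k)
  for (q in seq_len(k)) {
    idx <- (bounds[q] + 1):bounds[q + 1]
    assign_u[idx] <- q
    size[q] <- sum(uw[idx])
    centers[q] <- sum(uw[idx] * ux[idx]) / size[q]
    wss[q] <- sum(uw[idx] * (ux[idx] - centers[q])^2)
  }
  structure(list(cluster = assign_u[match(values, ux)], centers = centers,
                 size = size, withinss = wss, tot_withinss = sum(wss)),
            class = "kmeans1d")
}

#' Advisory elbow report for choosing k
#'
#' Total within-cluster SS of the exact solver for k = 1..k_max; the
#' number of populations is a user decision, this merely informs it.
#'
#' @param values Numeric vector.
#' @param k_max Largest k to evaluate.
#' @param weights Optional weights.
#' @return data.frame with `k` and `tot_withinss`.
#' @export
kmeans_1d_elbow <- function(values, k_max = 6, weights = NULL) {
  k_max <- min(k_max, length(unique(values)))
  data.frame(k = seq_len(k_max),
             tot_withinss = vapply(seq_len(k_max), function(k)
               kmeans_1d(values, k, weights)$tot_withinss, numeric(1)))
}

#' Call population sizes and abundances
#'
#' Clusters intensities with the exact 1-D k-means, maps each cluster mean
#' to base pairs through the calibration curve, and reports relative
#' abundances over all clustered molecules.
#'
#' @param values Molecule intensities (e.g. from [residual_sample()] or
#'   the colocalized fraction).
#' @param k Number of populations to call.
#' @param curve A `calibration_curve`.
#' @param condition Sample condition tag checked against the curve.
#' @param min_cluster_fraction Clusters below this abundance are flagged
#'   (`supported = FALSE`) as too sparse to claim a true subpopulation.
#' @return A data.frame of class `population_calls`: `cluster`, `n`,
#'   `mean_intensity`, `size_bp`, `size_error`, `abundance`, `supported`.
#' @export
call_populations <- function(values, k, curve, condition = curve$condition,
                             min_cluster_fraction = 0.01) {
  km <- kmeans_1d(values, k)
  sz <- intensity_to_size(curve, km$centers, condition = condition)
  out <- data.frame(cluster = seq_len(k), n = km$size,
                    mean_intensity = km$centers, size_bp = sz$size_bp,
                    size_error = sz$size_error,
                    abundance = km$size / sum(km$size))
  out$supported <- out$abundance >= min_cluster_fraction
  class(out) <- c("population_calls", class(out))
  out
}
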
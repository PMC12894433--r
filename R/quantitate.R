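#' Fit a qPCR standard curve
#'
#' Linear fit of cycle threshold against log10 initial copy number. The
#' slope of a perfectly efficient reaction is -log2(10) = -3.3219 cycles
#' per decade; efficiency is reported as `10^(-1/slope) - 1`.
#'
#' @param copies Known copy numbers of the dilution series (>= 3 points).
#' @param ct Measured Ct values.
#' @return Object of class `standard_curve`: `slope` (Ct per log10
#'   copies), `intercept` (Ct at 1 copy), `r_squared`, `efficiency`,
#'   `copy_range`, and the fitted `model`.
#' @export
fit_standard_curve <- function(copies, ct) {
  if (length(copies) != length(ct)) stopf("copies and ct lengths differ")
  if (length(copies) < 3) stopf("need >= 3 standard points")
  if (any(copies <= 0)) stopf("copy numbers must be positive")
  d <- data.frame(log_copies = log10(copies), ct = ct)
  if (stats::var(d$log_copies) == 0) stopf("degenerate dilution series")
  model <- stats::lm(ct ~ log_copies, data = d)
  slope <- unname(stats::coef(model)[["log_copies"]])
  ss_res <- sum(stats::residuals(model)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(model)[["(Intercept)"]]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 efficiency = 10^(-1 / slope) - 1,
                 copy_range = range(copies), model = model),
            class = "standard_curve")
}

#' Invert a standard curve: Ct to copy number
#'
#' @param curve A `standard_curve`.
#' @param ct Ct values.
#' @return Estimated initial copy numbers.
#' @export
ct_to_copies <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Gate conditions against the limit of detection
#'
#' The no-template control defines the background Ct (limit of detection);
#' only conditions amplifying earlier than the NTC (smaller Ct, i.e. more
#' template than background) are included.
#'
#' @param ct_values Named or unnamed Ct values per condition.
#' @param ntc_ct Ct of the no-template control.
#' @return Logical vector: `TRUE` = included.
#' @export
lod_gate <- function(ct_values, ntc_ct) {
  if (missing(ntc_ct) || length(ntc_ct) != 1 || !is.finite(ntc_ct))
    stopf("a finite no-template-control Ct is required")
  if (any(!is.finite(ct_values))) stopf("Ct values must be finite")
  ct_values < ntc_ct
}

#' Convert copy number to DNA mass
#'
#' `mass = copies * size_bp * mean_bp_mass / N_A`, reported in picograms.
#'
#' @param copies Copy number (>= 0).
#' @param size_bp Molecule size in base pairs (> 0).
#' @param mean_bp_mass Average mass of one base pair in Daltons (g/mol);
#'   650 is the standard double-stranded DNA value.
#' @return Mass in pg.
#' @export
copies_to_mass <- function(copies, size_bp, mean_bp_mass = 650) {
  if (any(copies < 0)) stopf("copies must be >= 0")
  if (any(size_bp <= 0)) stopf("size_bp must be > 0")
  copies * size_bp * mean_bp_mass / 6.02214076e23 * 1e12
}

#' Predict surface density and per-field molecule counts
#'
#' @param copies Number of molecules deposited.
#' @param deposition_area_um2 Area the sample spreads over, um^2.
#' @param field_area_um2 Area of one imaged field, um^2. The default
#'   1.5e4 is inferred from a deposition regime of 1 molecule per 15 um^2
#'   yielding ~1000 molecules per field.
#' @return A list: `density_per_um2`, `um2_per_molecule`,
#'   `expected_per_field`.
#' @export
density_estimate <- function(copies, deposition_area_um2,
                             field_area_um2 = 1.5e4) {
  if (deposition_area_um2 <= 0 || field_area_um2 <= 0)
    stopf("areas must be positive")
  if (copies < 0) stopf("copies must be >= 0")
  density <- copies / deposition_area_um2
  list(density_per_um2 = density,
       um2_per_molecule = if (density > 0) 1 / density else Inf,
       expected_per_field = density * field_area_um2)
}

#' Full qPCR quantitation chain for one condition
#'
#' Standard curve -> copies -> mass -> mass fraction -> surface density.
#' Reports every intermediate so unit inconsistencies stay visible.
#'
#' @param curve A `standard_curve`.
#' @param ct Condition Ct.
#' @param size_bp Assumed size of one copy, bp.
#' @param sample_mass_pg Total DNA mass the copies are contained in, pg.
#' @param deposited_mass_pg Mass deposited for imaging, pg.
#' @param deposition_area_um2 Deposition area, um^2.
#' @param field_area_um2 Field of view area, um^2.
#' @param mean_bp_mass Mass per bp, Da.
#' @return data.frame with copies, mass_pg, mass_fraction,
#'   deposited_copies, density_per_um2, um2_per_molecule,
#'   expected_per_field.
#' @export
quantitate_condition <- function(curve, ct, size_bp = 2684,
                                 sample_mass_pg, deposited_mass_pg,
                                 deposition_area_um2,
                                 field_area_um2 = 1.5e4,
                                 mean_bp_mass = 650) {
  copies <- ct_to_copies(curve, ct)
  mass_pg <- copies_to_mass(copies, size_bp, mean_bp_mass)
  frac <- mass_pg / sample_mass_pg
  dep_copies <- copies * deposited_mass_pg / sample_mass_pg
  de <- density_estimate(dep_copies, deposition_area_um2, field_area_um2)
  data.frame(copies = copies, mass_pg = mass_pg, mass_fraction = frac,
             deposited_copies = dep_copies,
             density_per_um2 = de$density_per_um2,
             um2_per_molecule = de$um2_per_molecule,
             expected_per_field = de$expected_per_field)
}
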
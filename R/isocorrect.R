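# Isotope data reduction: calibration of raw ratios and corrections producing
# analysis-ready d15N / d18O / D17O values. All delta values are per mil (‰)
# on the AIR (nitrogen) and VSMOW (oxygen) scales; no ratio-space conversion.

#' Triple-oxygen isotope anomaly
#'
#' Computes the mass-independent oxygen isotope anomaly
#' \eqn{\Delta^{17}O = \delta^{17}O - \lambda\,\delta^{18}O}, the offset of a
#' sample from the terrestrial (mass-dependent) fractionation line. Nitrate
#' oxidised in the atmosphere inherits excess 17-O from ozone and plots above
#' the line; nitrate cycled through terrestrial or freshwater systems has
#' \eqn{\Delta^{17}O \approx 0}.
#'
#' @param d17O delta-17O of the sample (per mil, VSMOW).
#' @param d18O delta-18O of the sample (per mil, VSMOW).
#' @param lambda slope of the terrestrial fractionation line (default 0.52).
#' @return Delta-17O in per mil. Vectorised over `d17O`/`d18O`.
#' @examples
#' delta17O_excess(58.02, 66.0)  # snow-like nitrate, ~ +23.7
#' @export
delta17O_excess <- function(d17O, d18O, lambda = 0.52) {
  stopifnot(is.numeric(d17O), is.numeric(d18O), length(lambda) == 1L,
            is.finite(lambda), lambda > 0)
  if (any(!is.finite(d17O)) || any(!is.finite(d18O)))
    stop("delta17O_excess: non-finite delta values", call. = FALSE)
  d17O - lambda * d18O
}

#' Estimate the mass-overlap offset coefficient for delta-15N
#'
#' The 15N-14N-16O and 14N-14N-17O isotopologues of N2O share mass 45. Standard
#' ('Craig') data reduction assumes mass-dependent 17-O abundance, so samples
#' with a non-zero Delta-17O acquire a spurious delta-15N offset proportional
#' to the anomaly. The coefficient is estimated from a standard of known
#' Delta-17O (conventionally USGS-35) as
#' `(calibrated d15N - true d15N) / calibrated Delta-17O`.
#'
#' @param d15N_cal_std calibrated delta-15N measured for the standard (per mil).
#' @param d15N_true_std accepted delta-15N of the standard (per mil).
#' @param D17O_cal_std calibrated Delta-17O of the standard (per mil); must be
#'   non-zero.
#' @param standard name used in error messages (default "USGS-35").
#' @return Offset in per mil delta-15N per per mil Delta-17O.
#' @seealso [correct_d15N_mass_overlap()]
#' @export
estimate_xcorr <- function(d15N_cal_std, d15N_true_std, D17O_cal_std,
                           standard = "USGS-35") {
  stopifnot(is.finite(d15N_cal_std), is.finite(d15N_true_std),
            is.finite(D17O_cal_std))
  if (D17O_cal_std == 0)
    stop(sprintf("estimate_xcorr: Delta-17O of standard '%s' is zero; cannot form the offset ratio",
                 standard), call. = FALSE)
  (d15N_cal_std - d15N_true_std) / D17O_cal_std
}

#' Correct delta-15N for the mass-independent isotopologue overlap
#'
#' Subtracts `xcorr * Delta17O` from the calibrated delta-15N. At the default
#' coefficient of 0.1 per mil per per mil, a sample with Delta-17O of +30 per
#' mil has its delta-15N lowered by 3 per mil. Samples with missing Delta-17O
#' (e.g. nitrate too dilute to measure the anomaly) are returned unchanged;
#' use [apply_corrections()] to carry the corrected/uncorrected flag on a
#' sample table.
#'
#' @param d15N_cal calibrated delta-15N (per mil); vectorised.
#' @param D17O_sample Delta-17O of each sample (per mil); `NA` allowed.
#' @param xcorr overlap coefficient (per mil / per mil, default 0.1).
#' @return Corrected delta-15N (per mil).
#' @export
correct_d15N_mass_overlap <- function(d15N_cal, D17O_sample, xcorr = 0.1) {
  stopifnot(is.numeric(d15N_cal), is.numeric(D17O_sample),
            length(xcorr) == 1L, is.finite(xcorr))
  if (any(!is.finite(d15N_cal)))
    stop("correct_d15N_mass_overlap: non-finite d15N", call. = FALSE)
  if (any(is.infinite(D17O_sample)))
    stop("correct_d15N_mass_overlap: non-finite Delta-17O", call. = FALSE)
  corr <- ifelse(is.na(D17O_sample), 0, xcorr * D17O_sample)
  d15N_cal - corr
}

#' Correct delta-18O for oxygen exchange with laboratory water
#'
#' During the chemical conversion of nitrate to N2O a fraction `f` of the
#' oxygen in the measured product derives from exchange with water oxygen
#' rather than from the original nitrate. Treating the measured value as a
#' two-component mixture, `measured = (1 - f) * nitrate + f * water`, the
#' nitrate value is recovered by inversion:
#' `(d18O_measured - f * water_d18O) / (1 - f)`.
#'
#' @param d18O_measured measured delta-18O of the analyte (per mil, VSMOW).
#' @param water_d18O delta-18O of the laboratory water (per mil, VSMOW).
#' @param f fraction of oxygen exchanged, in `[0, 1)` (default 0.13).
#' @return delta-18O of the original nitrate (per mil).
#' @export
correct_d18O_water_exchange <- function(d18O_measured, water_d18O, f = 0.13) {
  stopifnot(is.numeric(d18O_measured), is.numeric(water_d18O),
            length(f) == 1L, is.finite(f))
  if (f < 0 || f >= 1)
    stop("correct_d18O_water_exchange: exchange fraction f must be in [0, 1)",
         call. = FALSE)
  (d18O_measured - f * water_d18O) / (1 - f)
}

#' Correction parameter set
#'
#' Bundles the parameters of the data-reduction corrections.
#'
#' @param xcorr delta-15N mass-overlap coefficient (per mil / per mil).
#' @param exchange_fraction fraction of N2O oxygen exchanged with water,
#'   in `[0, 1)`.
#' @param water_d18O delta-18O of laboratory water (per mil, VSMOW). The
#'   default of -10 is typical of mid-latitude continental tap water and
#'   should be replaced with the measured value for the laboratory.
#' @param tfl_slope slope of the terrestrial fractionation line.
#' @return An object of class `correction_parameters`.
#' @export
correction_parameters <- function(xcorr = 0.1, exchange_fraction = 0.13,
                                  water_d18O = -10, tfl_slope = 0.52) {
  stopifnot(is.finite(xcorr), is.finite(water_d18O),
            is.finite(exchange_fraction), exchange_fraction >= 0,
            exchange_fraction < 1, is.finite(tfl_slope), tfl_slope > 0)
  structure(list(xcorr = xcorr, exchange_fraction = exchange_fraction,
                 water_d18O = water_d18O, tfl_slope = tfl_slope),
            class = "correction_parameters")
}

#' @export
print.correction_parameters <- function(x, ...) {
  cat("Isotope correction parameters\n")
  cat(sprintf("  xcorr:             %.3g permil d15N per permil D17O\n", x$xcorr))
  cat(sprintf("  exchange fraction: %.3g\n", x$exchange_fraction))
  cat(sprintf("  water d18O:        %.3g permil VSMOW\n", x$water_d18O))
  cat(sprintf("  TFL slope:         %.3g\n", x$tfl_slope))
  invisible(x)
}

#' Apply data-reduction corrections to a calibrated sample table
#'
#' Applies, in order: the water-exchange correction to `d18O`, recomputation of
#' `D17O` from `d17O`/`d18O` where both are present, and the delta-15N
#' mass-overlap correction. Samples without a measurable Delta-17O keep their
#' uncorrected delta-15N and are flagged `d15N_corrected_flag = FALSE`.
#' A `D17O` column supplied directly (without `d17O`) is taken as final and
#' passed through unscaled.
#'
#' @param samples data frame with at least `d15N`, `d18O`, and either `d17O`
#'   or `D17O` columns (see [read_samples_csv()] for the schema).
#' @param params a [correction_parameters()] object.
#' @return The sample table with corrected values and a logical
#'   `d15N_corrected_flag` column.
#' @export
apply_corrections <- function(samples, params = correction_parameters()) {
  stopifnot(is.data.frame(samples), inherits(params, "correction_parameters"))
  for (col in c("d15N", "d18O"))
    if (!col %in% names(samples))
      stop(sprintf("apply_corrections: missing column '%s'", col), call. = FALSE)
  out <- samples
  out$d18O <- correct_d18O_water_exchange(out$d18O, params$water_d18O,
                                          params$exchange_fraction)
  if (!"d17O" %in% names(out)) out$d17O <- NA_real_
  # exchange with (mass-dependent, D17O = 0) water dilutes the anomaly by
  # (1 - f); inverting d17O against water at tfl_slope * water_d18O restores
  # D17O_nitrate = D17O_measured / (1 - f)
  has17 <- !is.na(out$d17O)
  out$d17O[has17] <- correct_d18O_water_exchange(
    out$d17O[has17], params$tfl_slope * params$water_d18O,
    params$exchange_fraction)
  D17O <- rep(NA_real_, nrow(out))
  D17O[has17] <- delta17O_excess(out$d17O[has17], out$d18O[has17],
                                 params$tfl_slope)
  if ("D17O" %in% names(out)) {
    keep <- !has17 & !is.na(out$D17O)
    D17O[keep] <- out$D17O[keep]
  }
  out$D17O <- D17O
  out$d15N <- correct_d15N_mass_overlap(out$d15N, out$D17O, params$xcorr)
  out$d15N_corrected_flag <- !is.na(out$D17O)
  out
}
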
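# Standard-based linear calibration of raw isotope ratios to the AIR (d15N)
# and VSMOW (d18O, d17O) scales.

#' Published reference values for nitrate isotope standards
#'
#' Consensus values for the international reference materials USGS-32, USGS-34
#' and USGS-35, the IAEA-NO-3 accuracy-check standard, and the GSI-NO-3
#' internal standard (delta-15N = +1.3, delta-18O = +14.13 per mil). Shipped
#' as an editable CSV in `inst/extdata/reference_standards.csv`; laboratories
#' should substitute their own in-use values.
#'
#' @param path optional path to an alternative CSV with columns
#'   `standard_name, d15N, d18O, d17O` (empty cells allowed).
#' @return Data frame of reference values (per mil).
#' @export
reference_standards <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_standards.csv",
                        package = "no3apport", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("standard_name", "d15N", "d18O")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("reference_standards: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out
}

#' Read an instrument run sheet
#'
#' A run sheet lists, per analysis run, the raw delta values of unknowns and
#' bracketing standards. Required columns: `run_id, sample_id, role,
#' standard_name, raw_d15N, raw_d18O, raw_d17O` (the last may be empty).
#' `role` is `"standard"` or `"unknown"`; an optional `group` column carries
#' the sample group label through to the reduced data.
#'
#' @param path CSV file path.
#' @return Data frame of run entries.
#' @export
read_run_sheet <- function(path) {
  if (!file.exists(path))
    stop("read_run_sheet: file not found: ", path, call. = FALSE)
  run <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "sample_id", "role", "standard_name",
            "raw_d15N", "raw_d18O")
  miss <- setdiff(need, names(run))
  if (length(miss))
    stop("read_run_sheet: missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"raw_d17O" %in% names(run)) run$raw_d17O <- NA_real_
  bad <- !run$role %in% c("standard", "unknown")
  if (any(bad))
    stop("read_run_sheet: role must be 'standard' or 'unknown' (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  run
}

#' Linear calibration of one tracer against reference standards
#'
#' Ordinary least squares of the accepted reference values on the raw measured
#' values of the standards in a run; unknowns are mapped through the fitted
#' line `calibrated = slope * raw + intercept`. With exactly two (distinct)
#' standards the line interpolates both exactly.
#'
#' @param run a run-sheet data frame (see [read_run_sheet()]).
#' @param tracer one of `"d15N"`, `"d18O"`, `"d17O"`; the raw column used is
#'   `paste0("raw_", tracer)`.
#' @param reference_values named numeric vector mapping `standard_name` to the
#'   accepted value (per mil), or a data frame as from
#'   [reference_standards()].
#' @return List with `slope`, `intercept`, `calibrated` (numeric vector
#'   aligned with the rows of `run`), and `residuals` (per standard).
#' @export
calibrate_linear <- function(run, tracer, reference_values) {
  stopifnot(is.data.frame(run), tracer %in% c("d15N", "d18O", "d17O"))
  rawcol <- paste0("raw_", tracer)
  if (!rawcol %in% names(run))
    stop("calibrate_linear: run sheet lacks column ", rawcol, call. = FALSE)
  if (is.data.frame(reference_values)) {
    rv <- reference_values[[tracer]]
    names(rv) <- reference_values$standard_name
    reference_values <- rv[!is.na(rv)]
  }
  std <- run$role == "standard" & run$standard_name %in% names(reference_values)
  raw <- run[[rawcol]][std]
  ref <- unname(reference_values[run$standard_name[std]])
  ok <- is.finite(raw) & is.finite(ref)
  raw <- raw[ok]; ref <- ref[ok]
  if (length(unique(ref)) < 2L)
    stop("calibrate_linear: need >= 2 standards with distinct reference values for ",
         tracer, call. = FALSE)
  if (length(unique(raw)) < 2L)
    stop("calibrate_linear: standard raw values are all identical for ",
         tracer, call. = FALSE)
  fit <- stats::lm(ref ~ raw)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  list(slope = slope, intercept = intercept,
       calibrated = slope * run[[rawcol]] + intercept,
       residuals = unname(stats::residuals(fit)))
}

#' Reduce a run sheet to an analysis-ready sample table
#'
#' Calibrates each tracer present in the run against the standards, then
#' applies the data-reduction corrections ([apply_corrections()]). One row per
#' unknown is returned in the [read_samples_csv()] schema.
#'
#' @param run a run-sheet data frame.
#' @param reference_values as for [calibrate_linear()]; defaults to
#'   [reference_standards()].
#' @param params a [correction_parameters()] object.
#' @return Analysis-ready sample data frame.
#' @export
reduce_run <- function(run, reference_values = reference_standards(),
                       params = correction_parameters()) {
  cal15 <- calibrate_linear(run, "d15N", reference_values)
  cal18 <- calibrate_linear(run, "d18O", reference_values)
  has17 <- any(is.finite(run$raw_d17O[run$role == "standard"]))
  cal17 <- if (has17) {
    tryCatch(calibrate_linear(run, "d17O", reference_values),
             error = function(e) NULL)
  }
  unk <- run$role == "unknown"
  samples <- data.frame(
    sample_id = run$sample_id[unk],
    group = if ("group" %in% names(run)) run$group[unk] else "other",
    d15N = cal15$calibrated[unk],
    d18O = cal18$calibrated[unk],
    d17O = if (!is.null(cal17)) cal17$calibrated[unk] else NA_real_,
    no3_uM = if ("no3_uM" %in% names(run)) run$no3_uM[unk] else NA_real_,
    nh4_uM = if ("nh4_uM" %in% names(run)) run$nh4_uM[unk] else NA_real_,
    stringsAsFactors = FALSE
  )
  apply_corrections(samples, params)
}
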
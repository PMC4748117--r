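# Sample table readers/writers and the survey's sample-selection rules.

.group_levels <- c("snow", "inflow", "lake", "snowmelt", "other")

.sample_cols <- c("sample_id", "group", "d15N", "d18O", "d17O", "D17O",
                  "no3_uM", "nh4_uM", "d15N_corrected_flag")

#' Read an analysis-ready sample table
#'
#' Comma-separated, UTF-8, header required, '.' decimal, empty cell =
#' missing. Required columns: `sample_id, group, d15N, d18O, no3_uM, nh4_uM`;
#' optional: `d17O`, `D17O`, `d15N_corrected_flag`. Group labels come from
#' the closed vocabulary snow/inflow/lake/snowmelt/other; unknown labels are
#' an error. Rows with missing Delta-17O are retained and flagged
#' (`d15N_corrected_flag = FALSE`). Where both `d17O` and `d18O` are present,
#' the stored `D17O` is checked against `d17O - 0.52 * d18O`.
#'
#' @param path CSV file path.
#' @param tfl_slope slope used for the consistency check (default 0.52).
#' @return Validated sample data frame.
#' @export
read_samples_csv <- function(path, tfl_slope = 0.52) {
  if (!file.exists(path))
    stop("read_samples_csv: file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "d15N", "d18O", "no3_uM", "nh4_uM")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("read_samples_csv: missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  x$sample_id <- as.character(x$sample_id)
  x$group <- as.character(x$group)
  if (nrow(x) == 0L) {
    warning("read_samples_csv: empty data section in ", path, call. = FALSE)
    for (col in setdiff(.sample_cols, names(x)))
      x[[col]] <- if (col == "d15N_corrected_flag") logical(0) else numeric(0)
    return(x[, .sample_cols])
  }
  bad <- !x$group %in% .group_levels
  if (any(bad))
    stop("read_samples_csv: unknown group label(s): ",
         paste(unique(x$group[bad]), collapse = ", "),
         " (rows ", paste(which(bad), collapse = ", "), ")", call. = FALSE)
  for (col in c("d15N", "d18O", "d17O", "D17O", "no3_uM", "nh4_uM")) {
    if (!col %in% names(x)) { x[[col]] <- NA_real_; next }
    if (!is.numeric(x[[col]])) {
      conv <- suppressWarnings(as.numeric(x[[col]]))
      badrow <- which(!is.na(x[[col]]) & x[[col]] != "" & is.na(conv))
      if (length(badrow))
        stop("read_samples_csv: malformed numeric cells in '", col,
             "' at row(s) ", paste(badrow, collapse = ", "), call. = FALSE)
      x[[col]] <- conv
    }
  }
  neg <- which(x$no3_uM < 0 | x$nh4_uM < 0)
  if (length(neg))
    stop("read_samples_csv: negative concentration(s) at row(s) ",
         paste(neg, collapse = ", "), call. = FALSE)
  both <- !is.na(x$d17O) & !is.na(x$d18O)
  if ("D17O" %in% names(x)) {
    chk <- both & !is.na(x$D17O)
    off <- which(chk & abs(x$D17O - (x$d17O - tfl_slope * x$d18O)) > 1e-9)
    if (length(off))
      stop("read_samples_csv: D17O inconsistent with d17O - ", tfl_slope,
           " * d18O at row(s) ", paste(off, collapse = ", "), call. = FALSE)
  }
  x$D17O <- ifelse(both, x$d17O - tfl_slope * x$d18O, x$D17O)
  if (!"d15N_corrected_flag" %in% names(x))
    x$d15N_corrected_flag <- !is.na(x$D17O)
  x$d15N_corrected_flag <- as.logical(x$d15N_corrected_flag)
  x[, .sample_cols]
}

#' Write a sample table to CSV
#'
#' @param samples sample data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(samples, path) {
  stopifnot(is.data.frame(samples))
  utils::write.csv(samples, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the survey's sample-selection rules
#'
#' Excludes, with machine-readable reasons: samples whose nitrate
#' concentration is not strictly above the threshold
#' (`below_no3_threshold`), samples in transitional groups such as snowmelt
#' (`transitional_group`), and -- when filtering for model fitting -- samples
#' lacking a Delta-17O value (`missing_D17O`). Kept and excluded partitions
#' are disjoint and together restore the input; filtering is idempotent.
#'
#' @param records sample data frame.
#' @param min_no3_uM nitrate threshold in uM N; kept samples satisfy
#'   `no3_uM > min_no3_uM` strictly (default 1.6).
#' @param excluded_groups group labels excluded outright
#'   (default `"snowmelt"`).
#' @param for_fitting if `TRUE` (default) also exclude samples without
#'   Delta-17O, which cannot enter a Delta-17O-based model fit.
#' @return List with `kept` (data frame) and `excluded` (data frame with an
#'   extra `reason` column).
#' @export
filter_samples <- function(records, min_no3_uM = 1.6,
                           excluded_groups = "snowmelt", for_fitting = TRUE) {
  stopifnot(is.data.frame(records), min_no3_uM >= 0)
  reason <- rep(NA_character_, nrow(records))
  grp <- records$group %in% excluded_groups
  reason[grp] <- "transitional_group"
  low <- is.na(reason) &
    (is.na(records$no3_uM) | records$no3_uM <= min_no3_uM)
  reason[low] <- "below_no3_threshold"
  if (for_fitting) {
    no17 <- is.na(reason) & is.na(records$D17O)
    reason[no17] <- "missing_D17O"
  }
  excluded <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!is.na(reason)]
  else excluded$reason <- character(0)
  list(kept = records[is.na(reason), , drop = FALSE], excluded = excluded)
}
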
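# Closed-form calculators: snowpack ammonium delta-15N mass balance, the
# tropospheric NOx budget scaling, and the anthropogenic-share roll-up.

#' Snowpack ammonium delta-15N by isotope mass balance
#'
#' Snowpack nitrogen is delivered partly as ammonium, which is nitrified on
#' release to soils and streams. Assuming the inflow delta-15N integrates the
#' combined isotopic composition of snow ammonium and nitrate, that the snow
#' nitrate delta-15N equals the measured snow delta-15N, and negligible
#' fractionation during nitrification, the snow ammonium delta-15N solves the
#' balance
#' `d15N_inflow * (nh4 + no3) = d15N_nh4 * nh4 + d15N_snow * no3`.
#'
#' @param d15N_inflow mean inflow delta-15N of nitrate (per mil).
#' @param d15N_snow mean snow delta-15N of nitrate (per mil).
#' @param nh4_snow snow ammonium concentration (uM N, > 0).
#' @param no3_snow snow nitrate concentration (uM N, >= 0).
#' @return delta-15N of snow ammonium (per mil).
#' @examples
#' snow_ammonium_d15N(-1.6, 0.9, 5.8, 6.73)  # about -4.5
#' @export
snow_ammonium_d15N <- function(d15N_inflow, d15N_snow, nh4_snow, no3_snow) {
  stopifnot(all(is.finite(d15N_inflow)), all(is.finite(d15N_snow)),
            all(is.finite(nh4_snow)), all(is.finite(no3_snow)),
            all(no3_snow >= 0))
  if (any(nh4_snow <= 0))
    stop("snow_ammonium_d15N: nh4_snow must be > 0", call. = FALSE)
  (d15N_inflow * (nh4_snow + no3_snow) - d15N_snow * no3_snow) / nh4_snow
}

#' Monte-Carlo uncertainty for the snow ammonium mass balance
#'
#' Draws each input from an independent normal with the supplied standard
#' deviation (concentrations truncated at zero by rejection) and propagates
#' through [snow_ammonium_d15N()].
#'
#' @inheritParams snow_ammonium_d15N
#' @param sds named numeric vector of standard deviations for any of
#'   `d15N_inflow`, `d15N_snow`, `nh4_snow`, `no3_snow` (omitted = exact).
#' @param n number of draws.
#' @param seed RNG seed.
#' @return List with `mean`, `sd` and the vector of `draws` (per mil).
#' @export
snow_ammonium_d15N_mc <- function(d15N_inflow, d15N_snow, nh4_snow, no3_snow,
                                  sds = c(), n = 10000L, seed = 1L) {
  set.seed(seed)
  g <- function(mean, nm, lower = -Inf) {
    s <- if (nm %in% names(sds)) sds[[nm]] else 0
    if (s == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, s)
    while (any(x <= lower)) {
      i <- x <= lower
      x[i] <- stats::rnorm(sum(i), mean, s)
    }
    x
  }
  draws <- snow_ammonium_d15N(
    g(d15N_inflow, "d15N_inflow"), g(d15N_snow, "d15N_snow"),
    g(nh4_snow, "nh4_snow", lower = 0), g(no3_snow, "no3_snow", lower = -1e-12))
  list(mean = mean(draws), sd = stats::sd(draws), draws = draws)
}

#' Default tropospheric NOx source budget
#'
#' Global tropospheric NOx source strengths (Tg N per year): fossil fuels 24,
#' lightning 12, soil emissions 12, biomass burning 8, NH3 oxidation 3,
#' stratospheric transport 0.4, aircraft 0.4. Shipped as an editable CSV.
#'
#' @param path optional alternative CSV with columns `name, tg_per_year`.
#' @return Data frame with columns `name`, `tg_per_year`.
#' @export
default_nox_budget <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nox_budget.csv", package = "no3apport",
                        mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("name", "tg_per_year"), names(out))
  if (length(miss))
    stop("default_nox_budget: missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out
}

#' Apportion lake nitrate among tropospheric NOx sources
#'
#' Scales each NOx source's share of the global tropospheric budget by the
#' modal probability estimate of the atmospherically oxidised nitrate (AON)
#' contribution to the lakes: `percent_of_nox = 100 * tg / total` and
#' `contribution_to_lakes = percent_of_nox / 100 * aon_mpe`. Values are
#' returned at full precision; [format_nox_budget()] applies the display
#' rounding and appends the Total row.
#'
#' @param table data frame with columns `name` and `tg_per_year`
#'   (all >= 0, total > 0); default [default_nox_budget()].
#' @param aon_mpe AON modal probability estimate for the receiving waters,
#'   in percent `[0, 100]`.
#' @return Data frame with columns `name`, `tg_per_year`, `percent_of_nox`,
#'   `contribution_to_lakes`.
#' @export
nox_budget_apportionment <- function(table = default_nox_budget(), aon_mpe) {
  stopifnot(is.data.frame(table), is.finite(aon_mpe),
            aon_mpe >= 0, aon_mpe <= 100)
  if (nrow(table) == 0L)
    stop("nox_budget_apportionment: empty NOx table", call. = FALSE)
  if (any(table$tg_per_year < 0) || sum(table$tg_per_year) <= 0)
    stop("nox_budget_apportionment: tg_per_year must be >= 0 with positive total",
         call. = FALSE)
  pct <- 100 * table$tg_per_year / sum(table$tg_per_year)
  data.frame(name = table$name, tg_per_year = table$tg_per_year,
             percent_of_nox = pct,
             contribution_to_lakes = pct / 100 * aon_mpe,
             stringsAsFactors = FALSE)
}

#' Format a NOx apportionment for display
#'
#' Applies the table display convention (values >= 1 rounded half away from
#' zero to integers; values < 1 to one decimal) and appends a Total row
#' computed from the unrounded sums.
#'
#' @param x result of [nox_budget_apportionment()].
#' @return Data frame with a trailing `Total` row and rounded cells.
#' @export
format_nox_budget <- function(x) {
  stopifnot(is.data.frame(x))
  disp_round <- function(v)
    ifelse(abs(v) >= 1, round_half_away(v), round_half_away(v, 1L))
  tot <- data.frame(name = "Total", tg_per_year = sum(x$tg_per_year),
                    percent_of_nox = sum(x$percent_of_nox),
                    contribution_to_lakes = sum(x$contribution_to_lakes),
                    stringsAsFactors = FALSE)
  out <- rbind(x, tot)
  for (col in c("tg_per_year", "percent_of_nox", "contribution_to_lakes"))
    out[[col]] <- disp_round(out[[col]])
  out
}

#' Anthropogenic share of nitrate inputs
#'
#' Rolls up the anthropogenic contribution: the fertiliser (plus rain
#' ammonium) MPE plus the fossil-fuel fraction of the AON MPE, i.e.
#' `fertilizer_mpe + fossil_fraction_of_nox * aon_mpe`. Returned unrounded,
#' in percent.
#'
#' @param fertilizer_mpe fertiliser + rain ammonium MPE (percent).
#' @param aon_mpe AON MPE (percent).
#' @param fossil_fraction_of_nox fraction of tropospheric NOx from fossil
#'   fuels, in `[0, 1]`.
#' @return Percentage of total nitrate that is anthropogenic.
#' @examples
#' anthropogenic_share(62, 23, 0.40)  # 71.2
#' @export
anthropogenic_share <- function(fertilizer_mpe, aon_mpe,
                                fossil_fraction_of_nox) {
  stopifnot(is.finite(fertilizer_mpe), fertilizer_mpe >= 0,
            fertilizer_mpe <= 100, is.finite(aon_mpe), aon_mpe >= 0,
            aon_mpe <= 100, is.finite(fossil_fraction_of_nox),
            fossil_fraction_of_nox >= 0, fossil_fraction_of_nox <= 1)
  fertilizer_mpe + fossil_fraction_of_nox * aon_mpe
}
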
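# The 12 ESAC prescription-quality indicators, per physician-year.

#' Names of the 12 quality indicators
#'
#' In fixed order: volume indicators in DID (DDD per 1000 inhabitants per
#' day) for all systemic antibacterials and four subgroups, subclass shares as
#' a percentage of total J01 DDDs, the broad/narrow spectrum ratio, and the
#' winter/summer seasonal-variation percentages for J01 and quinolones.
#'
#' @return Character vector of length 12.
#' @export
indicator_names <- function() {
  c("j01_did", "j01c_did", "j01d_did", "j01f_did", "j01m_did",
    "j01ce_pct", "j01cr_pct", "j01dd_de_pct", "j01ma_pct",
    "j01_bn_ratio", "j01_sv", "j01m_sv")
}

#' Number of days in a calendar year
#' @param year Integer calendar year(s).
#' @return 365 or 366 (leap years).
#' @export
days_in_year <- function(year) {
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(leap, 366L, 365L)
}

#' DDDs per 1000 inhabitants per day
#'
#' `ddd_total / (persons * days) * 1000` — the population-standardised
#' consumption rate used by drug-utilisation surveillance.
#'
#' @param ddd_total Total DDDs dispensed over the period (non-negative).
#' @param persons Panel size (patients allocated to the physician), > 0.
#' @param days Length of the period in days, > 0.
#' @return DID value(s).
#' @examples
#' compute_did(7300, 1000, 365)  # 20
#' @export
compute_did <- function(ddd_total, persons, days) {
  if (any(persons <= 0) || any(days <= 0)) {
    stop("persons and days must be positive", call. = FALSE)
  }
  if (any(ddd_total < 0)) stop("ddd_total must be non-negative", call. = FALSE)
  ddd_total / (persons * days) * 1000
}

#' Subclass consumption as a percentage of total J01 DDDs
#'
#' @param group_ddd DDDs in the subclass.
#' @param total_j01_ddd Total J01 DDDs over the same slice.
#' @return Percentage in \[0, 100\]; `NA` when the denominator is zero.
#' @export
compute_subclass_pct <- function(group_ddd, total_j01_ddd) {
  if (any(group_ddd < 0) || any(total_j01_ddd < 0)) {
    stop("DDD totals must be non-negative", call. = FALSE)
  }
  # a subclass exceeding its parent total indicates a group-map violation
  if (any(group_ddd > total_j01_ddd * (1 + 1e-9) & total_j01_ddd > 0) ||
      any(group_ddd > 0 & total_j01_ddd == 0)) {
    stop("subclass DDDs exceed total J01 DDDs", call. = FALSE)
  }
  ifelse(total_j01_ddd > 0, 100 * group_ddd / total_j01_ddd, NA_real_)
}

#' Broad-to-narrow spectrum consumption ratio
#'
#' Plain unitless quotient of broad-spectrum DDDs (J01CR + J01DC + J01DD +
#' J01F without erythromycin) to narrow-spectrum DDDs (J01CE + J01DB +
#' erythromycin).
#'
#' @param broad_ddd,narrow_ddd Non-negative DDD totals.
#' @return Ratio; `NA` when `narrow_ddd` is zero.
#' @export
compute_bn_ratio <- function(broad_ddd, narrow_ddd) {
  if (any(broad_ddd < 0) || any(narrow_ddd < 0)) {
    stop("DDD totals must be non-negative", call. = FALSE)
  }
  ifelse(narrow_ddd > 0, broad_ddd / narrow_ddd, NA_real_)
}

#' Months of a July-to-June seasonal year
#'
#' The seasonal year starting July of `start_year` runs to June of
#' `start_year + 1`.  Winter is October--December plus January--March of the
#' following calendar year; summer is July--September plus April--June.
#'
#' @param start_year Calendar year in which the seasonal year starts (July).
#' @return Tibble with columns `year`, `month`, `season`.
#' @export
seasonal_year <- function(start_year) {
  tibble::tibble(
    year = c(rep(start_year, 6L), rep(start_year + 1L, 6L)),
    month = c(7:12, 1:6),
    season = ifelse(c(7:12, 1:6) %in% c(10:12, 1:3), "winter", "summer")
  )
}

#' Seasonal variation in consumption
#'
#' Percent excess of winter-half-year over summer-half-year DDDs on a
#' July-to-June year: `100 * (winter / summer - 1)`.
#'
#' @param records Validated prescription records.
#' @param group ATC group name (e.g. `"J01"`, `"J01M"`).
#' @param physician_id Physician to restrict to; `NULL` for all.
#' @param start_year July start of the seasonal year.
#' @param map Group map.
#' @return Percentage; `NA` when the summer total is zero.
#' @export
compute_seasonal_variation <- function(records, group, physician_id = NULL,
                                       start_year, map = atc_group_map()) {
  sy <- seasonal_year(start_year)
  winter <- aggregate_ddd(records, group, physician_id,
                          sy[sy$season == "winter", ], map)
  summer <- aggregate_ddd(records, group, physician_id,
                          sy[sy$season == "summer", ], map)
  if (summer == 0) NA_real_ else 100 * (winter / summer - 1)
}

# Season labels for calendar (year, month) cells: the seasonal year starting
# July of Y is assigned to analysis year Y + 1.
.season_cells <- function(year, month) {
  tibble::tibble(
    analysis_year = ifelse(month >= 7L, year + 1L, year),
    season = ifelse(month %in% c(10:12, 1:3), "winter", "summer")
  )
}

#' Compute the 12 ESAC indicators for every physician-year
#'
#' Calendar-year DDD aggregates feed the DID, percentage and ratio
#' indicators; the two seasonal-variation indicators use the July-to-June
#' seasonal year ending June of the analysis year, and are `NA` for analysis
#' years whose seasonal window extends before the start of the extract
#' (`window_start`).
#'
#' @param prescriptions Validated prescription records (`physician_id`,
#'   `year`, `month`, `atc`, `ddd_total`).
#' @param panels Panel records (`physician_id`, `year`, `persons`); one row
#'   per physician-year to score.
#' @param map Group map, defaults to [atc_group_map()].
#' @param window_start First calendar year covered by the prescription
#'   extract; defaults to the earliest year in `panels`.
#' @return Tibble with `physician_id`, `year` and the 12 indicator columns of
#'   [indicator_names()]; undefined indicators are `NA`.
#' @export
compute_indicators <- function(prescriptions, panels, map = atc_group_map(),
                               window_start = NULL) {
  if (nrow(panels) == 0L) stop("no panel records supplied", call. = FALSE)
  if (any(panels$persons <= 0)) {
    stop("panel sizes must be positive", call. = FALSE)
  }
  if (is.null(window_start)) window_start <- min(panels$year)

  rx <- prescriptions
  groups <- c("J01", "J01C", "J01D", "J01F", "J01M", "J01CE", "J01CR",
              "J01DD", "J01DE", "J01MA", "BROAD", "NARROW")
  memb <- lapply(groups, function(g) in_group(rx$atc, g, map))
  names(memb) <- groups

  key <- paste(rx$physician_id, rx$year, sep = "\r")
  cal <- lapply(memb, function(m) {
    v <- rowsum(rx$ddd_total * m, key)
    stats::setNames(as.vector(v), rownames(v))
  })

  seas <- .season_cells(rx$year, rx$month)
  skey <- paste(rx$physician_id, seas$analysis_year, seas$season, sep = "\r")
  sv_groups <- c("J01", "J01M")
  sea <- lapply(sv_groups, function(g) {
    v <- rowsum(rx$ddd_total * memb[[g]], skey)
    stats::setNames(as.vector(v), rownames(v))
  })
  names(sea) <- sv_groups

  pk <- paste(panels$physician_id, panels$year, sep = "\r")
  if (anyDuplicated(pk)) {
    stop("duplicate physician-year rows in panels", call. = FALSE)
  }
  pull_cal <- function(g) {
    v <- cal[[g]][pk]
    v[is.na(v)] <- 0
    unname(v)
  }
  pull_sea <- function(g, season) {
    v <- sea[[g]][paste(panels$physician_id, panels$year, season, sep = "\r")]
    v[is.na(v)] <- 0
    unname(v)
  }

  days <- days_in_year(panels$year)
  tot <- pull_cal("J01")
  sv_ok <- panels$year - 1L >= window_start
  sv_of <- function(g) {
    w <- pull_sea(g, "winter")
    s <- pull_sea(g, "summer")
    ifelse(sv_ok & s > 0, 100 * (w / s - 1), NA_real_)
  }

  tibble::tibble(
    physician_id = panels$physician_id,
    year = panels$year,
    j01_did  = compute_did(tot, panels$persons, days),
    j01c_did = compute_did(pull_cal("J01C"), panels$persons, days),
    j01d_did = compute_did(pull_cal("J01D"), panels$persons, days),
    j01f_did = compute_did(pull_cal("J01F"), panels$persons, days),
    j01m_did = compute_did(pull_cal("J01M"), panels$persons, days),
    j01ce_pct = compute_subclass_pct(pull_cal("J01CE"), tot),
    j01cr_pct = compute_subclass_pct(pull_cal("J01CR"), tot),
    j01dd_de_pct = compute_subclass_pct(pull_cal("J01DD") + pull_cal("J01DE"),
                                        tot),
    j01ma_pct = compute_subclass_pct(pull_cal("J01MA"), tot),
    j01_bn_ratio = compute_bn_ratio(pull_cal("BROAD"), pull_cal("NARROW")),
    j01_sv  = sv_of("J01"),
    j01m_sv = sv_of("J01M")
  )
}

#' Compute one physician-year's indicator vector
#'
#' Convenience wrapper around [compute_indicators()] for a single physician
#' and year.
#'
#' @param prescriptions Validated prescription records.
#' @param panel One-row data frame (`physician_id`, `year`, `persons`) for
#'   the physician-year.
#' @param map Group map.
#' @param window_start First calendar year of the extract (see
#'   [compute_indicators()]); defaults to the earliest year in
#'   `prescriptions`, or the panel year if there are no records.
#' @return One-row tibble of the 12 indicators.
#' @export
compute_indicator_vector <- function(prescriptions, panel,
                                     map = atc_group_map(),
                                     window_start = NULL) {
  if (nrow(panel) != 1L) {
    stop("panel must identify exactly one physician-year", call. = FALSE)
  }
  if (is.null(window_start)) {
    window_start <- if (nrow(prescriptions)) min(prescriptions$year)
                    else panel$year
  }
  compute_indicators(prescriptions, panel, map, window_start)
}
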
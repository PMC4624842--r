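# Plain-text reporting utilities: response-rate arithmetic, the
# primary-care-to-total consumption extrapolation, and aligned-text renderings
# of the item screen and the cohort indicator report.

#' Questionnaire response percentage
#'
#' @param n Number of responders.
#' @param total Number approached.
#' @param digits Decimal places, default 1.
#' @return Percentage rounded to `digits`.
#' @examples
#' response_percentage(1428, 2100)  # 68.0
#' @export
response_percentage <- function(n, total, digits = 1) {
  if (any(total <= 0) || any(n < 0) || any(n > total)) {
    stop("need 0 <= n <= total with total > 0", call. = FALSE)
  }
  round(100 * n / total, digits)
}

#' Format a response rate as text
#'
#' @inheritParams response_percentage
#' @return String such as `"68.0% (1428/2100)"`.
#' @export
format_response_rate <- function(n, total, digits = 1) {
  sprintf("%.*f%% (%d/%d)", digits, response_percentage(n, total, digits),
          as.integer(n), as.integer(total))
}

#' Extrapolate primary-care consumption to total consumption
#'
#' Scales a primary-care DID value up by the share of all prescribing that
#' primary care accounts for: `total = primary_care_did / share`.
#'
#' @param primary_care_did Consumption observed in primary care, in DID.
#' @param share Primary-care share of total prescribing (default 0.85).
#' @param digits Decimal places of the result, default 2.
#' @return Extrapolated total consumption in DID.
#' @examples
#' extrapolate_total_did(15.65)  # 18.41
#' @export
extrapolate_total_did <- function(primary_care_did, share = 0.85,
                                  digits = 2) {
  if (any(share <= 0) || any(share > 1)) {
    stop("share must lie in (0, 1]", call. = FALSE)
  }
  round(primary_care_did / share, digits)
}

#' Render the item screen as an aligned text table
#'
#' One line per item with the exposure percentiles, the IqOR with its
#' confidence interval, and the p-value; skipped or failed items show their
#' status instead.
#'
#' @param screen Tibble from [run_item_screen()].
#' @return Character vector of report lines.
#' @export
format_item_screen <- function(screen) {
  hdr <- sprintf("%-6s %6s %6s %6s  %-22s %8s", "item", "p25", "p50", "p75",
                 "IqOR (95% CI)", "p")
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  lines <- vapply(seq_len(nrow(screen)), function(i) {
    r <- screen[i, ]
    if (!identical(r$status, "ok")) {
      return(sprintf("%-6s %s (%s)", as.character(r$item_id), r$status,
                     r$note))
    }
    sprintf("%-6s %6.1f %6.1f %6.1f  %-22s %8s",
            as.character(r$item_id), r$q25, r$q50, r$q75,
            sprintf("%.2f (%.2f-%.2f)", r$iqor, r$ci_low, r$ci_high),
            fmt_p(r$p_value))
  }, character(1))
  c(hdr, lines)
}

#' Render the cohort indicator report as an aligned text table
#'
#' One line per indicator with the reference value, direction of better, the
#' cohort mean over defined physician-years, and the percentage of
#' physician-years better than reference.
#'
#' @param report Tibble from [cohort_indicator_report()].
#' @return Character vector of report lines.
#' @export
format_indicator_report <- function(report) {
  hdr <- sprintf("%-14s %10s %7s %12s %12s %8s", "indicator", "reference",
                 "better", "cohort mean", "pct better", "n")
  lines <- vapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    sprintf("%-14s %10.2f %7s %12s %12s %8d",
            r$indicator, r$reference_value, r$better_direction,
            ifelse(is.na(r$mean_value), "NA", sprintf("%.2f", r$mean_value)),
            ifelse(is.na(r$pct_better), "NA", sprintf("%.1f", r$pct_better)),
            r$n_defined)
  }, character(1))
  c(hdr, lines)
}
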
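# Reference standard and the binary AQPA (Appropriate Quality Prescription
# of Antibiotics) outcome.

#' National reference standard for the 12 indicators
#'
#' Default reference values are the Spanish national values the study cohort
#' was benchmarked against, one per indicator, together with the direction in
#' which a physician's value counts as better.  Lower is better for every
#' indicator except the share of beta-lactamase-sensitive (narrow-spectrum)
#' penicillins, where higher consumption reflects more conservative
#' prescribing.
#'
#' @return Tibble with columns `indicator`, `reference_value`,
#'   `better_direction` (`"lower"` or `"higher"`).
#' @export
reference_standard <- function() {
  tibble::tibble(
    indicator = indicator_names(),
    reference_value = c(19.68, 12.31, 1.56, 1.90, 2.42,
                        0.50, 38.70, 2.80, 12.0,
                        56.89, 125.8, 117.3),
    better_direction = c(rep("lower", 5L), "higher", rep("lower", 6L))
  )
}

.check_standard <- function(standard) {
  need <- indicator_names()
  if (!all(c("indicator", "reference_value", "better_direction") %in%
           names(standard))) {
    stop("reference standard must have columns indicator, reference_value, ",
         "better_direction", call. = FALSE)
  }
  missing <- setdiff(need, standard$indicator)
  if (length(missing)) {
    stop("reference standard is missing indicator(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(standard$better_direction %in% c("lower", "higher"))) {
    stop("better_direction must be 'lower' or 'higher'", call. = FALSE)
  }
  standard[match(need, standard$indicator), ]
}

#' Compare an indicator value against its reference
#'
#' Strict comparison: a value exactly equal to the reference is *not* better
#' (it is counted as worse, the conservative reading of "better than").
#' Undefined (`NA`) values yield `"undefined"`.
#'
#' @param value Numeric vector of indicator values (may contain `NA`).
#' @param reference Reference value(s).
#' @param direction `"lower"` or `"higher"` (recycled).
#' @return Character vector of `"better"`, `"worse"`, `"undefined"`.
#' @export
is_better <- function(value, reference, direction) {
  if (any(!is.finite(reference))) stop("reference must be finite", call. = FALSE)
  if (any(!direction %in% c("lower", "higher"))) {
    stop("direction must be 'lower' or 'higher'", call. = FALSE)
  }
  n <- max(length(value), length(reference), length(direction))
  value <- rep_len(value, n)
  reference <- rep_len(reference, n)
  direction <- rep_len(direction, n)
  better <- ifelse(direction == "lower", value < reference, value > reference)
  ifelse(is.na(value), "undefined", ifelse(better, "better", "worse"))
}

#' Classify physician-years as AQPA
#'
#' For each physician-year, counts how many of the 12 indicators are better
#' than the reference standard.  A physician-year shows Appropriate Quality
#' Prescription of Antibiotics when half or more (>= 6 of 12) indicators are
#' better.  Undefined indicators count toward neither better nor worse; the
#' threshold remains 6 out of 12, not 6 of the defined ones.  The
#' complementary `n_worse` count is returned so the alternative ">= 6 worse"
#' rule can be applied downstream.
#'
#' @param indicators Indicator tibble from [compute_indicators()] (or any
#'   data frame with `physician_id`, `year` and the 12 indicator columns).
#' @param standard Reference standard, defaults to [reference_standard()].
#' @return Tibble with `physician_id`, `year`, `n_better`, `n_worse`,
#'   `n_undefined`, `aqpa` (logical).
#' @export
classify_aqpa <- function(indicators, standard = reference_standard()) {
  standard <- .check_standard(standard)
  vals <- as.matrix(indicators[, standard$indicator, drop = FALSE])
  status <- vapply(seq_len(nrow(standard)), function(j) {
    is_better(vals[, j], standard$reference_value[j],
              standard$better_direction[j])
  }, character(nrow(vals)))
  status <- matrix(status, nrow = nrow(vals))
  n_better <- rowSums(status == "better")
  n_worse <- rowSums(status == "worse")
  tibble::tibble(
    physician_id = indicators$physician_id,
    year = indicators$year,
    n_better = as.integer(n_better),
    n_worse = as.integer(n_worse),
    n_undefined = as.integer(12L - n_better - n_worse),
    aqpa = n_better >= 6L
  )
}

#' Per-indicator share of physician-years better than reference
#'
#' For each indicator, the percentage of physician-years whose value is
#' better than the reference, among physician-years where the indicator is
#' defined.  Indicators undefined everywhere are reported with `NA` and zero
#' `n_defined`.
#'
#' @param indicators Indicator tibble from [compute_indicators()].
#' @param standard Reference standard.
#' @return Tibble with `indicator`, `reference_value`, `better_direction`,
#'   `mean_value` (cohort mean over defined physician-years), `pct_better`,
#'   `n_defined`.
#' @export
cohort_indicator_report <- function(indicators,
                                    standard = reference_standard()) {
  if (nrow(indicators) == 0L) {
    stop("no physician-years supplied", call. = FALSE)
  }
  standard <- .check_standard(standard)
  rows <- lapply(seq_len(nrow(standard)), function(j) {
    v <- indicators[[standard$indicator[j]]]
    st <- is_better(v, standard$reference_value[j],
                    standard$better_direction[j])
    n_def <- sum(st != "undefined")
    tibble::tibble(
      indicator = standard$indicator[j],
      reference_value = standard$reference_value[j],
      better_direction = standard$better_direction[j],
      mean_value = if (n_def) mean(v[st != "undefined"]) else NA_real_,
      pct_better = if (n_def) 100 * sum(st == "better") / n_def else NA_real_,
      n_defined = n_def
    )
  })
  dplyr::bind_rows(rows)
}
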
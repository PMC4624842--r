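# Per-item screen: one adjusted random-intercept model per questionnaire
# item, summarised as interquartile odds ratios.

#' Assemble model data for one questionnaire item
#'
#' Joins AQPA outcomes (one row per physician-year) with the item's VAS score
#' (constant over a physician's follow-up years; the questionnaire was
#' administered once) and the physician covariates: on-call duty, night
#' shifts, and the mean panel size over the physician's follow-up years.
#' Physicians without a response to the item are dropped.
#'
#' @param aqpa_results Tibble from [classify_aqpa()].
#' @param attitudes Attitude responses (`physician_id`, `item_id`, `score`).
#' @param physicians Physician covariates (`physician_id`, `on_call`,
#'   `night_shifts`).
#' @param panels Panel records (`physician_id`, `year`, `persons`).
#' @param item Item id to extract.
#' @return Tibble with `physician_id`, `year`, `aqpa`, `item_id`, `score`,
#'   `on_call`, `night_shifts`, `mean_panel`.
#' @export
build_model_data <- function(aqpa_results, attitudes, physicians, panels,
                             item) {
  resp <- attitudes[attitudes$item_id == item,
                    c("physician_id", "item_id", "score")]
  if (anyDuplicated(resp$physician_id)) {
    stop("multiple responses to item ", item, " for the same physician",
         call. = FALSE)
  }
  mp <- dplyr::summarise(dplyr::group_by(panels, .data$physician_id),
                         mean_panel = mean(.data$persons), .groups = "drop")
  out <- dplyr::inner_join(
    aqpa_results[, c("physician_id", "year", "aqpa")], resp,
    by = "physician_id"
  )
  out <- dplyr::inner_join(out, physicians, by = "physician_id")
  out <- dplyr::inner_join(out, mp, by = "physician_id")
  out$aqpa <- as.integer(out$aqpa)
  out[, c("physician_id", "year", "aqpa", "item_id", "score",
          "on_call", "night_shifts", "mean_panel")]
}

#' Screen all questionnaire items against AQPA
#'
#' Fits one covariate-adjusted random-intercept logistic model per item (a
#' joint multi-item model is deliberately not fitted) and summarises each as
#' an interquartile odds ratio with 95% Wald confidence interval and p-value.
#' Items with a degenerate exposure (25th percentile equal to the 75th) are
#' reported as skipped; a fit that fails or does not converge is reported,
#' and the screen continues.  P-values are unadjusted; `adjust = TRUE` adds a
#' Benjamini-Hochberg column.
#'
#' @param aqpa_results Tibble from [classify_aqpa()].
#' @param attitudes Attitude responses (`physician_id`, `item_id`, `score`).
#' @param physicians Physician covariates (`physician_id`, `on_call`,
#'   `night_shifts`).
#' @param panels Panel records.
#' @param items Items to screen; default all items present in `attitudes`.
#' @param covariates Covariate columns for adjustment; default the study set.
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column.
#' @param conf_level Confidence level for the IqOR interval.
#' @return Tibble with one row per screened item: the [compute_iqor()]
#'   columns plus `status` (`"ok"`, `"degenerate"`, `"failed"`) and `note`.
#' @export
run_item_screen <- function(aqpa_results, attitudes, physicians, panels,
                            items = NULL,
                            covariates = c("on_call", "night_shifts",
                                           "mean_panel"),
                            adjust = FALSE, conf_level = 0.95) {
  if (is.null(items)) items <- sort(unique(attitudes$item_id))
  rows <- lapply(items, function(it) {
    md <- build_model_data(aqpa_results, attitudes, physicians, panels, it)
    empty <- tibble::tibble(
      item_id = it, q25 = NA_real_, q50 = NA_real_, q75 = NA_real_,
      iqor = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      p_value = NA_real_, pct_change = NA_real_, orientation = NA_character_
    )
    scores <- md$score[!duplicated(md$physician_id)]
    q <- vas_quantile(scores)
    if (q[[3]] - q[[1]] <= 0) {
      return(dplyr::mutate(empty, q25 = q[[1]], q50 = q[[2]], q75 = q[[3]],
                           status = "degenerate",
                           note = "interquartile range of the exposure is zero"))
    }
    res <- tryCatch({
      fit <- fit_random_intercept_logistic(md, exposure = "score",
                                           covariates = covariates)
      out <- compute_iqor(fit, scores, conf_level = conf_level, item_id = it)
      note <- if (length(fit$warnings)) paste(fit$warnings, collapse = "; ")
              else ""
      dplyr::mutate(out, status = "ok", note = note)
    }, error = function(e) {
      dplyr::mutate(empty, status = "failed", note = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  if (adjust) {
    out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}
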
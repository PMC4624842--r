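# Longitudinal random-intercept logistic model of AQPA and its
# interquartile-odds-ratio summary.

#' Fit a random-intercept logistic model of AQPA
#'
#' Fits `logit P(aqpa = 1 | u_i) = b0 + b_exposure * exposure + covariates +
#' u_i` with a physician-level Normal random intercept `u_i ~ N(0, sigma_u^2)`
#' by maximum likelihood via [lme4::glmer()].  Yearly observations are level
#' 1, physicians level 2.  The likelihood is integrated over the scalar
#' random intercept by adaptive Gauss-Hermite quadrature (`nAGQ = 9` by
#' default; `nAGQ = 1` gives the Laplace approximation), which is markedly
#' more stable than the Laplace Hessian when the random-intercept SD is
#' large.
#'
#' @param data Data frame with one row per physician-year: the outcome column
#'   (0/1 or logical), the exposure column, any covariate columns, and the
#'   grouping column.
#' @param exposure Name of the exposure column (default `"score"`).
#' @param covariates Character vector of covariate column names (default
#'   none).  A covariate named `mean_panel` is internally rescaled to
#'   thousands of patients for numerical stability; its coefficient is
#'   reported on that scale.
#' @param outcome Name of the outcome column (default `"aqpa"`).
#' @param group Name of the physician grouping column (default
#'   `"physician_id"`).
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature nodes.
#' @return An object of class `aqpa_fit`: a list with `beta0`,
#'   `beta_exposure`, `se_exposure`, `beta_covariates`, `sigma_u`, `loglik`,
#'   `converged`, `n_obs`, `n_physicians`, `exposure` and the underlying
#'   `model`.
#' @export
fit_random_intercept_logistic <- function(data, exposure = "score",
                                          covariates = character(),
                                          outcome = "aqpa",
                                          group = "physician_id",
                                          nAGQ = 9L) {
  need <- c(outcome, exposure, covariates, group)
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("model data lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(data[[group]])) < 2L) {
    stop("need at least two physicians", call. = FALSE)
  }
  y <- as.integer(data[[outcome]])
  if (length(unique(y)) < 2L) {
    stop("outcome is constant; the model is not identifiable", call. = FALSE)
  }

  df <- data.frame(
    .y = y,
    .g = factor(data[[group]]),
    check.names = FALSE
  )
  df[[exposure]] <- data[[exposure]]
  for (cv in covariates) {
    df[[cv]] <- if (cv == "mean_panel") data[[cv]] / 1000 else data[[cv]]
  }
  rhs <- paste(c(sprintf("`%s`", c(exposure, covariates)), "(1 | .g)"),
               collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))

  run_fit <- function(...) {
    warned <- character()
    fit <- withCallingHandlers(
      lme4::glmer(form, data = df, family = stats::binomial(), nAGQ = nAGQ,
                  ...),
      warning = function(w) {
        warned <<- c(warned, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    list(fit = fit, warned = warned,
         fail = any(grepl("failed to converge|Model failed", warned)) ||
           length(fit@optinfo$conv$lme4$messages %||% character()) > 0)
  }
  res <- run_fit()
  if (res$fail) {
    # retry with a derivative-free optimizer before declaring failure
    retry <- run_fit(control = lme4::glmerControl(optimizer = "bobyqa"))
    if (!retry$fail) res <- retry
  }
  fit <- res$fit
  warned <- res$warned
  conv_fail <- res$fail
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(
    beta0 = unname(fe[["(Intercept)"]]),
    beta_exposure = unname(fe[[exposure]]),
    se_exposure = unname(se[[exposure]]),
    beta_covariates = fe[setdiff(names(fe), c("(Intercept)", exposure))],
    sigma_u = sqrt(unname(lme4::VarCorr(fit)$.g[1, 1])),
    loglik = as.numeric(stats::logLik(fit)),
    converged = !conv_fail,
    n_obs = nrow(df),
    n_physicians = nlevels(df$.g),
    exposure = exposure,
    warnings = warned,
    model = fit
  ), class = "aqpa_fit")
}

#' @export
print.aqpa_fit <- function(x, ...) {
  cat("Random-intercept logistic model of AQPA\n")
  cat(sprintf("  %d observations, %d physicians\n", x$n_obs, x$n_physicians))
  cat(sprintf("  exposure %-14s beta = %8.4f  (SE %.4f)\n",
              x$exposure, x$beta_exposure, x$se_exposure))
  cat(sprintf("  sigma_u = %.4f   logLik = %.2f   converged: %s\n",
              x$sigma_u, x$loglik, x$converged))
  invisible(x)
}

#' Quartiles of VAS scores
#'
#' Scores are snapped to the 0.5-step grid of the visual analog scale and
#' quartiles taken with the median-unbiased quantile definition
#' (`type = 8`).
#'
#' @param scores Numeric scores in \[0, 10\].
#' @param probs Probabilities, default the three quartiles.
#' @return Named numeric vector of quantiles.
#' @export
vas_quantile <- function(scores, probs = c(0.25, 0.5, 0.75)) {
  g <- round(scores * 2) / 2
  stats::quantile(g, probs = probs, type = 8, na.rm = TRUE, names = TRUE)
}

#' Interquartile odds ratio from a fitted model
#'
#' Rescales the fitted log-odds per exposure unit to the shift from the 25th
#' to the 75th percentile of the cohort's exposure distribution:
#' `IqOR = exp(beta * (q75 - q25))`, with a Wald confidence interval on the
#' coefficient scale exponentiated after the same rescaling.
#'
#' @param fit An `aqpa_fit` object.
#' @param scores The cohort exposure distribution (one score per physician,
#'   or per physician-year).
#' @param conf_level Confidence level, default 0.95.
#' @param item_id Optional item identifier carried into the result.
#' @return One-row tibble: `item_id`, `q25`, `q50`, `q75`, `iqor`, `ci_low`,
#'   `ci_high`, `p_value`, `pct_change`, `orientation`.
#' @export
compute_iqor <- function(fit, scores, conf_level = 0.95, item_id = NA) {
  if (!inherits(fit, "aqpa_fit")) stop("fit must be an aqpa_fit", call. = FALSE)
  if (!fit$converged) {
    stop("model fit did not converge; IqOR not computed", call. = FALSE)
  }
  q <- vas_quantile(scores)
  iqr <- q[[3]] - q[[1]]
  if (iqr <= 0) {
    stop("degenerate exposure: 25th and 75th percentiles coincide",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- fit$beta_exposure
  se <- fit$se_exposure
  iqor <- exp(b * iqr)
  pc <- percent_change(iqor)
  tibble::tibble(
    item_id = item_id,
    q25 = q[[1]], q50 = q[[2]], q75 = q[[3]],
    iqor = iqor,
    ci_low = exp((b - z * se) * iqr),
    ci_high = exp((b + z * se) * iqr),
    p_value = 2 * stats::pnorm(-abs(b / se)),
    pct_change = pc$pct_change,
    orientation = pc$orientation
  )
}

#' Percent-change rendering of an interquartile odds ratio
#'
#' An IqOR at or above 1 is rendered as `(IqOR - 1) * 100` percent increase in
#' the odds of AQPA as exposure rises from the 25th to the 75th percentile.
#' An IqOR below 1 is inverted first (`1/IqOR`), giving the percent increase
#' when exposure *decreases* from the 75th to the 25th percentile.  The
#' magnitude is therefore symmetric: `percent_change(x)` equals
#' `percent_change(1/x)`.
#'
#' @param iqor Positive odds ratio(s).
#' @return Tibble with `iqor`, `pct_change` (non-negative percent) and
#'   `orientation` (`"increase with exposure"` or
#'   `"increase when exposure decreases"`).
#' @examples
#' percent_change(2.19)  # 119% increase with exposure
#' percent_change(0.60)  # ~67% increase when exposure decreases
#' @export
percent_change <- function(iqor) {
  if (any(!is.finite(iqor)) || any(iqor <= 0)) {
    stop("iqor must be positive and finite", call. = FALSE)
  }
  tibble::tibble(
    iqor = iqor,
    pct_change = ifelse(iqor >= 1, (iqor - 1) * 100, (1 / iqor - 1) * 100),
    orientation = ifelse(iqor >= 1, "increase with exposure",
                         "increase when exposure decreases")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
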
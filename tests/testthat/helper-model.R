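# Direct simulation from the random-intercept logistic model (bypassing the
# prescription pipeline) for model-level checks: known beta, sigma_u, and a
# VAS-like exposure distribution centred at 5.
simulate_model_data <- function(n_phys, beta = -0.25, sigma_u = 1,
                                b0 = 1.25, years = 3L) {
  u <- stats::rnorm(n_phys, 0, sigma_u)
  score <- round(stats::rbeta(n_phys, 1.2, 1.2) * 20) / 2
  id <- rep(seq_len(n_phys), each = years)
  eta <- b0 + beta * (score[id] - 5) + u[id]
  tibble::tibble(
    physician_id = sprintf("P%04d", id),
    aqpa = stats::rbinom(n_phys * years, 1L, stats::plogis(eta)),
    score = score[id]
  )
}

fake_fit <- function(beta, se = 0.1) {
  structure(list(beta_exposure = beta, se_exposure = se, converged = TRUE),
            class = "aqpa_fit")
}
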
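# Synthetic physician cohort with known ground-truth attitude effects.
#
# The generative chain works on a latent prescribing-quality scale: each
# physician's questionnaire scores and a Normal random intercept combine into
# a latent propensity q, which tilts prescribing volume downward and the
# class mix from broad- toward narrow-spectrum agents.  AQPA is never drawn
# directly; it emerges from the simulated prescriptions through the indicator
# and classifier pipeline, so the whole chain is exercised.

# Probability mass of a Beta(a, b) score scaled to [0, 10] and snapped to the
# 0.5-step VAS grid.
.vas_grid_dist <- function(shape1, shape2) {
  g <- seq(0, 10, by = 0.5)
  up <- pmin(1, (g + 0.25) / 10)
  lo <- pmax(0, (g - 0.25) / 10)
  p <- stats::pbeta(up, shape1, shape2) - stats::pbeta(lo, shape1, shape2)
  list(grid = g, p = p / sum(p))
}

.vas_grid_quantile <- function(shape1, shape2, probs = c(0.25, 0.5, 0.75)) {
  d <- .vas_grid_dist(shape1, shape2)
  cdf <- cumsum(d$p)
  vapply(probs, function(pr) d$grid[which(cdf >= pr - 1e-12)[1]], numeric(1))
}

.vas_grid_mean <- function(shape1, shape2) {
  d <- .vas_grid_dist(shape1, shape2)
  sum(d$grid * d$p)
}

#' Fit Beta shape parameters to VAS score quartiles
#'
#' Finds Beta-on-\[0,10\] shape parameters whose 0.5-step discretised
#' distribution has quartiles close to the targets, by a two-stage grid
#' search in log-shape space.
#'
#' @param q25,q50,q75 Target quartiles on the 0 to 10 VAS scale.
#' @param tol Largest acceptable absolute quartile error (VAS units).
#' @return List with `shape1`, `shape2`, `achieved` (the three achieved
#'   quartiles) and `max_err`.
#' @export
vas_beta_from_quartiles <- function(q25, q50, q75, tol = 0.5) {
  targets <- c(q25, q50, q75)
  if (q75 <= q25) {
    stop("degenerate quartile targets: q75 must exceed q25", call. = FALSE)
  }
  objective <- function(a, b) {
    sum(abs(.vas_grid_quantile(a, b) - targets))
  }
  search <- function(la_range, lb_range, len) {
    la <- seq(la_range[1], la_range[2], length.out = len)
    lb <- seq(lb_range[1], lb_range[2], length.out = len)
    best <- c(Inf, NA, NA)
    for (i in la) for (j in lb) {
      o <- objective(exp(i), exp(j))
      if (o < best[1]) best <- c(o, i, j)
    }
    best
  }
  coarse <- search(log(c(0.15, 80)), log(c(0.15, 80)), 35L)
  fine <- search(coarse[2] + c(-0.25, 0.25), coarse[3] + c(-0.25, 0.25), 21L)
  a <- exp(fine[2]); b <- exp(fine[3])
  achieved <- .vas_grid_quantile(a, b)
  max_err <- max(abs(achieved - targets))
  if (max_err > tol) {
    stop(sprintf(
      "no Beta shape reproduces quartiles (%.1f, %.1f, %.1f) within %.1f VAS units (best error %.2f)",
      q25, q50, q75, tol, max_err), call. = FALSE)
  }
  list(shape1 = a, shape2 = b, achieved = achieved, max_err = max_err)
}

#' Default questionnaire item calibration
#'
#' The eleven analysed knowledge/attitude items with the cohort score
#' quartiles the generator is calibrated to, the true latent effect of one
#' VAS unit on the log-odds scale of the latent quality propensity, and the
#' test-retest reliability used for retest generation.  Items 12-16 are
#' low-reliability filler items (no latent effect) so that the
#' ICC-based retention step has something to drop.
#'
#' @return Tibble with `item_id`, `q25`, `q50`, `q75`, `effect`,
#'   `reliability`.
#' @export
default_vas_targets <- function() {
  t1 <- tibble::tribble(
    ~item_id, ~q25, ~q50, ~q75, ~effect,
    1L,  7.5, 9.5, 9.5,  0.00,
    2L,  1.5, 3.0, 5.5,  0.00,
    3L,  1.0, 1.5, 4.0, -0.10,
    4L,  2.5, 5.0, 6.5, -0.08,
    5L,  2.5, 5.0, 7.5, -0.22,
    6L,  4.5, 6.5, 8.5,  0.10,
    7L,  1.0, 3.0, 5.5, -0.15,
    8L,  1.5, 3.5, 5.5, -0.13,
    9L,  0.5, 1.0, 2.5, -0.09,
    10L, 2.5, 5.5, 8.0,  0.00,
    11L, 5.0, 7.5, 9.5,  0.17
  )
  t1$reliability <- 0.85
  filler <- tibble::tibble(
    item_id = 12:16, q25 = 3.0, q50 = 5.0, q75 = 7.0,
    effect = 0, reliability = 0.30
  )
  dplyr::bind_rows(t1, filler)
}

# Generator class cells: baseline share of total J01 volume, the direction in
# which the latent-quality gradient tilts the share (+1 narrow-spectrum /
# conservative, -1 broad-spectrum / quinolone, 0 neutral).
.default_class_mix <- function() {
  tibble::tibble(
    class = c("J01CA", "J01CE", "J01CF", "J01CR", "J01DB", "J01DC", "J01DD",
              "J01DE", "J01FA01", "J01Foth", "J01MA", "J01MB", "J01oth"),
    share = c(0.150, 0.0015, 0.003, 0.420, 0.0012, 0.071, 0.042,
              0.0008, 0.0015, 0.103, 0.129, 0.002, 0.075),
    tilt = c(0, 1, 0, -1, 1, -1, -1, -1, 1, -1, -1, 0, 0)
  )
}

# Within-class code weights for emitting substance-level records.
.class_code_weights <- function() {
  codes <- j01_codes()
  w <- c(
    J01CA04 = 0.92, J01CA01 = 0.08,
    J01CE02 = 0.85, J01CE01 = 0.15,
    J01CF02 = 1,
    J01CR02 = 0.97, J01CR05 = 0.03,
    J01DB01 = 0.7, J01DB05 = 0.3,
    J01DC02 = 0.8, J01DC04 = 0.2,
    J01DD08 = 0.75, J01DD14 = 0.25,
    J01DE01 = 1,
    J01FA01 = 1,
    J01FA09 = 0.45, J01FA10 = 0.45, J01FA02 = 0.05, J01FF01 = 0.05,
    J01MA02 = 0.45, J01MA12 = 0.35, J01MA14 = 0.15, J01MA06 = 0.05,
    J01MB04 = 1,
    J01AA02 = 0.5, J01EE01 = 0.3, J01XE01 = 0.15, J01XX08 = 0.05
  )
  codes$weight <- unname(w[codes$atc])
  codes
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions: 1428 responding physicians followed
#' over 2008-2010, log-normal panel sizes with median 1329 patients, VAS item
#' distributions calibrated to the observed item quartiles, mean total J01
#' consumption around 15.6 DID with a 25% winter excess, and a latent quality
#' gradient that shifts prescribing volume down and the class mix from
#' broad- to narrow-spectrum as attitude-driven quality rises.
#'
#' @param n_physicians Number of physicians.
#' @param years Follow-up calendar years.
#' @param seed Integer seed; the cohort is reproducible given config + seed.
#' @param panel_meanlog,panel_sdlog Log-normal panel-size parameters
#'   (`panel_meanlog = log(1329)` puts the median at 1329 patients).
#' @param items Item calibration tibble (see [default_vas_targets()]); its
#'   `effect` column is the ground-truth latent effect per VAS unit.
#' @param sigma_u SD of the physician-level latent heterogeneity.
#' @param baseline_did Expected total J01 consumption (DID) for a physician
#'   with latent quality 0.
#' @param winter_multiplier Multiplicative winter (Oct-Mar) excess on monthly
#'   expected volume; >= 1.
#' @param dispersion Negative-binomial size parameter of monthly
#'   physician-class DDD counts (smaller = more overdispersion).
#' @param volume_gradient Reduction in log total volume per unit latent
#'   quality.
#' @param mix_gradient Log-share tilt per unit latent quality applied with
#'   the sign of each class's `tilt`.
#' @param class_mix Class-mix tibble (`class`, `share`, `tilt`); shares must
#'   sum to 1.
#' @param retest_n Number of physicians with a retest administration.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_physicians = 1428L,
                          years = 2008:2010,
                          seed = 1L,
                          panel_meanlog = log(1329),
                          panel_sdlog = 0.35,
                          items = default_vas_targets(),
                          sigma_u = 1.0,
                          baseline_did = 15.6,
                          winter_multiplier = 1.25,
                          dispersion = 30,
                          volume_gradient = 0.10,
                          mix_gradient = 0.25,
                          class_mix = .default_class_mix(),
                          retest_n = 100L) {
  cfg <- list(
    n_physicians = as.integer(n_physicians), years = as.integer(years),
    seed = as.integer(seed), panel_meanlog = panel_meanlog,
    panel_sdlog = panel_sdlog, items = items, sigma_u = sigma_u,
    baseline_did = baseline_did, winter_multiplier = winter_multiplier,
    dispersion = dispersion, volume_gradient = volume_gradient,
    mix_gradient = mix_gradient, class_mix = class_mix,
    retest_n = as.integer(retest_n)
  )
  class(cfg) <- "cohort_config"
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  if (cfg$n_physicians < 2L) stop("need at least 2 physicians", call. = FALSE)
  if (abs(sum(cfg$class_mix$share) - 1) > 1e-6) {
    stop("class-mix shares must sum to 1", call. = FALSE)
  }
  if (any(cfg$class_mix$share < 0)) {
    stop("class-mix shares must be non-negative", call. = FALSE)
  }
  if (cfg$baseline_did <= 0) stop("baseline_did must be positive", call. = FALSE)
  if (cfg$winter_multiplier < 1) {
    stop("winter_multiplier must be >= 1", call. = FALSE)
  }
  if (cfg$dispersion <= 0) {
    stop("dispersion must be positive", call. = FALSE)
  }
  if (cfg$sigma_u < 0) stop("sigma_u must be non-negative", call. = FALSE)
  if (any(cfg$items$reliability < 0 | cfg$items$reliability > 1)) {
    stop("item reliabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

# Resolve item Beta shapes from quartile targets (cached per target triple).
.shape_cache <- new.env(parent = emptyenv())
.item_shapes <- function(items) {
  key <- paste(items$q25, items$q50, items$q75, sep = "|")
  out <- matrix(NA_real_, nrow(items), 2L)
  for (i in seq_len(nrow(items))) {
    hit <- .shape_cache[[key[i]]]
    if (is.null(hit)) {
      f <- vas_beta_from_quartiles(items$q25[i], items$q50[i], items$q75[i])
      hit <- c(f$shape1, f$shape2)
      assign(key[i], hit, envir = .shape_cache)
    }
    out[i, ] <- hit
  }
  out
}

#' Generate a synthetic physician cohort
#'
#' Draws questionnaire responses, yearly panels, physician covariates and
#' monthly substance-level prescription records from the configured
#' generative model, and returns them together with the ground truth (latent
#' quality per physician, true effects, `sigma_u`, seed).  DDD totals are
#' integer-valued negative-binomial draws; monthly expected volume is flat
#' across months apart from the winter multiplier.
#'
#' @param config A [cohort_config()].
#' @return List with tibbles `attitudes` (`physician_id`, `item_id`, `score`,
#'   `retest_score`), `panels`, `physicians` (`physician_id`, `on_call`,
#'   `night_shifts`), `prescriptions`, and a `ground_truth` list.
#' @export
generate_cohort <- function(config = cohort_config()) {
  .validate_config(config)
  set.seed(config$seed, kind = "Mersenne-Twister")
  n <- config$n_physicians
  ids <- sprintf("MD%05d", seq_len(n))
  items <- config$items
  shapes <- .item_shapes(items)

  # questionnaire scores (administered once; constant over follow-up)
  score_mat <- matrix(NA_real_, n, nrow(items))
  retest_mat <- matrix(NA_real_, n, nrow(items))
  retest_idx <- seq_len(min(config$retest_n, n))
  for (k in seq_len(nrow(items))) {
    a <- shapes[k, 1]; b <- shapes[k, 2]
    cont <- stats::rbeta(n, a, b) * 10
    score_mat[, k] <- round(cont * 2) / 2
    m <- 10 * a / (a + b)
    s <- 10 * sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    r <- items$reliability[k]
    re <- m + r * (cont[retest_idx] - m) +
      sqrt(1 - r^2) * s * stats::rnorm(length(retest_idx))
    retest_mat[retest_idx, k] <- pmin(10, pmax(0, round(re * 2) / 2))
  }

  # latent quality propensity
  grid_means <- vapply(seq_len(nrow(items)),
                       function(k) .vas_grid_mean(shapes[k, 1], shapes[k, 2]),
                       numeric(1))
  u <- stats::rnorm(n, 0, config$sigma_u)
  q <- as.vector(sweep(score_mat, 2L, grid_means) %*% items$effect) + u

  # panels: physician base size, small year-to-year jitter
  base_panel <- stats::rlnorm(n, config$panel_meanlog, config$panel_sdlog)
  yrs <- config$years
  panels <- tibble::tibble(
    physician_id = rep(ids, each = length(yrs)),
    year = rep(yrs, times = n),
    persons = pmax(50L, as.integer(round(
      rep(base_panel, each = length(yrs)) *
        exp(stats::rnorm(n * length(yrs), 0, 0.03))
    )))
  )

  physicians <- tibble::tibble(
    physician_id = ids,
    on_call = stats::rbinom(n, 1L, 0.7),
    night_shifts = stats::rbinom(n, 1L, 0.5)
  )

  # class shares tilted by latent quality (softmax renormalisation)
  mix <- config$class_mix
  logit_shift <- outer(q * config$mix_gradient, mix$tilt)   # n x classes
  shares <- sweep(exp(logit_shift), 2L, mix$share, `*`)
  shares <- shares / rowSums(shares)

  # expected annual volume per physician-year
  ann <- dplyr::left_join(
    panels,
    tibble::tibble(physician_id = ids, q = q),
    by = "physician_id"
  )
  ann$target_ddd <- config$baseline_did / 1000 * ann$persons *
    days_in_year(ann$year) * exp(-config$volume_gradient * ann$q)

  # monthly seasonal weights, normalised so the 12 months sum to 1
  wm <- config$winter_multiplier
  mfac <- ifelse(1:12 %in% c(10:12, 1:3), wm, 1)
  mfac <- mfac / sum(mfac)

  codes <- .class_code_weights()
  codes <- dplyr::inner_join(codes, mix[, c("class", "tilt")], by = "class")
  cls_index <- match(codes$class, mix$class)

  ny <- nrow(ann)
  nc <- nrow(codes)
  # long layout: physician-year x month x code
  row_iy <- rep(seq_len(ny), each = 12L * nc)
  mon <- rep(rep(1:12, each = nc), times = ny)
  cod <- rep(seq_len(nc), times = 12L * ny)
  phys_of_iy <- match(ann$physician_id, ids)
  mu <- ann$target_ddd[row_iy] * mfac[mon] *
    shares[cbind(phys_of_iy[row_iy], cls_index[cod])] * codes$weight[cod]
  ddd <- stats::rnbinom(length(mu), mu = mu, size = config$dispersion)

  keep <- ddd > 0L
  prescriptions <- tibble::tibble(
    physician_id = ann$physician_id[row_iy[keep]],
    year = ann$year[row_iy[keep]],
    month = mon[keep],
    atc = codes$atc[cod[keep]],
    ddd_total = as.numeric(ddd[keep])
  )
  prescriptions <- dplyr::arrange(prescriptions, .data$physician_id,
                                  .data$year, .data$month, .data$atc)

  attitudes <- tibble::tibble(
    physician_id = rep(ids, times = nrow(items)),
    item_id = rep(items$item_id, each = n),
    score = as.vector(score_mat),
    retest_score = as.vector(retest_mat)
  )
  attitudes <- dplyr::arrange(attitudes, .data$physician_id, .data$item_id)

  list(
    attitudes = attitudes,
    panels = panels,
    physicians = physicians,
    prescriptions = prescriptions,
    ground_truth = list(
      seed = config$seed,
      sigma_u = config$sigma_u,
      effects = stats::setNames(items$effect, items$item_id),
      latent_quality = tibble::tibble(physician_id = ids, q = q, u = u)
    )
  )
}

#' Calibrate a configuration to target quartiles and consumption
#'
#' Refits the per-item Beta shapes so that the discretised score quartiles
#' match the supplied targets within half a VAS unit, and rescales
#' `baseline_did` so that the simulated cohort mean total J01 DID lands
#' within 10% of the target (checked on a pilot simulation).
#'
#' @param config A [cohort_config()].
#' @param vas_targets Optional tibble (`item_id`, `q25`, `q50`, `q75`)
#'   overriding the item quartile targets.
#' @param target_mean_did Optional target for the cohort mean total J01 DID.
#' @param pilot_n Number of physicians in the calibration pilot simulation.
#' @return The adjusted configuration.
#' @export
tune_to_study <- function(config = cohort_config(), vas_targets = NULL,
                          target_mean_did = NULL, pilot_n = 300L) {
  if (!is.null(vas_targets)) {
    for (i in seq_len(nrow(vas_targets))) {
      it <- vas_targets$item_id[i]
      j <- match(it, config$items$item_id)
      if (is.na(j)) stop("unknown item_id: ", it, call. = FALSE)
      fit <- tryCatch(
        vas_beta_from_quartiles(vas_targets$q25[i], vas_targets$q50[i],
                                vas_targets$q75[i]),
        error = function(e) {
          stop("item ", it, ": ", conditionMessage(e), call. = FALSE)
        }
      )
      config$items$q25[j] <- vas_targets$q25[i]
      config$items$q50[j] <- vas_targets$q50[i]
      config$items$q75[j] <- vas_targets$q75[i]
    }
  } else {
    # validate that every configured target is attainable
    .item_shapes(config$items)
  }
  if (!is.null(target_mean_did)) {
    pilot <- config
    pilot$n_physicians <- as.integer(pilot_n)
    mean_did <- function(cf) {
      co <- generate_cohort(cf)
      ind <- compute_indicators(co$prescriptions, co$panels)
      mean(ind$j01_did)
    }
    config$baseline_did <- config$baseline_did *
      target_mean_did / mean_did(pilot)
    pilot$baseline_did <- config$baseline_did
    achieved <- mean_did(pilot)
    if (abs(achieved - target_mean_did) / target_mean_did > 0.10) {
      stop(sprintf(
        "calibration failed: pilot mean DID %.2f not within 10%% of target %.2f",
        achieved, target_mean_did), call. = FALSE)
    }
  }
  config
}
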
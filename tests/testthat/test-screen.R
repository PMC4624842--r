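# One moderate synthetic cohort shared by the screen tests.
screen_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(cohort_config(n_physicians = 450L, seed = 77L))
      ind <- compute_indicators(co$prescriptions, co$panels)
      aq <- classify_aqpa(ind)
      cache <<- list(co = co, aq = aq)
    }
    cache
  }
})

test_that("model data joins outcomes, exposure and covariates per physician-year", {
  s <- screen_cohort()
  md <- build_model_data(s$aq, s$co$attitudes, s$co$physicians, s$co$panels, 11L)
  expect_named(md, c("physician_id", "year", "aqpa", "item_id", "score",
                     "on_call", "night_shifts", "mean_panel"))
  expect_equal(nrow(md), nrow(s$aq))
  expect_true(all(md$item_id == 11L))
  expect_true(all(md$aqpa %in% 0:1))
  # mean panel is constant within physician
  expect_true(all(tapply(md$mean_panel, md$physician_id,
                         function(x) length(unique(x))) == 1L))
})

test_that("the screen flags truly associated items and covers null items", {
  s <- screen_cohort()
  scr <- run_item_screen(s$aq, s$co$attitudes, s$co$physicians, s$co$panels,
                         items = c(1L, 5L, 10L, 11L))
  expect_equal(scr$status, rep("ok", 4L))
  strong_neg <- scr[scr$item_id == 5L, ]
  expect_lt(strong_neg$ci_high, 1)          # fear item: CI excludes 1
  expect_equal(strong_neg$orientation, "increase when exposure decreases")
  strong_pos <- scr[scr$item_id == 11L, ]
  expect_gt(strong_pos$ci_low, 1)           # knowledge item: CI excludes 1
  for (null_item in c(1L, 10L)) {
    row <- scr[scr$item_id == null_item, ]
    expect_lt(row$ci_low, 1)
    expect_gt(row$ci_high, 1)
  }
})

test_that("a constant-score item is skipped and the screen continues", {
  s <- screen_cohort()
  att <- s$co$attitudes
  att$score[att$item_id == 2L] <- 7
  scr <- run_item_screen(s$aq, att, s$co$physicians, s$co$panels,
                         items = c(2L, 11L))
  expect_equal(scr$status[scr$item_id == 2L], "degenerate")
  expect_match(scr$note[scr$item_id == 2L], "interquartile")
  expect_equal(scr$status[scr$item_id == 11L], "ok")
  expect_equal(nrow(scr), 2L)
})

test_that("BH adjustment is off by default and monotone when requested", {
  s <- screen_cohort()
  scr <- run_item_screen(s$aq, s$co$attitudes, s$co$physicians, s$co$panels,
                         items = c(5L, 9L, 11L), adjust = TRUE)
  expect_true("p_adj_bh" %in% names(scr))
  expect_true(all(scr$p_adj_bh >= scr$p_value - 1e-12))
  scr0 <- run_item_screen(s$aq, s$co$attitudes, s$co$physicians, s$co$panels,
                          items = 5L)
  expect_false("p_adj_bh" %in% names(scr0))
})

test_that("screen output renders as an aligned text report", {
  s <- screen_cohort()
  scr <- run_item_screen(s$aq, s$co$attitudes, s$co$physicians, s$co$panels,
                         items = c(5L, 11L))
  txt <- format_item_screen(scr)
  expect_length(txt, 3L)
  expect_match(txt[1], "IqOR")
  expect_match(txt[2], "^5")
})

test_that("the full chain recovers the sign of every nonzero true effect", {
  set.seed(88)
  effects <- with(default_vas_targets(), stats::setNames(effect, item_id))
  nonzero <- as.integer(names(effects)[effects != 0])
  strong <- as.integer(names(effects)[abs(effects) >= 0.15])
  n_rep <- 20L
  sign_ok <- matrix(NA, n_rep, length(nonzero),
                    dimnames = list(NULL, nonzero))
  for (r in seq_len(n_rep)) {
    co <- generate_cohort(cohort_config(n_physicians = 200L, seed = 8800L + r))
    aq <- classify_aqpa(compute_indicators(co$prescriptions, co$panels))
    scr <- run_item_screen(aq, co$attitudes, co$physicians, co$panels,
                           items = nonzero)
    ok <- scr$status == "ok"
    sign_ok[r, ok] <- sign(log(scr$iqor[ok])) ==
      sign(effects[as.character(scr$item_id[ok])])
  }
  # every effect's sign is recovered in the majority of replicates,
  # and the strong fear/knowledge/tracking effects almost always
  expect_true(all(colMeans(sign_ok, na.rm = TRUE) > 0.5))
  expect_true(all(colMeans(sign_ok[, as.character(strong)],
                           na.rm = TRUE) >= 0.9))
})
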
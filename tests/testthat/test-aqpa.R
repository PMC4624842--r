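test_that("is_better respects direction, ties and undefined values", {
  # cohort DID below the national reference counts as better
  expect_equal(is_better(15.65, 19.68, "lower"), "better")
  # a value exactly at the reference is not better
  expect_equal(is_better(19.68, 19.68, "lower"), "worse")
  # narrow-spectrum penicillin share: higher is better
  expect_equal(is_better(0.54, 0.50, "higher"), "better")
  expect_equal(is_better(0.43, 0.50, "higher"), "worse")
  expect_equal(is_better(NA_real_, 1, "lower"), "undefined")
  expect_equal(
    is_better(c(1, 3, NA), c(2, 2, 2), "lower"),
    c("better", "worse", "undefined")
  )
  expect_error(is_better(1, Inf, "lower"), "finite")
  expect_error(is_better(1, 1, "sideways"), "direction")
})

test_that("classify_aqpa implements the half-or-more rule with undefined counts", {
  v6 <- vector_with_pattern(c(rep("better", 6), rep("worse", 6)))
  r6 <- classify_aqpa(v6)
  expect_true(r6$aqpa)
  expect_equal(r6$n_better, 6L)
  expect_equal(r6$n_worse, 6L)

  v5 <- vector_with_pattern(c(rep("better", 5), rep("worse", 7)))
  expect_false(classify_aqpa(v5)$aqpa)

  v12 <- vector_with_pattern(rep("better", 12))
  r12 <- classify_aqpa(v12)
  expect_true(r12$aqpa)
  expect_equal(r12$n_better, 12L)

  # undefined indicators count toward neither side; threshold stays 6 of 12
  vu <- vector_with_pattern(c(rep("better", 5), rep("undefined", 7)))
  ru <- classify_aqpa(vu)
  expect_false(ru$aqpa)
  expect_equal(ru$n_undefined, 7L)
  expect_equal(ru$n_better + ru$n_worse + ru$n_undefined, 12L)
})

test_that("classification is invariant to indicator and standard ordering", {
  set.seed(21)
  v <- vector_with_pattern(sample(c("better", "worse", "tie"), 12,
                                  replace = TRUE))
  std <- reference_standard()
  shuffled_std <- std[sample(12L), ]
  shuffled_cols <- v[, c("physician_id", "year", sample(indicator_names()))]
  expect_equal(classify_aqpa(v, std), classify_aqpa(shuffled_cols, std))
  expect_equal(classify_aqpa(v, std), classify_aqpa(v, shuffled_std))
})

test_that("an incomplete or malformed standard is rejected", {
  std <- reference_standard()
  expect_error(classify_aqpa(vector_with_pattern(rep("better", 12)),
                             std[-1, ]), "missing indicator")
  std$better_direction[1] <- "sideways"
  expect_error(classify_aqpa(vector_with_pattern(rep("better", 12)), std),
               "lower")
})

test_that("cohort_indicator_report counts better among defined physician-years", {
  vecs <- dplyr::bind_rows(
    vector_with_pattern(rep("better", 12)),
    vector_with_pattern(rep("better", 12)),
    vector_with_pattern(rep("worse", 12)),
    vector_with_pattern(rep("worse", 12))
  )
  rep1 <- cohort_indicator_report(vecs)
  expect_equal(rep1$pct_better, rep(50, 12))
  expect_equal(rep1$n_defined, rep(4L, 12))

  # an indicator undefined everywhere is flagged not-computable
  vecs$j01_sv <- NA_real_
  rep2 <- cohort_indicator_report(vecs)
  expect_true(is.na(rep2$pct_better[rep2$indicator == "j01_sv"]))
  expect_equal(rep2$n_defined[rep2$indicator == "j01_sv"], 0L)
  expect_error(cohort_indicator_report(vecs[0, ]), "no physician-years")
})

test_that("cohort report equals a per-row manual count on random cohorts", {
  set.seed(22)
  std <- reference_standard()
  for (rep in 1:10) {
    vecs <- dplyr::bind_rows(lapply(1:8, function(i) {
      vector_with_pattern(sample(c("better", "worse", "tie", "undefined"),
                                 12, replace = TRUE))
    }))
    got <- cohort_indicator_report(vecs, std)
    for (j in sample(12L, 3L)) {
      v <- vecs[[std$indicator[j]]]
      manual_better <- 0L; manual_def <- 0L
      for (i in seq_along(v)) {
        if (is.na(v[i])) next
        manual_def <- manual_def + 1L
        b <- if (std$better_direction[j] == "lower") v[i] < std$reference_value[j]
             else v[i] > std$reference_value[j]
        if (b) manual_better <- manual_better + 1L
      }
      expect_equal(got$n_defined[j], manual_def)
      if (manual_def > 0) {
        expect_equal(got$pct_better[j], 100 * manual_better / manual_def)
      }
    }
  }
})

test_that("improving one indicator never flips AQPA from true to false", {
  set.seed(23)
  std <- reference_standard()
  for (rep in 1:40) {
    v <- vector_with_pattern(sample(c("better", "worse", "tie", "undefined"),
                                    12, replace = TRUE))
    before <- classify_aqpa(v, std)$aqpa
    j <- sample(12L, 1L)
    nm <- std$indicator[j]
    improved <- v
    improved[[nm]] <- if (std$better_direction[j] == "lower")
      std$reference_value[j] * 0.5 else std$reference_value[j] * 2
    after <- classify_aqpa(improved, std)$aqpa
    expect_false(before && !after)
  }
})
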
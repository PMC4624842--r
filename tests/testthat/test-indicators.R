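test_that("compute_did applies the DDD per 1000 inhabitants per day formula", {
  expect_equal(compute_did(5713.25, 1000, 365), 15.65, tolerance = 0.005 / 15.65)
  expect_equal(compute_did(0, 1500, 365), 0)
  expect_equal(compute_did(7300, 1000, 365), 20)
  expect_error(compute_did(100, 0, 365), "positive")
  expect_error(compute_did(100, 1000, 0), "positive")
  expect_error(compute_did(-1, 1000, 365), "non-negative")
})

test_that("subclass percentage and broad/narrow ratio handle zero denominators", {
  expect_equal(compute_subclass_pct(41.9, 100), 41.9)
  expect_equal(compute_subclass_pct(0, 50), 0)
  expect_true(is.na(compute_subclass_pct(0, 0)))
  expect_error(compute_subclass_pct(50, 40), "exceed")
  expect_equal(compute_bn_ratio(110, 50), 2.2)
  expect_equal(compute_bn_ratio(0, 10), 0)
  expect_true(is.na(compute_bn_ratio(10, 0)))
})

test_that("seasonal year partitions twelve months into winter and summer halves", {
  sy <- seasonal_year(2008)
  expect_equal(nrow(sy), 12L)
  expect_equal(sum(sy$season == "winter"), 6L)
  expect_equal(sum(sy$season == "summer"), 6L)
  # winter: Oct-Dec of the start year, Jan-Mar of the next
  expect_setequal(sy$month[sy$season == "winter" & sy$year == 2008], 10:12)
  expect_setequal(sy$month[sy$season == "winter" & sy$year == 2009], 1:3)
  expect_setequal(sy$month[sy$season == "summer" & sy$year == 2008], 7:9)
  expect_setequal(sy$month[sy$season == "summer" & sy$year == 2009], 4:6)
})

test_that("seasonal variation is the percent winter excess over summer", {
  rec <- tibble::tibble(
    physician_id = "A",
    year = c(2008L, 2009L),
    month = c(10L, 4L),
    atc = c("J01CR02", "J01CR02"),
    ddd_total = c(240, 200)
  )
  expect_equal(compute_seasonal_variation(rec, "J01", "A", 2008), 20)
  rec$ddd_total <- c(200, 200)
  expect_equal(compute_seasonal_variation(rec, "J01", "A", 2008), 0)
  rec$ddd_total <- c(452, 200)
  expect_equal(compute_seasonal_variation(rec, "J01", "A", 2008), 126)
  # zero summer consumption leaves the indicator undefined
  rec$ddd_total <- c(452, 0)
  expect_true(is.na(compute_seasonal_variation(rec, "J01", "A", 2008)))
})

test_that("a hand-built physician-year reproduces the spreadsheet arithmetic", {
  monthly <- tibble::tribble(
    ~atc, ~ddd,
    "J01CR02", 100,
    "J01CE02", 10,
    "J01DC02", 20,
    "J01DD08", 5,
    "J01FA01", 2,
    "J01FA09", 30,
    "J01MA02", 25,
    "J01AA02", 8
  )
  rec2009 <- tidyr::expand_grid(month = 1:12, monthly) |>
    dplyr::transmute(physician_id = "A", year = 2009L, month,
                     atc, ddd_total = ddd)
  rec2008 <- tibble::tibble(
    physician_id = "A", year = 2008L, month = 7:12, atc = "J01CR02",
    ddd_total = c(50, 50, 50, 80, 80, 80)
  )
  rec <- dplyr::bind_rows(rec2009, rec2008)
  panel <- tibble::tibble(physician_id = "A", year = 2009L, persons = 1000L)
  v <- compute_indicator_vector(rec, panel, window_start = 2008L)

  # yearly J01 total 2400 DDD over 1000 persons and 365 days
  expect_equal(v$j01_did, 2400 / 365)
  expect_equal(v$j01c_did, 1320 / 365)
  expect_equal(v$j01d_did, 300 / 365)
  expect_equal(v$j01f_did, 384 / 365)
  expect_equal(v$j01m_did, 300 / 365)
  expect_equal(v$j01ce_pct, 5)
  expect_equal(v$j01cr_pct, 50)
  expect_equal(v$j01dd_de_pct, 2.5)
  expect_equal(v$j01ma_pct, 12.5)
  # broad 1200+240+60+360, narrow 120+24
  expect_equal(v$j01_bn_ratio, 1860 / 144)
  # winter 3*80 + 3*200, summer 3*50 + 3*200
  expect_equal(v$j01_sv, 100 * (840 / 750 - 1))
  expect_equal(v$j01m_sv, 0)
})

test_that("a physician with no prescriptions gets zero DID and undefined shares", {
  rec <- tibble::tibble(physician_id = character(), year = integer(),
                        month = integer(), atc = character(),
                        ddd_total = numeric())
  panel <- tibble::tibble(physician_id = "A", year = 2009L, persons = 1200L)
  v <- compute_indicator_vector(rec, panel, window_start = 2008L)
  expect_equal(v$j01_did, 0)
  expect_equal(v$j01m_did, 0)
  expect_true(all(is.na(c(v$j01ce_pct, v$j01cr_pct, v$j01dd_de_pct,
                          v$j01ma_pct, v$j01_bn_ratio, v$j01_sv, v$j01m_sv))))
})

test_that("seasonal indicators are undefined for the extract's boundary year", {
  set.seed(11)
  co <- random_small_cohort(n_phys = 3L)
  ind <- compute_indicators(co$records, co$panels)
  expect_true(all(is.na(ind$j01_sv[ind$year == 2008])))
  expect_true(all(is.na(ind$j01m_sv[ind$year == 2008])))
})

test_that("missing panels and bad panels are rejected", {
  co <- random_small_cohort(n_phys = 2L)
  bad <- co$panels
  bad$persons[1] <- 0L
  expect_error(compute_indicators(co$records, bad), "positive")
  expect_error(compute_indicators(co$records, co$panels[0, ]), "no panel")
  expect_error(compute_indicator_vector(co$records, co$panels), "exactly one")
})

test_that("doubling all DDDs doubles DIDs and leaves shape indicators unchanged", {
  set.seed(12)
  for (rep in 1:5) {
    co <- random_small_cohort()
    ind1 <- compute_indicators(co$records, co$panels)
    rec2 <- co$records
    rec2$ddd_total <- rec2$ddd_total * 2
    ind2 <- compute_indicators(rec2, co$panels)
    for (nm in c("j01_did", "j01c_did", "j01d_did", "j01f_did", "j01m_did")) {
      expect_equal(ind2[[nm]], 2 * ind1[[nm]])
    }
    for (nm in c("j01ce_pct", "j01cr_pct", "j01dd_de_pct", "j01ma_pct",
                 "j01_bn_ratio", "j01_sv", "j01m_sv")) {
      expect_equal(ind2[[nm]], ind1[[nm]])
    }
  }
})

test_that("subgroup DIDs never exceed the total and engine matches the oracle", {
  set.seed(13)
  for (rep in 1:15) {
    co <- random_small_cohort()
    ind <- compute_indicators(co$records, co$panels)
    expect_true(all(ind$j01c_did + ind$j01d_did + ind$j01f_did +
                      ind$j01m_did <= ind$j01_did + 1e-9))
    i <- sample(nrow(ind), 1L)
    expected <- oracle_indicator_vector(
      co$records, ind$physician_id[i], ind$year[i],
      co$panels$persons[co$panels$physician_id == ind$physician_id[i] &
                          co$panels$year == ind$year[i]],
      window_start = min(co$panels$year)
    )
    got <- unlist(ind[i, indicator_names()])
    expect_equal(got, expected, tolerance = 1e-12)
  }
})
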
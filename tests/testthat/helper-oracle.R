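# Independent brute-force oracles and small-fixture builders.
# These deliberately avoid the package's vectorised paths: membership is
# decided by explicit substring comparison and every aggregate is a
# per-record loop.

oracle_member <- function(code, group) {
  pre <- function(p) substr(code, 1, nchar(p)) == p
  switch(group,
    J01 = pre("J01"), J01C = pre("J01C"), J01D = pre("J01D"),
    J01F = pre("J01F"), J01M = pre("J01M"), J01CE = pre("J01CE"),
    J01CR = pre("J01CR"), J01DD = pre("J01DD"), J01DE = pre("J01DE"),
    J01MA = pre("J01MA"), J01DB = pre("J01DB"), J01DC = pre("J01DC"),
    J01FA01 = pre("J01FA01"),
    BROAD = (pre("J01CR") || pre("J01DC") || pre("J01DD") ||
               (pre("J01F") && !pre("J01FA01"))),
    NARROW = (pre("J01CE") || pre("J01DB") || pre("J01FA01")),
    stop("oracle: unknown group ", group)
  )
}

oracle_sum <- function(records, group, phys, cells) {
  total <- 0
  for (i in seq_len(nrow(records))) {
    if (records$physician_id[i] != phys) next
    if (!oracle_member(records$atc[i], group)) next
    if (!is.null(cells) &&
        !any(records$year[i] == cells$year &
               records$month[i] == cells$month)) next
    total <- total + records$ddd_total[i]
  }
  total
}

# Per-record-loop recomputation of the 12 indicators for one physician-year.
oracle_indicator_vector <- function(records, phys, year, persons,
                                    window_start) {
  cal <- data.frame(year = rep(year, 12L), month = 1:12)
  days <- if ((year %% 4 == 0 && year %% 100 != 0) || year %% 400 == 0)
    366 else 365
  s <- function(g, cells = cal) oracle_sum(records, g, phys, cells)
  tot <- s("J01")
  did <- function(x) x / (persons * days) * 1000
  pct <- function(x) if (tot > 0) 100 * x / tot else NA_real_

  sv <- function(group) {
    if (year - 1 < window_start) return(NA_real_)
    wy <- year - 1
    winter <- data.frame(year = c(wy, wy, wy, year, year, year),
                         month = c(10, 11, 12, 1, 2, 3))
    summer <- data.frame(year = c(wy, wy, wy, year, year, year),
                         month = c(7, 8, 9, 4, 5, 6))
    w <- oracle_sum(records, group, phys, winter)
    su <- oracle_sum(records, group, phys, summer)
    if (su == 0) NA_real_ else 100 * (w / su - 1)
  }

  narrow <- s("NARROW")
  c(j01_did = did(tot), j01c_did = did(s("J01C")), j01d_did = did(s("J01D")),
    j01f_did = did(s("J01F")), j01m_did = did(s("J01M")),
    j01ce_pct = pct(s("J01CE")), j01cr_pct = pct(s("J01CR")),
    j01dd_de_pct = pct(s("J01DD") + s("J01DE")), j01ma_pct = pct(s("J01MA")),
    j01_bn_ratio = if (narrow > 0) s("BROAD") / narrow else NA_real_,
    j01_sv = sv("J01"), j01m_sv = sv("J01M"))
}

# Small random cohort of raw prescription/panel rows (not via the generator).
random_small_cohort <- function(n_phys = 4L, years = 2008:2010) {
  codes <- aqpa::j01_codes()$atc
  phys <- sprintf("P%02d", seq_len(n_phys))
  n <- sample(30:120, 1L)
  records <- tibble::tibble(
    physician_id = sample(phys, n, replace = TRUE),
    year = sample(years, n, replace = TRUE),
    month = sample(1:12, n, replace = TRUE),
    atc = sample(codes, n, replace = TRUE),
    ddd_total = round(stats::rexp(n, 1 / 40), 1)
  )
  records <- suppressWarnings(aqpa::validate_prescriptions(records))
  panels <- tibble::tibble(
    physician_id = rep(phys, each = length(years)),
    year = rep(years, times = n_phys),
    persons = sample(500:2500, n_phys * length(years), replace = TRUE)
  )
  list(records = records, panels = panels)
}

# Indicator vectors with prescribed better/worse/undefined pattern relative
# to the default reference standard.
vector_with_pattern <- function(pattern) {
  std <- aqpa::reference_standard()
  stopifnot(length(pattern) == 12L)
  val <- numeric(12L)
  for (j in seq_len(12L)) {
    ref <- std$reference_value[j]
    dir <- std$better_direction[j]
    val[j] <- switch(pattern[j],
      better = if (dir == "lower") ref * 0.8 else ref * 1.2,
      worse = if (dir == "lower") ref * 1.2 else ref * 0.8,
      tie = ref,
      undefined = NA_real_
    )
  }
  out <- tibble::as_tibble(as.list(stats::setNames(val, std$indicator)))
  dplyr::bind_cols(tibble::tibble(physician_id = "P01", year = 2009L), out)
}
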
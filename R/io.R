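# Delimited-text readers, writers and schema validators for every pipeline
# stage.  All tables are plain CSV (UTF-8, "." decimal separator, header
# required); writers prepend "#"-prefixed provenance comment lines that
# readers skip.

.read_csv_quiet <- function(path, col_types) {
  readr::read_csv(path, col_types = col_types, comment = "#",
                  progress = FALSE, lazy = FALSE)
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Validate (and normalise) prescription records
#'
#' Checks the schema (`physician_id`, `year`, `month`, `atc`, `ddd_total`),
#' the month range, non-negative DDDs and the ATC grammar, addressing
#' offending rows in error messages.  Duplicate
#' (physician, year, month, atc) rows are summed with a warning rather than
#' rejected, since dispensing extracts commonly split lines.
#'
#' @param df Data frame of raw prescription rows.
#' @return Validated tibble, one row per (physician, year, month, atc).
#' @export
validate_prescriptions <- function(df) {
  .require_cols(df, c("physician_id", "year", "month", "atc", "ddd_total"),
                "prescription")
  bad_month <- which(!(df$month %in% 1:12))
  if (length(bad_month)) {
    stop("invalid month ", df$month[bad_month[1]], " in prescription row ",
         bad_month[1], call. = FALSE)
  }
  bad_ddd <- which(is.na(df$ddd_total) | df$ddd_total < 0)
  if (length(bad_ddd)) {
    stop("negative or missing ddd_total in prescription row ", bad_ddd[1],
         call. = FALSE)
  }
  out <- tibble::tibble(
    physician_id = as.character(df$physician_id),
    year = as.integer(df$year),
    month = as.integer(df$month),
    atc = parse_atc(df$atc),
    ddd_total = as.numeric(df$ddd_total)
  )
  key <- paste(out$physician_id, out$year, out$month, out$atc)
  if (anyDuplicated(key)) {
    warning("duplicate (physician, year, month, atc) rows summed on ingest",
            call. = FALSE)
    out <- dplyr::summarise(
      dplyr::group_by(out, .data$physician_id, .data$year, .data$month,
                      .data$atc),
      ddd_total = sum(.data$ddd_total), .groups = "drop"
    )
  }
  out
}

#' Validate panel records
#' @param df Data frame with `physician_id`, `year`, `persons`.
#' @return Validated tibble.
#' @export
validate_panels <- function(df) {
  .require_cols(df, c("physician_id", "year", "persons"), "panel")
  bad <- which(is.na(df$persons) | df$persons <= 0)
  if (length(bad)) {
    stop("non-positive panel size in panel row ", bad[1], call. = FALSE)
  }
  out <- tibble::tibble(
    physician_id = as.character(df$physician_id),
    year = as.integer(df$year),
    persons = as.integer(df$persons)
  )
  if (anyDuplicated(paste(out$physician_id, out$year))) {
    stop("duplicate physician-year rows in panel table", call. = FALSE)
  }
  out
}

#' Validate attitude responses
#' @param df Data frame with `physician_id`, `item_id`, `score` and
#'   optionally `retest_score`.
#' @return Validated tibble (a missing `retest_score` column is added as
#'   `NA`).
#' @export
validate_attitudes <- function(df) {
  .require_cols(df, c("physician_id", "item_id", "score"), "attitude")
  if (!"retest_score" %in% names(df)) df$retest_score <- NA_real_
  for (col in c("score", "retest_score")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 10))
    if (length(bad)) {
      stop(col, " outside the 0-10 VAS range in attitude row ", bad[1],
           call. = FALSE)
    }
  }
  out <- tibble::tibble(
    physician_id = as.character(df$physician_id),
    item_id = as.integer(df$item_id),
    score = as.numeric(df$score),
    retest_score = as.numeric(df$retest_score)
  )
  if (anyDuplicated(paste(out$physician_id, out$item_id))) {
    stop("duplicate (physician, item) attitude responses", call. = FALSE)
  }
  out
}

#' Read pipeline tables from CSV
#'
#' Each reader parses the stage's CSV schema, skips `#` provenance comment
#' lines, and runs the corresponding validator.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @name pipeline_readers
NULL

#' @rdname pipeline_readers
#' @export
read_prescriptions <- function(path) {
  validate_prescriptions(.read_csv_quiet(path, readr::cols(
    physician_id = readr::col_character(), year = readr::col_integer(),
    month = readr::col_integer(), atc = readr::col_character(),
    ddd_total = readr::col_double()
  )))
}

#' @rdname pipeline_readers
#' @export
read_panels <- function(path) {
  validate_panels(.read_csv_quiet(path, readr::cols(
    physician_id = readr::col_character(), year = readr::col_integer(),
    persons = readr::col_integer()
  )))
}

#' @rdname pipeline_readers
#' @export
read_attitudes <- function(path) {
  validate_attitudes(.read_csv_quiet(path, readr::cols(
    .default = readr::col_double(), physician_id = readr::col_character(),
    item_id = readr::col_integer()
  )))
}

#' @rdname pipeline_readers
#' @export
read_physicians <- function(path) {
  df <- .read_csv_quiet(path, readr::cols(
    physician_id = readr::col_character(), on_call = readr::col_integer(),
    night_shifts = readr::col_integer()
  ))
  .require_cols(df, c("physician_id", "on_call", "night_shifts"), "physician")
  df
}

#' @rdname pipeline_readers
#' @export
read_indicators <- function(path) {
  df <- .read_csv_quiet(path, readr::cols(
    .default = readr::col_double(), physician_id = readr::col_character(),
    year = readr::col_integer()
  ))
  .require_cols(df, c("physician_id", "year", indicator_names()), "indicator")
  df
}

#' @rdname pipeline_readers
#' @export
read_aqpa <- function(path) {
  df <- .read_csv_quiet(path, readr::cols(
    physician_id = readr::col_character(), year = readr::col_integer(),
    n_better = readr::col_integer(), n_worse = readr::col_integer(),
    n_undefined = readr::col_integer(), aqpa = readr::col_logical()
  ))
  .require_cols(df, c("physician_id", "year", "n_better", "n_worse",
                      "n_undefined", "aqpa"), "AQPA")
  df
}

#' Read a reference standard from CSV
#'
#' Expects columns `indicator`, `reference_value`, `better_direction`; all 12
#' indicators must be present.
#'
#' @param path Path to the CSV file.
#' @return Validated reference-standard tibble in canonical indicator order.
#' @export
read_reference_standard <- function(path) {
  df <- .read_csv_quiet(path, readr::cols(
    indicator = readr::col_character(),
    reference_value = readr::col_double(),
    better_direction = readr::col_character()
  ))
  .check_standard(df)
}

#' Write a pipeline table as CSV with a provenance header
#'
#' Numeric columns are written with six significant digits so output is
#' stable and diffable.  The provenance header carries the package version
#' and any caller-supplied key-value pairs (e.g. seed); set `timestamp =
#' FALSE` for byte-reproducible output.
#'
#' @param df Tibble to write.
#' @param path Output path.
#' @param provenance Named character vector of extra header fields.
#' @param timestamp Include a write timestamp in the header.
#' @return `path`, invisibly.
#' @export
write_pipeline_csv <- function(df, path, provenance = character(),
                               timestamp = FALSE) {
  out <- df
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  for (j in which(num)) out[[j]] <- signif(out[[j]], 6)
  hdr <- c(
    sprintf("# aqpa %s", as.character(utils::packageVersion("aqpa"))),
    if (timestamp) sprintf("# written %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    if (length(provenance)) sprintf("# %s %s", names(provenance), provenance)
  )
  writeLines(hdr, path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Write simulated cohort ground truth as JSON
#'
#' @param ground_truth The `ground_truth` element of [generate_cohort()]
#'   output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(
    list(
      seed = ground_truth$seed,
      sigma_u = ground_truth$sigma_u,
      effects = as.list(ground_truth$effects),
      latent_quality = ground_truth$latent_quality
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
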
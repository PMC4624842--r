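# ATC code grammar, the J01 subgroup taxonomy, and DDD aggregation.

# Valid code shapes by length: A, A02, A02B, A02BC, A02BC01.
.atc_regex <- c(
  "1" = "^[A-Z]$",
  "3" = "^[A-Z][0-9]{2}$",
  "4" = "^[A-Z][0-9]{2}[A-Z]$",
  "5" = "^[A-Z][0-9]{2}[A-Z]{2}$",
  "7" = "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
)

#' Parse and validate ATC codes
#'
#' Normalises (trims, upper-cases) character input and validates it against
#' the WHO ATC grammar: codes of length 1, 3, 4, 5 or 7 with the alternating
#' letter/digit pattern of the classification (e.g. `"J01"`, `"J01CR"`,
#' `"J01CR02"`).
#'
#' @param x Character vector of putative ATC codes.
#' @return A character vector of validated, normalised ATC codes.
#' @examples
#' parse_atc(c("j01cr02", "J01"))
#' @export
parse_atc <- function(x) {
  if (length(x) == 0L) stop("no ATC codes supplied", call. = FALSE)
  code <- toupper(trimws(as.character(x)))
  len <- nchar(code)
  ok <- !is.na(code) & len %in% c(1L, 3L, 4L, 5L, 7L)
  idx <- which(ok)
  ok[idx] <- vapply(idx, function(i) {
    grepl(.atc_regex[[as.character(len[i])]], code[i])
  }, logical(1))
  if (!all(ok)) {
    bad <- unique(x[!ok])
    stop("malformed ATC code(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  code
}

#' The J01 group map used by the ESAC indicators
#'
#' Returns the named code-sets over antibacterials for systemic use (J01) that
#' the prescription-quality indicators draw on.  Plain groups are prefix sets
#' (`J01`, `J01C`, `J01D`, `J01F`, `J01M`, `J01CE`, `J01CR`, `J01DD`, `J01DE`,
#' `J01MA`, `J01DB`, `J01DC`, `J01FA01`).  Two derived spectra sets are
#' defined for the broad/narrow ratio:
#' \describe{
#'   \item{BROAD}{penicillin/beta-lactamase-inhibitor combinations (J01CR),
#'     second-generation cephalosporins (J01DC), third-generation
#'     cephalosporins (J01DD) and macrolides/lincosamides/streptogramins other
#'     than erythromycin (J01F minus J01FA01).}
#'   \item{NARROW}{beta-lactamase-sensitive penicillins (J01CE),
#'     first-generation cephalosporins (J01DB) and erythromycin (J01FA01).}
#' }
#' Membership is decided by prefix matching so inputs may mix chemical-subgroup
#' (5-character) and substance (7-character) codes.
#'
#' @return A named list; each element has character vectors `include` and
#'   `exclude` of code prefixes.
#' @export
atc_group_map <- function() {
  grp <- function(include, exclude = character()) {
    list(include = include, exclude = exclude)
  }
  list(
    J01     = grp("J01"),
    J01C    = grp("J01C"),
    J01D    = grp("J01D"),
    J01F    = grp("J01F"),
    J01M    = grp("J01M"),
    J01CE   = grp("J01CE"),
    J01CR   = grp("J01CR"),
    J01DD   = grp("J01DD"),
    J01DE   = grp("J01DE"),
    J01MA   = grp("J01MA"),
    J01DB   = grp("J01DB"),
    J01DC   = grp("J01DC"),
    J01FA01 = grp("J01FA01"),
    BROAD   = grp(c("J01CR", "J01DC", "J01DD", "J01F"), exclude = "J01FA01"),
    NARROW  = grp(c("J01CE", "J01DB", "J01FA01"))
  )
}

.has_prefix <- function(code, prefixes) {
  if (length(prefixes) == 0L) return(rep(FALSE, length(code)))
  hit <- rep(FALSE, length(code))
  for (p in prefixes) hit <- hit | startsWith(code, p)
  hit
}

#' Test group membership of ATC codes
#'
#' A code belongs to a group when one of the group's include prefixes is a
#' prefix of the code and no exclude prefix is.  Erythromycin (`J01FA01`)
#' therefore falls in `NARROW` but not in `BROAD` even though it matches the
#' `J01F` prefix.
#'
#' @param code Character vector of ATC codes (validated with [parse_atc()]).
#' @param group Single group name from [atc_group_map()].
#' @param map Group map, defaults to [atc_group_map()].
#' @return Logical vector.
#' @examples
#' in_group("J01CR02", "J01CR")
#' in_group("J01FA01", "BROAD")
#' @export
in_group <- function(code, group, map = atc_group_map()) {
  if (length(group) != 1L || !group %in% names(map)) {
    stop("unknown ATC group: ", paste(group, collapse = ", "), call. = FALSE)
  }
  g <- map[[group]]
  .has_prefix(code, g$include) & !.has_prefix(code, g$exclude)
}

#' Sum dispensed DDDs over a physician/group/period slice
#'
#' @param records Prescription records as returned by [read_prescriptions()] or
#'   [validate_prescriptions()]: columns `physician_id`, `year`, `month`,
#'   `atc`, `ddd_total`.
#' @param group Group name from `map`; `NULL` selects all records.
#' @param physician_id Physician to restrict to; `NULL` selects all.
#' @param period Data frame with columns `year` and `month` giving the
#'   (year, month) cells to include; `NULL` selects all.
#' @param map Group map, defaults to [atc_group_map()].
#' @return A single non-negative number (DDD); 0 when nothing matches.
#' @export
aggregate_ddd <- function(records, group = NULL, physician_id = NULL,
                          period = NULL, map = atc_group_map()) {
  sel <- rep(TRUE, nrow(records))
  if (!is.null(physician_id)) sel <- sel & records$physician_id %in% physician_id
  if (!is.null(group)) sel <- sel & in_group(records$atc, group, map)
  if (!is.null(period)) {
    key <- paste(records$year, records$month)
    sel <- sel & key %in% paste(period$year, period$month)
  }
  sum(records$ddd_total[sel])
}

#' Bundled J01 substance codes
#'
#' A representative set of level-5 (substance) J01 codes spanning every class
#' cell the group map distinguishes.  It is sufficient for the group map and
#' the synthetic-cohort generator; it is not the complete WHO J01 register.
#'
#' @return A tibble with columns `atc`, `class` (generator class cell) and
#'   `name`.
#' @export
j01_codes <- function() {
  tibble::tribble(
    ~atc,      ~class,    ~name,
    "J01CA04", "J01CA",   "amoxicillin",
    "J01CA01", "J01CA",   "ampicillin",
    "J01CE02", "J01CE",   "phenoxymethylpenicillin",
    "J01CE01", "J01CE",   "benzylpenicillin",
    "J01CF02", "J01CF",   "cloxacillin",
    "J01CR02", "J01CR",   "amoxicillin and beta-lactamase inhibitor",
    "J01CR05", "J01CR",   "piperacillin and beta-lactamase inhibitor",
    "J01DB01", "J01DB",   "cefalexin",
    "J01DB05", "J01DB",   "cefadroxil",
    "J01DC02", "J01DC",   "cefuroxime",
    "J01DC04", "J01DC",   "cefaclor",
    "J01DD08", "J01DD",   "cefixime",
    "J01DD14", "J01DD",   "ceftibuten",
    "J01DE01", "J01DE",   "cefepime",
    "J01FA01", "J01FA01", "erythromycin",
    "J01FA09", "J01Foth", "clarithromycin",
    "J01FA10", "J01Foth", "azithromycin",
    "J01FA02", "J01Foth", "spiramycin",
    "J01FF01", "J01Foth", "clindamycin",
    "J01MA02", "J01MA",   "ciprofloxacin",
    "J01MA12", "J01MA",   "levofloxacin",
    "J01MA14", "J01MA",   "moxifloxacin",
    "J01MA06", "J01MA",   "norfloxacin",
    "J01MB04", "J01MB",   "pipemidic acid",
    "J01AA02", "J01oth",  "doxycycline",
    "J01EE01", "J01oth",  "sulfamethoxazole and trimethoprim",
    "J01XE01", "J01oth",  "nitrofurantoin",
    "J01XX08", "J01oth",  "linezolid"
  )
}
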
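# Claims data model: column schemas, closed vocabularies, readers/writers,
# and cross-table validation.

# Closed vocabularies ------------------------------------------------------

#' Vocabularies of the claims data model
#'
#' Closed sets of tokens used by the admissions and events tables:
#' infection-site codes (plus the explicit `"unknown"` code), site labels
#' after collapsing, sex, discharge status, and clinical event types.
#'
#' @format Character vectors.
#' @name claims_vocabulary
NULL

#' @rdname claims_vocabulary
#' @export
site_codes <- function() {
  c("respiratory", "urogenital", "abdominal", "bone_soft_tissue",
    "meninges_brain_spinal", "heart", "blood")
}

#' @rdname claims_vocabulary
#' @export
site_labels <- function() {
  c(site_codes(), "multiple", "unknown", "missing")
}

#' @rdname claims_vocabulary
#' @export
event_types <- function() {
  c("iv_antibiotic", "blood_culture", "vasopressor",
    "mechanical_ventilation", "oxygen_supplementation", "diuretic",
    "renal_dysfunction_code", "renal_replacement_therapy",
    "liver_dysfunction_code", "thrombocytopenia_code",
    "metabolic_acidosis_code")
}

discharge_statuses <- function() c("home", "nursing_facility", "transfer", "death")
sexes <- function() c("male", "female")

admissions_schema <- function() {
  c("admission_id", "patient_id", "admission_year", "age", "sex",
    "length_of_stay", "discharge_status", "icu_admission", "surgery",
    "chronic_disease_count", "infection_site_codes", "total_cost")
}

events_schema <- function() c("admission_id", "day_index", "event_type", "agent")

# Series config -------------------------------------------------------------

#' Cost-adjustment series configuration
#'
#' Bundles the three series every cost computation needs: a consumer price
#' index (CPI) by year, the count of patients registered in the claims system
#' by year, the reference year whose prices and registrant count anchor
#' adjustment, and the JPY-per-USD exchange rate.
#'
#' @param cpi_by_year Named numeric vector, names are calendar years,
#'   values CPI index levels (> 0).
#' @param registrants_by_year Named numeric vector of yearly registrant
#'   counts (> 0).
#' @param reference_year Year anchoring CPI deflation and registrant
#'   adjustment; must be present in both series.
#' @param jpy_per_usd Exchange rate in yen per US dollar (> 0).
#' @return A `series_config` object (a validated list).
#' @seealso [default_series_config()], [read_series_config()]
#' @export
series_config <- function(cpi_by_year, registrants_by_year, reference_year,
                          jpy_per_usd) {
  s <- structure(
    list(cpi_by_year = unlist(cpi_by_year),
         registrants_by_year = unlist(registrants_by_year),
         reference_year = as.integer(reference_year),
         jpy_per_usd = as.numeric(jpy_per_usd)),
    class = "series_config"
  )
  validate_series_config(s)
  s
}

validate_series_config <- function(s) {
  if (any(s$cpi_by_year <= 0)) stop("all CPI values must be > 0", call. = FALSE)
  if (any(s$registrants_by_year <= 0))
    stop("all registrant counts must be > 0", call. = FALSE)
  if (s$jpy_per_usd <= 0)
    stop("jpy_per_usd must be > 0", call. = FALSE)
  ry <- as.character(s$reference_year)
  if (!ry %in% names(s$cpi_by_year))
    stop("reference_year ", ry, " missing from cpi_by_year", call. = FALSE)
  if (!ry %in% names(s$registrants_by_year))
    stop("reference_year ", ry, " missing from registrants_by_year", call. = FALSE)
  invisible(s)
}

#' Read a series configuration from YAML or JSON
#'
#' The file must contain keys `cpi_by_year`, `registrants_by_year`,
#' `reference_year` and `jpy_per_usd`; year maps are given as mappings from
#' year to value.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `series_config` object.
#' @export
read_series_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (k in c("cpi_by_year", "registrants_by_year", "reference_year",
              "jpy_per_usd")) {
    if (is.null(raw[[k]])) stop("config is missing key '", k, "'", call. = FALSE)
  }
  series_config(raw$cpi_by_year, raw$registrants_by_year,
                raw$reference_year, raw$jpy_per_usd)
}

# Readers -------------------------------------------------------------------

parse_site_cell <- function(x) {
  # ";"-separated cell -> character vector of codes; empty/NA -> character(0)
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  codes <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  codes[nzchar(codes)]
}

check_tokens <- function(x, allowed, field, id, line) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad)) {
    sprintf("line %d (%s): %s '%s' not one of {%s}",
            line, id, field, bad[1], paste(allowed, collapse = ", "))
  } else {
    character(0)
  }
}

#' Read an admissions table
#'
#' Reads a comma-separated admissions file (UTF-8, one header row) into a
#' tibble of hospitalization records. The `infection_site_codes` cell is a
#' `";"`-separated set of site codes (possibly empty) and is parsed into a
#' list-column of character vectors.
#'
#' All schema and invariant violations are reported as errors: a missing
#' column names the column; a bad value names the line; duplicate
#' `admission_id` values are rejected.
#'
#' @param path Path to `admissions.csv`.
#' @return A tibble with columns `admission_id`, `patient_id`,
#'   `admission_year`, `age`, `sex`, `length_of_stay`, `discharge_status`,
#'   `icu_admission`, `surgery`, `chronic_disease_count`,
#'   `infection_site_codes` (list-column), `total_cost` (nominal JPY).
#' @seealso [read_events()], [validate_claims()], [write_admissions()]
#' @export
read_admissions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing_cols <- setdiff(admissions_schema(), names(df))
  if (length(missing_cols))
    stop("admissions file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  adm <- tibble::tibble(
    admission_id = df$admission_id,
    patient_id = df$patient_id,
    admission_year = suppressWarnings(as.integer(df$admission_year)),
    age = suppressWarnings(as.integer(df$age)),
    sex = df$sex,
    length_of_stay = suppressWarnings(as.integer(df$length_of_stay)),
    discharge_status = df$discharge_status,
    icu_admission = parse_bool(df$icu_admission),
    surgery = parse_bool(df$surgery),
    chronic_disease_count = suppressWarnings(as.integer(df$chronic_disease_count)),
    infection_site_codes = lapply(df$infection_site_codes, parse_site_cell),
    total_cost = suppressWarnings(as.numeric(df$total_cost))
  )
  problems <- admission_violations(adm, line_offset = 1L)
  if (length(problems))
    stop("invalid admissions file:\n", paste(problems, collapse = "\n"),
         call. = FALSE)
  adm
}

parse_bool <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  out
}

# Row-level invariant checks shared by read_admissions() and validate_claims().
admission_violations <- function(adm, line_offset = 0L) {
  v <- character(0)
  line <- seq_len(nrow(adm)) + line_offset
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i))
      sprintf("line %d (%s): %s", line[i], adm$admission_id[i], msg)
    else character(0)
  }
  v <- c(v,
    bad(is.na(adm$admission_year), "unparseable admission_year"),
    bad(is.na(adm$age) | adm$age < 0, "age must be an integer >= 0"),
    bad(!adm$sex %in% sexes(),
        paste0("sex must be one of {", paste(sexes(), collapse = ", "), "}")),
    bad(is.na(adm$length_of_stay) | adm$length_of_stay < 1,
        "length_of_stay must be an integer >= 1"),
    bad(!adm$discharge_status %in% discharge_statuses(),
        paste0("discharge_status must be one of {",
               paste(discharge_statuses(), collapse = ", "), "}")),
    bad(is.na(adm$icu_admission), "icu_admission must be true/false"),
    bad(is.na(adm$surgery), "surgery must be true/false"),
    bad(is.na(adm$chronic_disease_count) | adm$chronic_disease_count < 0 |
          adm$chronic_disease_count > 8,
        "chronic_disease_count must be an integer in 0..8"),
    bad(is.na(adm$total_cost) | adm$total_cost < 0,
        "total_cost must be >= 0")
  )
  allowed <- c(site_codes(), "unknown")
  site_bad <- vapply(adm$infection_site_codes,
                     function(s) length(setdiff(s, allowed)) > 0, logical(1))
  v <- c(v, bad(site_bad,
                paste0("infection_site_codes must be drawn from {",
                       paste(allowed, collapse = ", "), "}")))
  dup <- duplicated(adm$admission_id)
  v <- c(v, bad(dup, "duplicate admission_id"))
  v
}

#' Read an events table
#'
#' Reads a comma-separated daily-events file into a tibble of dated clinical
#' events. `agent` is required exactly for `iv_antibiotic` events and must be
#' empty otherwise.
#'
#' @param path Path to `events.csv`.
#' @return A tibble with columns `admission_id`, `day_index` (1-based day of
#'   stay), `event_type`, `agent` (`NA` except for antibiotics).
#' @seealso [read_admissions()], [validate_claims()]
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing_cols <- setdiff(events_schema(), names(df))
  if (length(missing_cols))
    stop("events file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ev <- tibble::tibble(
    admission_id = df$admission_id,
    day_index = suppressWarnings(as.integer(df$day_index)),
    event_type = df$event_type,
    agent = ifelse(is.na(df$agent) | !nzchar(trimws(df$agent)), NA_character_,
                   trimws(df$agent))
  )
  problems <- event_violations(ev, line_offset = 1L)
  if (length(problems))
    stop("invalid events file:\n", paste(problems, collapse = "\n"),
         call. = FALSE)
  ev
}

event_violations <- function(ev, line_offset = 0L) {
  line <- seq_len(nrow(ev)) + line_offset
  v <- character(0)
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) sprintf("line %d (%s): %s", line[i], ev$admission_id[i], msg)
    else character(0)
  }
  c(v,
    bad(is.na(ev$day_index) | ev$day_index < 1,
        "day_index must be an integer >= 1"),
    bad(!ev$event_type %in% event_types(),
        paste0("event_type must be one of {",
               paste(event_types(), collapse = ", "), "}")),
    bad(ev$event_type == "iv_antibiotic" & is.na(ev$agent),
        "iv_antibiotic events require an agent"),
    bad(ev$event_type != "iv_antibiotic" & !is.na(ev$agent),
        "agent is only allowed on iv_antibiotic events")
  )
}

# Writers -------------------------------------------------------------------

#' Write claims tables
#'
#' Writes admissions or events back to the documented CSV dialect
#' (comma-separated, UTF-8, one header row, `";"` as the inner separator of
#' the `infection_site_codes` set). `write_admissions(read_admissions(f))`
#' reproduces `f` record-for-record.
#'
#' @param admissions,events Tibbles as returned by [read_admissions()] /
#'   [read_events()].
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_admissions <- function(admissions, path) {
  out <- admissions
  out$infection_site_codes <- vapply(admissions$infection_site_codes,
                                     paste, character(1), collapse = ";")
  readr::write_csv(out, path, progress = FALSE)
  invisible(admissions)
}

#' @rdname write_admissions
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path, na = "", progress = FALSE)
  invisible(events)
}

# Validation ----------------------------------------------------------------

#' Validate a pair of claims tables
#'
#' Collects every invariant and referential-integrity violation across the
#' two tables: admission-level invariants, event-level invariants, events
#' referencing unknown admissions, and `day_index` beyond the referenced
#' stay. Violations are data, not exceptions: the report lists all of them.
#'
#' @param admissions Admissions tibble.
#' @param events Events tibble.
#' @return A `validation_report`: list with `n_admissions`, `n_events`,
#'   `violations` (tibble with `rule`, `id`, `message`), and `pass`
#'   (`TRUE` iff zero violations).
#' @export
#' @examples
#' sim <- generate_claims(default_generator_config(scale = 1 / 2000), seed = 1)
#' validate_claims(sim$admissions, sim$events)$pass
validate_claims <- function(admissions, events) {
  viol <- list()
  add <- function(rule, id, message) {
    if (length(id))
      viol[[length(viol) + 1L]] <<- tibble::tibble(rule = rule, id = id,
                                                   message = message)
  }
  av <- admission_violations(admissions)
  if (length(av)) add("admission_invariant",
                      sub("^line \\d+ \\(([^)]*)\\).*$", "\\1", av), av)
  ev <- event_violations(events)
  if (length(ev)) add("event_invariant",
                      sub("^line \\d+ \\(([^)]*)\\).*$", "\\1", ev), ev)

  unknown <- !events$admission_id %in% admissions$admission_id
  add("unknown_admission", events$admission_id[unknown],
      sprintf("event references unknown admission '%s'",
              events$admission_id[unknown]))

  los <- admissions$length_of_stay[match(events$admission_id,
                                         admissions$admission_id)]
  beyond <- !is.na(los) & !is.na(events$day_index) & events$day_index > los
  add("day_beyond_stay", events$admission_id[beyond],
      sprintf("day_index %d exceeds length_of_stay %d for admission '%s'",
              events$day_index[beyond], los[beyond],
              events$admission_id[beyond]))

  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(rule = character(0), id = character(0),
                   message = character(0))
  structure(
    list(n_admissions = nrow(admissions), n_events = nrow(events),
         violations = violations, pass = nrow(violations) == 0L),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Claims validation report\n")
  cat("  admissions:", x$n_admissions, " events:", x$n_events, "\n")
  cat("  violations:", nrow(x$violations), "->",
      if (x$pass) "PASS" else "FAIL", "\n")
  if (!x$pass) print(x$violations, ...)
  invisible(x)
}
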
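# Cost adjustment and yearly cost/effectiveness aggregates: CPI deflation,
# USD conversion, registrant adjustment, daily cost, survivor counts with
# repeat-admission deduplication, effective cost per survivor.

year_lookup <- function(series, field, year) {
  v <- series[[field]][as.character(year)]
  if (anyNA(v)) {
    missing <- unique(year[is.na(v)])
    stop("year(s) ", paste(missing, collapse = ", "), " missing from ",
         field, call. = FALSE)
  }
  unname(v)
}

#' Deflate nominal costs to reference-year prices
#'
#' `cost * CPI[reference_year] / CPI[year]`, expressing a nominal cost in
#' the prices of the series' reference year.
#'
#' @param cost Numeric cost(s) in nominal currency.
#' @param year Admission year(s), recycled against `cost`.
#' @param series A [series_config()].
#' @return Deflated cost(s), same currency.
#' @export
#' @examples
#' s <- default_series_config()
#' cpi_adjust(1000, 2017, s)  # reference year: unchanged
cpi_adjust <- function(cost, year, series) {
  stopifnot(inherits(series, "series_config"))
  cost * year_lookup(series, "cpi_by_year", series$reference_year) /
    year_lookup(series, "cpi_by_year", year)
}

#' Convert JPY to USD
#'
#' @param cost Cost(s) in JPY.
#' @param series A [series_config()]; the rate is `series$jpy_per_usd`.
#' @return Cost(s) in USD.
#' @export
#' @examples
#' to_usd(115.25, default_series_config())  # 1
to_usd <- function(cost, series) {
  stopifnot(inherits(series, "series_config"))
  if (series$jpy_per_usd <= 0) stop("jpy_per_usd must be > 0", call. = FALSE)
  cost / series$jpy_per_usd
}

# nominal JPY -> CPI-adjusted (reference-year) USD; the fixed pipeline order
adjusted_usd <- function(cost, year, series) {
  to_usd(cpi_adjust(cost, year, series), series)
}

#' Daily medical cost per person
#'
#' Adjusted total cost divided by length of stay.
#'
#' @param admissions Admissions tibble (needs `total_cost`,
#'   `admission_year`, `length_of_stay`).
#' @param series A [series_config()].
#' @return Numeric vector of daily costs in reference-year USD.
#' @export
daily_cost <- function(admissions, series) {
  if (any(admissions$length_of_stay < 1))
    stop("length_of_stay must be >= 1", call. = FALSE)
  adjusted_usd(admissions$total_cost, admissions$admission_year, series) /
    admissions$length_of_stay
}

#' Adjust yearly gross costs for claims-system coverage
#'
#' Rescales each year's gross cost by the ratio of reference-year to
#' that-year registrant counts, correcting for growth in database coverage:
#' `adjusted[y] = gross[y] * registrants[reference_year] / registrants[y]`.
#' The reference year is unchanged.
#'
#' @param gross_by_year Named numeric vector (names = years).
#' @param series A [series_config()].
#' @return Named numeric vector of adjusted gross costs.
#' @export
registrant_adjust <- function(gross_by_year, series) {
  stopifnot(inherits(series, "series_config"))
  years <- names(gross_by_year)
  if (is.null(years)) stop("gross_by_year must be named by year", call. = FALSE)
  ref <- year_lookup(series, "registrants_by_year", series$reference_year)
  gross_by_year * ref / year_lookup(series, "registrants_by_year", years)
}

# First (earliest-year, then first-listed) admission per patient.
dedup_first_admission <- function(adm) {
  adm <- adm[order(adm$admission_year, adm$admission_id), ]
  adm[!duplicated(adm$patient_id), ]
}

#' Yearly survivor counts with repeat-admission deduplication
#'
#' Deduplicates to the first admission per `patient_id` (earliest year,
#' ties broken by admission id order), assigns each unique patient to the
#' year of that retained admission, and counts deaths and survivors by the
#' retained admission's discharge status. `deaths + survivors =
#' unique patients` in every year.
#'
#' @param cohort A `sepsis_cohort` (from [build_cohort()]) or an admissions
#'   tibble with `patient_id`, `admission_year`, `discharge_status`.
#' @return Tibble with `year`, `n_unique_patients`, `n_deaths`,
#'   `n_survivors`.
#' @export
survivors_per_year <- function(cohort) {
  adm <- if (inherits(cohort, "sepsis_cohort")) cohort$included else cohort
  first <- dedup_first_admission(adm)
  first |>
    dplyr::group_by(year = .data$admission_year) |>
    dplyr::summarise(
      n_unique_patients = dplyr::n(),
      n_deaths = sum(.data$discharge_status == "death"),
      n_survivors = sum(.data$discharge_status != "death"),
      .groups = "drop")
}

#' Effective cost per survivor
#'
#' The cost-effectiveness metric: annual gross medical cost of *all*
#' treated patients (survivors and non-survivors, no deduplication in the
#' numerator) divided by the number of surviving unique patients that year.
#' Years with zero survivors yield `NA` with a warning.
#'
#' @param gross_cost Numeric vector of yearly gross costs.
#' @param survivors Integer vector of yearly survivor counts.
#' @return Numeric vector, USD per survivor.
#' @export
#' @examples
#' effective_cost_per_survivor(2e6, 100)  # 20000
effective_cost_per_survivor <- function(gross_cost, survivors) {
  out <- ifelse(survivors > 0, gross_cost / survivors, NA_real_)
  if (anyNA(out))
    warning("effective cost per survivor undefined for year(s) with zero ",
            "survivors; reported as NA", call. = FALSE)
  out
}

fivenum_stats <- function(x, prefix) {
  # Tukey hinges (median-of-halves quartile convention)
  if (length(x) == 0L) {
    v <- rep(NA_real_, 5)
  } else {
    f <- stats::fivenum(x)
    v <- c(mean(x), stats::sd(x), f[3], f[2], f[4])
  }
  stats::setNames(as.list(v),
                  paste0(prefix, c("_mean", "_sd", "_median", "_q1", "_q3")))
}

#' Yearly cost and cost-effectiveness summary
#'
#' One row per calendar year with the pipeline's cost aggregates, all
#' CPI-deflated to the reference year and converted to USD before
#' aggregation: gross cost over all admissions, registrant-adjusted gross
#' cost, mean/SD/median/quartiles of per-hospitalization cost, of daily
#' cost per person, and of length of stay, unique-patient and death counts
#' (repeat admissions removed), survivors, and effective cost per survivor.
#' Quartiles use Tukey hinges (median-of-halves).
#'
#' @param cohort A `sepsis_cohort` or admissions tibble (see
#'   [survivors_per_year()]).
#' @param series A [series_config()].
#' @param ecs_uses_adjusted_gross If `TRUE`, the effective-cost-per-survivor
#'   numerator uses the registrant-adjusted gross cost instead of the raw
#'   gross cost (default `FALSE`).
#' @param include_total Append a `year = NA` row summarising all years
#'   (survivors deduplicated over the whole span).
#' @return A tibble, one row per year.
#' @export
#' @examples
#' sim <- generate_claims(default_generator_config(scale = 1 / 1000), seed = 1)
#' cohort <- build_cohort(sim$admissions, sim$events)
#' yearly_summary(cohort, default_series_config())
yearly_summary <- function(cohort, series, ecs_uses_adjusted_gross = FALSE,
                           include_total = FALSE) {
  adm <- if (inherits(cohort, "sepsis_cohort")) cohort$included else cohort
  if (nrow(adm) == 0L)
    stop("cannot summarise an empty cohort", call. = FALSE)
  adm$cost_usd <- adjusted_usd(adm$total_cost, adm$admission_year, series)
  adm$daily_usd <- adm$cost_usd / adm$length_of_stay

  one_block <- function(a) {
    tibble::as_tibble(c(
      list(n_admissions = nrow(a)),
      list(gross_cost = sum(a$cost_usd)),
      fivenum_stats(a$cost_usd, "cost"),
      fivenum_stats(a$daily_usd, "daily_cost"),
      fivenum_stats(a$length_of_stay, "los")))
  }

  years <- sort(unique(adm$admission_year))
  per_year <- dplyr::bind_rows(lapply(years, function(y)
    one_block(adm[adm$admission_year == y, ])))
  per_year <- dplyr::bind_cols(tibble::tibble(year = years), per_year)
  per_year$adjusted_gross_cost <- unname(registrant_adjust(
    stats::setNames(per_year$gross_cost, per_year$year), series))

  surv <- survivors_per_year(adm)
  per_year <- dplyr::left_join(per_year, surv, by = "year")
  for (nm in c("n_unique_patients", "n_deaths", "n_survivors"))
    per_year[[nm]][is.na(per_year[[nm]])] <- 0L
  numerator <- if (ecs_uses_adjusted_gross) per_year$adjusted_gross_cost else
    per_year$gross_cost
  per_year$effective_cost_per_survivor <-
    effective_cost_per_survivor(numerator, per_year$n_survivors)

  if (include_total) {
    tot <- one_block(adm)
    tot$year <- NA_integer_
    tot$adjusted_gross_cost <- sum(per_year$adjusted_gross_cost)
    first <- dedup_first_admission(adm)
    tot$n_unique_patients <- nrow(first)
    tot$n_deaths <- sum(first$discharge_status == "death")
    tot$n_survivors <- tot$n_unique_patients - tot$n_deaths
    tot$effective_cost_per_survivor <- effective_cost_per_survivor(
      if (ecs_uses_adjusted_gross) tot$adjusted_gross_cost else
        tot$gross_cost,
      tot$n_survivors)
    per_year <- dplyr::bind_rows(per_year, tot)
  }
  dplyr::relocate(per_year, "year", "n_admissions", "n_unique_patients",
                  "n_deaths", "n_survivors", "gross_cost",
                  "adjusted_gross_cost")
}
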
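# Published yearly aggregates of the Japanese DPC sepsis cohort (2010-2017),
# used to calibrate the synthetic generator and as worked-example inputs.

#' Published yearly aggregates of the DPC sepsis cohort, 2010-2017
#'
#' Yearly summary statistics of the nationwide Japanese Diagnosis Procedure
#' Combination (DPC) sepsis cohort as published for 2010-2017: patient counts,
#' sex and in-hospital mortality counts, gross and registrant-adjusted gross
#' medical costs (2017-price USD), per-hospitalization and daily cost
#' statistics, and length-of-stay statistics. Mortality percentages use
#' deduplicated patient denominators (repeat admissions removed).
#'
#' These aggregates serve two purposes: they are the calibration targets of
#' [default_generator_config()], and they are usable directly as inputs to
#' [linear_trend()] for trend analyses on published series (for example the
#' yearly mean length of stay).
#'
#' @return A tibble with one row per calendar year and columns
#'   `year`, `n_admissions`, `male_n`, `deaths_n`, `mortality_pct`,
#'   `gross_cost_usd`, `adjusted_gross_cost_usd`,
#'   `cost_mean`, `cost_sd`, `cost_median`, `cost_q1`, `cost_q3`,
#'   `daily_cost_mean`, `daily_cost_sd`, `daily_cost_median`,
#'   `daily_cost_q1`, `daily_cost_q3`,
#'   `los_mean`, `los_sd`, `los_median`, `los_q1`, `los_q3`.
#' @seealso [dpc_reference_totals()] for study-level totals.
#' @export
#' @examples
#' ref <- dpc_yearly_reference()
#' sum(ref$n_admissions)
#' linear_trend(ref$los_mean, ref$year)
dpc_yearly_reference <- function() {
  tibble::tibble(
    year = 2010:2017,
    n_admissions = c(67318L, 100060L, 126414L, 141670L, 181813L, 197388L,
                     228190L, 233825L),
    male_n = c(40548L, 60018L, 76476L, 84679L, 106710L, 115588L, 132699L,
               135557L),
    deaths_n = c(15620L, 20108L, 24848L, 25405L, 30348L, 31152L, 34801L,
                 34325L),
    mortality_pct = c(24.1, 21.7, 21.5, 19.8, 18.6, 17.9, 17.3, 16.9),
    gross_cost_usd = c(1.73e9, 2.68e9, 2.83e9, 3.01e9, 3.66e9, 3.91e9,
                       4.28e9, 4.38e9),
    adjusted_gross_cost_usd = c(2.36e9, 3.22e9, 3.31e9, 3.55e9, 3.88e9,
                                3.91e9, 4.02e9, 4.38e9),
    cost_mean = c(25742, 26817, 22355, 21237, 20156, 19802, 18738, 18743),
    cost_sd = c(26248, 33192, 29723, 27746, 33135, 26045, 25032, 25442),
    cost_median = c(17432, 17033, 13690, 12759, 12092, 11917, 11355, 11410),
    cost_q1 = c(8795, 8668, 7007, 6629, 6341, 6292, 6144, 6213),
    cost_q3 = c(33018, 33126, 26699, 25157, 23702, 23219, 21881, 21835),
    daily_cost_mean = c(568, 574, 493, 495, 501, 505, 499, 504),
    daily_cost_sd = c(332, 619, 395, 364, 486, 388, 349, 354),
    daily_cost_median = c(480, 485, 386, 391, 396, 401, 400, 404),
    daily_cost_q1 = c(405, 412, 307, 312, 319, 323, 323, 326),
    daily_cost_q3 = c(617, 622, 547, 550, 554, 557, 550, 556),
    los_mean = c(50.3, 51.6, 51.0, 47.3, 44.2, 43.0, 41.2, 41.1),
    los_sd = c(70.1, 106.6, 109.8, 93.3, 86.0, 72.1, 96.0, 99.0),
    los_median = c(34, 33, 33, 30, 28, 28, 26, 26),
    los_q1 = c(17, 17, 17, 16, 15, 15, 15, 14),
    los_q3 = c(63, 63, 61, 57, 53, 52, 50, 49)
  )
}

#' Study-level totals of the DPC sepsis cohort
#'
#' Published study-level totals accompanying [dpc_yearly_reference()]:
#' admissions over all years, unique patients after repeat-admission
#' removal, deaths among unique patients, male admissions, screened adult
#' registrants, and the cohort median age.
#'
#' @return A named list with elements `n_admissions`, `n_unique_patients`,
#'   `n_deaths`, `n_male`, `n_screened_adults`, `median_age`.
#' @export
#' @examples
#' tot <- dpc_reference_totals()
#' 100 * tot$n_deaths / tot$n_unique_patients  # overall in-hospital mortality
dpc_reference_totals <- function() {
  list(
    n_admissions = 1276678L,
    n_unique_patients = 1143422L,
    n_deaths = 216607L,
    n_male = 752275L,
    n_screened_adults = 50490128L,
    median_age = 77L
  )
}

#' Default cost-adjustment series (Japan, 2010-2017)
#'
#' A [series_config()] anchored at 2017 with the Japanese national consumer
#' price index (2015 = 100), yearly DPC-registrant counts, and the
#' 115.25 JPY/USD exchange rate used to express costs in US dollars.
#' The registrant counts are calibration values reconstructed from the ratio
#' of published gross to registrant-adjusted gross costs, rescaled so that
#' the eight years sum to the published count of screened adult registrants;
#' they are synthetic in that sense and documented as such.
#'
#' @return A `series_config` object.
#' @export
#' @examples
#' s <- default_series_config()
#' to_usd(115.25, s)
default_series_config <- function() {
  series_config(
    cpi_by_year = c(`2010` = 96.5, `2011` = 96.3, `2012` = 96.2,
                    `2013` = 96.6, `2014` = 99.2, `2015` = 100.0,
                    `2016` = 99.9, `2017` = 100.4),
    registrants_by_year = c(`2010` = 5086700, `2011` = 5775385,
                            `2012` = 5932811, `2013` = 5883560,
                            `2014` = 6545629, `2015` = 6939082,
                            `2016` = 7387879, `2017` = 6939082),
    reference_year = 2017L,
    jpy_per_usd = 115.25
  )
}
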
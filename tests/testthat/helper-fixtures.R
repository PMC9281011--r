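# Builders for tiny in-code fixtures.

adm_row <- function(id = "A1", patient = id, year = 2015L, age = 70L,
                    sex = "male", los = 30L, status = "home", icu = FALSE,
                    surgery = FALSE, chronic = 0L,
                    sites = list("respiratory"), cost = 1e6) {
  tibble::tibble(
    admission_id = id, patient_id = patient, admission_year = as.integer(year),
    age = as.integer(age), sex = sex, length_of_stay = as.integer(los),
    discharge_status = status, icu_admission = icu, surgery = surgery,
    chronic_disease_count = as.integer(chronic),
    infection_site_codes = sites, total_cost = cost)
}

# Compact timeline builder: ab is a vector of days (one agent) or a
# data.frame(day, agent); cultures and dysfunction events are day vectors.
timeline <- function(id = "A1", ab = NULL, agent = "X",
                     cultures = integer(0), dys_type = character(0),
                     dys_day = integer(0)) {
  if (is.null(ab)) ab <- integer(0)
  if (!is.data.frame(ab))
    ab <- data.frame(day = ab,
                     agent = rep_len(agent, length.out = length(ab)))
  ev <- tibble::tibble(
    admission_id = id,
    day_index = as.integer(c(ab$day, cultures, dys_day)),
    event_type = c(rep("iv_antibiotic", nrow(ab)),
                   rep("blood_culture", length(cultures)),
                   dys_type),
    agent = c(as.character(ab$agent),
              rep(NA_character_, length(cultures) + length(dys_type))))
  ev[order(ev$day_index), ]
}

# Series with no-op adjustment: flat CPI, flat registrants, unit exchange.
flat_series <- function(years = 2010:2017) {
  nm <- as.character(years)
  series_config(
    cpi_by_year = stats::setNames(rep(100, length(years)), nm),
    registrants_by_year = stats::setNames(rep(1000, length(years)), nm),
    reference_year = max(years), jpy_per_usd = 1)
}

# A sepsis_cohort object wrapped around hand-built included admissions,
# for tests that target the modelling layer directly.
manual_cohort <- function(included) {
  defaults <- list(site_label = "abdominal", vasopressor = TRUE,
                   mechanical_ventilation = FALSE,
                   renal_replacement_therapy = FALSE,
                   any_dysfunction = TRUE)
  for (nm in names(defaults))
    if (is.null(included[[nm]])) included[[nm]] <- defaults[[nm]]
  structure(list(included = included, audit = included,
                 n_screened = nrow(included),
                 exclusions = c(below_age_threshold = 0L,
                                no_presumed_infection = 0L,
                                no_organ_dysfunction = 0L,
                                missing_site = 0L)),
            class = "sepsis_cohort")
}

# Generator config with all secular trends switched off (for null studies).
flat_generator_config <- function(n_per_year = 200, mortality = 0.19) {
  cfg <- default_generator_config(scale = 1)
  nm <- as.character(cfg$years)
  cfg$patients_per_year <- stats::setNames(rep(n_per_year, 8), nm)
  cfg$mortality_by_year <- stats::setNames(rep(mortality, 8), nm)
  cfg$los_meanlog_by_year <- stats::setNames(rep(log(30), 8), nm)
  cfg$los_sdlog_by_year <- stats::setNames(rep(0.9, 8), nm)
  cfg$cost_multipliers$per_year <- 1
  cfg
}
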
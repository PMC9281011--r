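# Synthetic administrative-claims generator with known ground truth.
#
# Emulates the yearly structure of the published DPC sepsis cohort (counts,
# declining mortality, declining LOS, declining real per-hospitalization
# cost) and emits event timelines that are rule-exact with respect to the
# sepsis case definition, so classifier output can be checked against ground
# truth label-for-label.

#' Default synthetic-cohort generator configuration
#'
#' Returns a [generator configuration][generate_claims] calibrated to the
#' published yearly aggregates of the DPC sepsis cohort
#' ([dpc_yearly_reference()]) and to the published multivariable cost-model
#' coefficients, which the generator uses as ground-truth multipliers:
#' age/year 0.998, male 1.047, chronic disease 1.078, ICU 1.740, surgery
#' 2.138, LOS/day 1.003, admission year 0.966, and the infection-site
#' multipliers (abdominal reference). Yearly admission targets equal the
#' published counts scaled by `scale` (default 1/100, keeping the full
#' eight-year simulation at about 12,800 admissions); per-year death
#' probabilities follow the published mortality percentages; log-normal
#' length-of-stay parameters are derived from the published yearly median
#' and mean LOS.
#'
#' Cost is multiplicative log-normal on the CPI-adjusted 2017-price USD
#' scale: `log cost = base + sum(log multipliers) + noise`; the stored
#' `total_cost` is converted back to nominal JPY so the claims tables stay
#' currency-honest.
#'
#' @param scale Multiplier applied to the published yearly admission counts.
#' @return A `generator_config` object (a validated list). Fields include
#'   `years`, `patients_per_year`, `sepsis_fraction`, `mortality_by_year`,
#'   `los_meanlog_by_year`, `los_sdlog_by_year`, `base_log_cost`,
#'   `cost_multipliers` (with `site` sub-vector), `log_cost_noise_sd`,
#'   `age_distribution`, `male_fraction`, `icu_fraction`, `surgery_fraction`,
#'   `site_mixture`, `repeat_admission_fraction`,
#'   `survivor_discharge_probs`, `negative_mode_probs`, `series`.
#' @export
#' @examples
#' cfg <- default_generator_config()
#' cfg$cost_multipliers$icu          # 1.740
#' cfg$patients_per_year[["2010"]] * 100
default_generator_config <- function(scale = 1 / 100) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  ref <- dpc_yearly_reference()
  yr <- as.character(ref$year)
  cfg <- structure(list(
    years = ref$year,
    patients_per_year = stats::setNames(ref$n_admissions * scale, yr),
    sepsis_fraction = 0.9,
    mortality_by_year = stats::setNames(ref$mortality_pct / 100, yr),
    los_meanlog_by_year = stats::setNames(log(ref$los_median), yr),
    los_sdlog_by_year = stats::setNames(
      sqrt(2 * log(ref$los_mean / ref$los_median)), yr),
    base_log_cost = 9.30,
    cost_multipliers = list(
      per_age_year = 0.998,
      male = 1.047,
      per_chronic_disease = 1.078,
      icu = 1.740,
      surgery = 2.138,
      per_los_day = 1.003,
      per_year = 0.966,
      site = c(abdominal = 1.000, blood = 2.028, bone_soft_tissue = 1.186,
               heart = 1.620, meninges_brain_spinal = 1.482,
               respiratory = 1.096, urogenital = 1.049, multiple = 1.324,
               unknown = 1.419)
    ),
    log_cost_noise_sd = 0.40,
    age_distribution = list(mean = 75, sd = 13, under20_fraction = 0.02,
                            min = 0, max = 105),
    male_fraction = 0.589,
    icu_fraction = 0.156,
    surgery_fraction = 0.30,
    chronic_disease_prob = 0.25,
    site_mixture = c(respiratory = 0.346, multiple = 0.292,
                     abdominal = 0.136, urogenital = 0.080,
                     bone_soft_tissue = 0.040, unknown = 0.050,
                     meninges_brain_spinal = 0.015, heart = 0.012,
                     blood = 0.009, missing = 0.020),
    repeat_admission_fraction = 0.145,
    survivor_discharge_probs = c(home = 0.605, nursing_facility = 0.100,
                                 transfer = 0.295),
    negative_mode_probs = c(no_events = 0.30, short_run = 0.25,
                            far_culture = 0.25, no_dysfunction = 0.20),
    antibiotic_agents = c("CTRX", "MEPM", "TAZ/PIPC", "CFPM", "VCM",
                          "ABPC/SBT", "LVFX", "CEZ"),
    series = default_series_config()
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @rdname generate_claims
#' @export
validate_generator_config <- function(config) {
  c_ <- config
  prob01 <- function(x, nm) {
    if (any(x < 0 | x > 1))
      stop("generator config: ", nm, " must lie in [0, 1]", call. = FALSE)
  }
  if (any(c_$patients_per_year <= 0))
    stop("generator config: patients_per_year must be > 0", call. = FALSE)
  prob01(c_$sepsis_fraction, "sepsis_fraction")
  prob01(c_$mortality_by_year, "mortality_by_year")
  prob01(c_$male_fraction, "male_fraction")
  prob01(c_$icu_fraction, "icu_fraction")
  prob01(c_$surgery_fraction, "surgery_fraction")
  prob01(c_$repeat_admission_fraction, "repeat_admission_fraction")
  for (nm in c("site_mixture", "survivor_discharge_probs",
               "negative_mode_probs")) {
    prob01(c_[[nm]], nm)
    if (abs(sum(c_[[nm]]) - 1) > 1e-9)
      stop("generator config: ", nm, " must sum to 1", call. = FALSE)
  }
  mult <- c(unlist(c_$cost_multipliers[setdiff(names(c_$cost_multipliers),
                                               "site")]),
            c_$cost_multipliers$site)
  if (any(mult <= 0))
    stop("generator config: all cost multipliers must be > 0", call. = FALSE)
  if (c_$log_cost_noise_sd < 0)
    stop("generator config: log_cost_noise_sd must be >= 0", call. = FALSE)
  missing_years <- setdiff(as.character(c_$years),
                           Reduce(intersect, list(names(c_$patients_per_year),
                                                  names(c_$mortality_by_year),
                                                  names(c_$los_meanlog_by_year))))
  if (length(missing_years))
    stop("generator config: year(s) ", paste(missing_years, collapse = ", "),
         " missing from a per-year series", call. = FALSE)
  invisible(config)
}

# Visit-level draws shared by first and repeat admissions. Patient-level
# attributes (age, sex, chronic count) are passed in fixed.
draw_visits <- function(cfg, year, age, male, chronic) {
  n <- length(year)
  ykey <- as.character(year)
  icu <- stats::runif(n) < cfg$icu_fraction
  surgery <- stats::runif(n) < cfg$surgery_fraction
  site_cat <- sample(names(cfg$site_mixture), n, replace = TRUE,
                     prob = cfg$site_mixture)
  is_sepsis <- stats::runif(n) < cfg$sepsis_fraction
  los <- pmax(1L, as.integer(round(stats::rlnorm(
    n, cfg$los_meanlog_by_year[ykey], cfg$los_sdlog_by_year[ykey]))))
  los[is_sepsis] <- pmax(4L, los[is_sepsis])
  death <- stats::runif(n) < cfg$mortality_by_year[ykey]
  status <- rep(NA_character_, n)
  status[death] <- "death"
  ns <- sum(!death)
  if (ns)
    status[!death] <- sample(names(cfg$survivor_discharge_probs), ns,
                             replace = TRUE,
                             prob = cfg$survivor_discharge_probs)
  m <- cfg$cost_multipliers
  site_log <- ifelse(site_cat == "missing", 0, log(m$site[site_cat]))
  log_usd <- cfg$base_log_cost +
    age * log(m$per_age_year) +
    male * log(m$male) +
    chronic * log(m$per_chronic_disease) +
    icu * log(m$icu) +
    surgery * log(m$surgery) +
    los * log(m$per_los_day) +
    (year - min(cfg$years)) * log(m$per_year) +
    site_log +
    stats::rnorm(n, 0, cfg$log_cost_noise_sd)
  s <- cfg$series
  cpi <- s$cpi_by_year
  jpy <- round(exp(log_usd) * s$jpy_per_usd *
                 cpi[ykey] / cpi[as.character(s$reference_year)])
  list(icu = icu, surgery = surgery, site_cat = site_cat,
       is_sepsis = is_sepsis, los = los, death = death, status = status,
       total_cost = unname(jpy))
}

site_codes_from_cat <- function(site_cat) {
  combos <- utils::combn(site_codes(), 2)
  out <- vector("list", length(site_cat))
  multi <- which(site_cat == "multiple")
  if (length(multi)) {
    j <- sample.int(ncol(combos), length(multi), replace = TRUE)
    out[multi] <- lapply(j, function(k) combos[, k])
  }
  out[site_cat == "missing"] <- list(character(0))
  single <- which(!site_cat %in% c("multiple", "missing"))
  out[single] <- as.list(site_cat[single])
  out
}

#' Generate a synthetic claims dataset with ground truth
#'
#' Draws admissions and daily event timelines under a generator
#' configuration (see [default_generator_config()]). True sepsis cases
#' receive a timeline that satisfies every clause of the case definition —
#' a new intravenous antibiotic started on a day `d`, a blood culture within
#' two days of `d`, antibiotic coverage on at least four consecutive days
#' from `d`, and at least one organ-dysfunction event — while non-sepsis
#' cases receive an adversarial timeline violating exactly one clause
#' (no events, a three-day antibiotic run, a culture three days from
#' initiation, or a valid infection episode without any dysfunction event).
#' A configurable fraction of first-admission survivors contributes a repeat
#' admission under the same `patient_id`, so downstream repeat-admission
#' deduplication is exercised.
#'
#' Output is deterministic for a fixed `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param config A `generator_config`.
#' @param seed Integer seed driving all randomness.
#' @param emit_events If `FALSE`, only admissions and ground truth are
#'   generated (useful for cost/trend studies that do not need timelines).
#' @return A list with `admissions`, `events` (empty tibble when
#'   `emit_events = FALSE`), and `ground_truth` (tibble with `admission_id`,
#'   `is_sepsis`, `negative_mode`, `episode_day`).
#' @export
#' @examples
#' sim <- generate_claims(default_generator_config(scale = 1 / 2000), seed = 7)
#' table(sim$ground_truth$is_sepsis)
generate_claims <- function(config, seed, emit_events = TRUE) {
  validate_generator_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  cfg <- config

  # --- first admissions, one per patient ---------------------------------
  ykey <- as.character(cfg$years)
  p <- cfg$mortality_by_year[ykey]
  r <- cfg$repeat_admission_fraction
  n_target <- round(cfg$patients_per_year[ykey])
  n_primary <- pmax(1L, as.integer(round(n_target / (1 + r * (1 - p)))))
  year <- rep(cfg$years, n_primary)
  n <- length(year)

  ad <- cfg$age_distribution
  under20 <- stats::runif(n) < ad$under20_fraction
  age <- as.integer(pmin(ad$max, pmax(20, round(stats::rnorm(n, ad$mean, ad$sd)))))
  age[under20] <- as.integer(floor(stats::runif(sum(under20), 0, 20)))
  male <- stats::runif(n) < cfg$male_fraction
  chronic <- stats::rbinom(n, 8L, cfg$chronic_disease_prob)
  patient_id <- sprintf("P%07d", seq_len(n))

  v1 <- draw_visits(cfg, year, age, male, chronic)
  idx_in_year <- stats::ave(seq_len(n), year, FUN = seq_along)
  aid1 <- sprintf("A%d-%06d-a", year, idx_in_year)

  # --- repeat admissions for a fraction of first-admission survivors -----
  rep_i <- which(!v1$death & stats::runif(n) < r)
  v2 <- draw_visits(cfg, year[rep_i], age[rep_i], male[rep_i], chronic[rep_i])
  aid2 <- sub("-a$", "-b", aid1[rep_i])

  admissions <- tibble::tibble(
    admission_id = c(aid1, aid2),
    patient_id = c(patient_id, patient_id[rep_i]),
    admission_year = c(year, year[rep_i]),
    age = c(age, age[rep_i]),
    sex = ifelse(c(male, male[rep_i]), "male", "female"),
    length_of_stay = c(v1$los, v2$los),
    discharge_status = c(v1$status, v2$status),
    icu_admission = c(v1$icu, v2$icu),
    surgery = c(v1$surgery, v2$surgery),
    chronic_disease_count = c(chronic, chronic[rep_i]),
    site_cat = c(v1$site_cat, v2$site_cat),
    is_sepsis = c(v1$is_sepsis, v2$is_sepsis),
    total_cost = c(v1$total_cost, v2$total_cost)
  )
  admissions <- admissions[order(admissions$admission_year,
                                 admissions$admission_id), ]
  admissions$infection_site_codes <- site_codes_from_cat(admissions$site_cat)

  ev_gt <- emit_timelines(admissions, cfg, emit_events)
  ground_truth <- ev_gt$ground_truth
  admissions$site_cat <- NULL
  admissions$is_sepsis <- NULL
  list(admissions = admissions, events = ev_gt$events,
       ground_truth = ground_truth)
}

dysfunction_event_types <- function() {
  c("vasopressor", "mechanical_ventilation", "oxygen_supplementation",
    "diuretic", "renal_dysfunction_code", "renal_replacement_therapy",
    "liver_dysfunction_code", "thrombocytopenia_code",
    "metabolic_acidosis_code")
}

emit_timelines <- function(adm, cfg, emit_events) {
  n <- nrow(adm)
  id <- adm$admission_id
  los <- adm$length_of_stay
  sepsis <- adm$is_sepsis

  mode <- rep(NA_character_, n)
  neg <- which(!sepsis)
  if (length(neg))
    mode[neg] <- sample(names(cfg$negative_mode_probs), length(neg),
                        replace = TRUE, prob = cfg$negative_mode_probs)
  # timelines violating a single clause need room for the run they truncate
  mode[!sepsis & mode == "short_run" & los < 3] <- "no_events"
  mode[!sepsis & mode %in% c("far_culture", "no_dysfunction") & los < 4] <-
    "no_events"

  episode_day <- rep(NA_integer_, n)
  gt <- tibble::tibble(admission_id = id, is_sepsis = sepsis,
                       negative_mode = mode, episode_day = episode_day)
  if (!emit_events) {
    gt$negative_mode[!sepsis] <- "not_emitted"
    return(list(events = tibble::tibble(admission_id = character(0),
                                        day_index = integer(0),
                                        event_type = character(0),
                                        agent = character(0)),
                ground_truth = gt))
  }

  dys_types <- dysfunction_event_types()
  dys_w <- c(2, 2, 3, 2, 1, 1, 1, 1, 1)  # commoner supports drawn more often
  pieces <- list()
  add <- function(adm_id, day, type, agent = NA_character_) {
    if (length(adm_id))
      pieces[[length(pieces) + 1L]] <<- tibble::tibble(
        admission_id = adm_id, day_index = as.integer(day),
        event_type = type, agent = agent)
  }
  ab_run <- function(i, d, run) {
    agent <- sample(cfg$antibiotic_agents, length(i), replace = TRUE)
    add(rep(id[i], run), rep(d, run) + (sequence(run) - 1L),
        "iv_antibiotic", rep(agent, run))
  }
  dys_events <- function(i, n_each) {
    tot <- sum(n_each)
    if (!tot) return(invisible())
    li <- rep(los[i], n_each)
    add(rep(id[i], n_each), 1L + floor(stats::runif(tot) * li),
        sample(dys_types, tot, replace = TRUE, prob = dys_w))
  }

  # positive timelines: all three clauses hold, plus >=1 dysfunction event
  pos <- which(sepsis)
  if (length(pos)) {
    d <- 1L + as.integer(floor(stats::runif(length(pos)) * (los[pos] - 3L)))
    delta <- sample(-2:2, length(pos), replace = TRUE)
    cday <- pmax(1L, d + delta)
    extra <- sample(0:3, length(pos), replace = TRUE,
                    prob = c(0.4, 0.3, 0.2, 0.1))
    run <- pmin(4L + extra, los[pos] - d + 1L)
    ab_run(pos, d, run)
    add(id[pos], cday, "blood_culture")
    dys_events(pos, 1L + stats::rbinom(length(pos), 2L, 0.3))
    episode_day[pos] <- d
  }

  sr <- which(!sepsis & mode == "short_run")
  if (length(sr)) {
    d <- 1L + as.integer(floor(stats::runif(length(sr)) * (los[sr] - 2L)))
    cday <- pmax(1L, d + sample(-2:2, length(sr), replace = TRUE))
    ab_run(sr, d, rep(3L, length(sr)))
    add(id[sr], cday, "blood_culture")
    dys_events(sr, rep(1L, length(sr)))
  }
  fc <- which(!sepsis & mode == "far_culture")
  if (length(fc)) {
    d <- 1L + as.integer(floor(stats::runif(length(fc)) * (los[fc] - 3L)))
    ab_run(fc, d, rep(4L, length(fc)))
    add(id[fc], d + 3L, "blood_culture")
    dys_events(fc, rep(1L, length(fc)))
  }
  nd <- which(!sepsis & mode == "no_dysfunction")
  if (length(nd)) {
    d <- 1L + as.integer(floor(stats::runif(length(nd)) * (los[nd] - 3L)))
    cday <- pmax(1L, d + sample(-2:2, length(nd), replace = TRUE))
    ab_run(nd, d, rep(4L, length(nd)))
    add(id[nd], cday, "blood_culture")
  }

  events <- dplyr::bind_rows(pieces)
  events <- events[order(match(events$admission_id, id), events$day_index), ]
  gt$episode_day <- episode_day
  list(events = events, ground_truth = gt)
}

#' Minimally break one clause of a sepsis-positive timeline
#'
#' Takes the events of a single sepsis-positive admission and returns a
#' minimally edited timeline that fails exactly the targeted clause of the
#' case definition: `"shorten_run"` truncates the antibiotic run to three
#' days, `"shift_culture"` moves every blood culture to three days from the
#' initiation day, and `"drop_dysfunction"` removes all organ-dysfunction
#' events. Used to build per-clause discriminating fixtures.
#'
#' @param events Events tibble of one admission.
#' @param mode One of `"shorten_run"`, `"shift_culture"`,
#'   `"drop_dysfunction"`.
#' @param length_of_stay Stay length bounding event days; defaults to the
#'   latest observed event day.
#' @return The edited events tibble.
#' @export
perturb_to_negative <- function(events,
                                mode = c("shorten_run", "shift_culture",
                                         "drop_dysfunction"),
                                length_of_stay = max(events$day_index)) {
  mode <- match.arg(mode)
  if (length(unique(events$admission_id)) != 1L)
    stop("events must belong to a single admission", call. = FALSE)
  events <- events[order(events$day_index), ]
  ep <- detect_infection_episode(events)
  dys <- events$event_type %in% dysfunction_event_types()
  if (is.null(ep) || !any(dys))
    stop("timeline is not sepsis-positive; nothing to perturb", call. = FALSE)
  d <- ep$initiation_day
  if (mode == "shorten_run") {
    keep <- events$event_type != "iv_antibiotic" |
      (events$day_index >= d & events$day_index <= d + 2L)
    return(events[keep, ])
  }
  if (mode == "shift_culture") {
    target <- if (d + 3L <= length_of_stay) d + 3L else d - 3L
    if (target < 1L)
      stop("stay too short to move the culture out of the ±2-day window",
           call. = FALSE)
    events$day_index[events$event_type == "blood_culture"] <- target
    return(events[order(events$day_index), ])
  }
  events[!dys, ]
}
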
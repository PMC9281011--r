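# Sepsis case definition on claims timelines: presumed serious infection
# (temporal antibiotic/culture rule) AND organ dysfunction, plus
# infection-site assignment and cohort-level inclusion/exclusion.

# event type -> organ-dysfunction flag
dysfunction_flag_map <- function() {
  c(vasopressor = "vasopressor",
    mechanical_ventilation = "respiratory_support",
    oxygen_supplementation = "respiratory_support",
    diuretic = "kidney_injury",
    renal_dysfunction_code = "kidney_injury",
    renal_replacement_therapy = "kidney_injury",
    liver_dysfunction_code = "liver_injury",
    thrombocytopenia_code = "thrombocytopenia",
    metabolic_acidosis_code = "metabolic_acidosis")
}

dysfunction_flag_names <- function() {
  c("vasopressor", "respiratory_support", "kidney_injury", "liver_injury",
    "thrombocytopenia", "metabolic_acidosis")
}

#' Detect a presumed-serious-infection episode in one admission's timeline
#'
#' Scans the events of a single admission for the earliest day `d` such
#' that:
#' * (a) some intravenous antibiotic agent is administered on `d` and that
#'   same agent was not administered on any of the `lookback_days` preceding
#'   days ("new" antibiotic therapy);
#' * (b) a blood culture occurs on some day `c` with
#'   `|c - d| <= window_days`;
#' * (c) intravenous antibiotics (any agent; switches allowed) are
#'   administered on every day of `d .. d + min_run_days - 1`.
#'
#' With `allow_censored_run = TRUE` and a supplied `length_of_stay`, clause
#' (c) is waived for days beyond discharge provided every in-stay day from
#' `d` onward is covered (for stays ending before the run can complete).
#'
#' @param events Events tibble of one admission, sorted by `day_index`.
#' @param lookback_days Days an agent must have been absent to count as new
#'   (default 2).
#' @param window_days Half-width of the culture window in days (default 2).
#' @param min_run_days Minimum consecutive covered days (default 4).
#' @param allow_censored_run Waive the run requirement at discharge/death.
#' @param length_of_stay Stay length; required when
#'   `allow_censored_run = TRUE`.
#' @return `NULL` if no day qualifies, else a list with `initiation_day`,
#'   `culture_day` (the qualifying culture closest to initiation, earlier
#'   day on ties), and `run_length` (consecutive covered days from
#'   initiation).
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   admission_id = "A1",
#'   day_index = c(3L, 4L, 5L, 6L, 7L),
#'   event_type = c("blood_culture", rep("iv_antibiotic", 4)),
#'   agent = c(NA, rep("CTRX", 4)))
#' detect_infection_episode(ev)
detect_infection_episode <- function(events, lookback_days = 2L,
                                     window_days = 2L, min_run_days = 4L,
                                     allow_censored_run = FALSE,
                                     length_of_stay = NULL) {
  if (nrow(events) == 0L) return(NULL)
  if (length(unique(events$admission_id)) > 1L)
    stop("detect_infection_episode() expects events of a single admission",
         call. = FALSE)
  if (is.unsorted(events$day_index))
    stop("events must be sorted by day_index", call. = FALSE)
  los <- if (is.null(length_of_stay)) NULL else
    stats::setNames(rep(length_of_stay, length(unique(events$admission_id))),
                    unique(events$admission_id))
  res <- episode_scan(events, lookback_days, window_days, min_run_days,
                      allow_censored_run, los = los)
  if (is.na(res$initiation_day[1])) NULL else
    list(initiation_day = res$initiation_day[1],
         culture_day = res$culture_day[1],
         run_length = res$run_length[1])
}

# Vectorized episode scan over one or many admissions. `events` may mix
# admissions; `los` is a named vector (admission_id -> length_of_stay) used
# only when censoring is allowed. Returns one row per admission id in `ids`.
episode_scan <- function(events, lookback_days = 2L, window_days = 2L,
                         min_run_days = 4L, allow_censored_run = FALSE,
                         los = NULL, ids = unique(events$admission_id)) {
  out <- tibble::tibble(admission_id = ids,
                        initiation_day = NA_integer_,
                        culture_day = NA_integer_,
                        run_length = NA_integer_)
  ab <- events[events$event_type == "iv_antibiotic", ]
  if (nrow(ab) == 0L) return(out)
  if (allow_censored_run && is.null(los))
    stop("allow_censored_run requires lengths of stay", call. = FALSE)

  agent_key <- paste(ab$admission_id, ab$agent, ab$day_index)
  is_new <- rep(TRUE, nrow(ab))
  for (k in seq_len(lookback_days)) {
    is_new <- is_new &
      !(paste(ab$admission_id, ab$agent, ab$day_index - k) %in% agent_key)
  }
  cand <- ab[is_new, c("admission_id", "day_index")]
  cand <- cand[!duplicated(paste(cand$admission_id, cand$day_index)), ]
  if (nrow(cand) == 0L) return(out)

  cover_key <- unique(paste(ab$admission_id, ab$day_index))
  cult <- events[events$event_type == "blood_culture", ]
  cult_key <- paste(cult$admission_id, cult$day_index)

  d <- cand$day_index
  aid <- cand$admission_id
  cens_los <- if (allow_censored_run) unname(los[aid]) else NULL

  run_ok <- rep(TRUE, nrow(cand))
  for (k in seq_len(min_run_days - 1L)) {
    covered <- paste(aid, d + k) %in% cover_key
    if (allow_censored_run) covered <- covered | (d + k > cens_los)
    run_ok <- run_ok & covered
  }
  cult_ok <- rep(FALSE, nrow(cand))
  for (delta in -window_days:window_days) {
    cult_ok <- cult_ok | (paste(aid, d + delta) %in% cult_key)
  }
  ok <- run_ok & cult_ok
  if (!any(ok)) return(out)

  hit <- tibble::tibble(admission_id = aid[ok], d = d[ok])
  hit <- hit[order(hit$admission_id, hit$d), ]
  hit <- hit[!duplicated(hit$admission_id), ]  # earliest qualifying day

  # culture closest to initiation, earlier day breaking ties
  cday <- rep(NA_integer_, nrow(hit))
  deltas <- seq(-window_days, window_days)
  for (delta in deltas[order(abs(deltas), deltas)]) {
    found <- is.na(cday) & paste(hit$admission_id, hit$d + delta) %in% cult_key
    cday[found] <- hit$d[found] + delta
  }
  # consecutive covered days from initiation
  run <- rep(1L, nrow(hit))
  alive <- rep(TRUE, nrow(hit))
  k <- 1L
  max_day <- max(ab$day_index)
  while (any(alive) && k <= max_day) {
    alive <- alive & (paste(hit$admission_id, hit$d + k) %in% cover_key)
    run <- run + alive
    k <- k + 1L
  }
  i <- match(hit$admission_id, out$admission_id)
  out$initiation_day[i] <- hit$d
  out$culture_day[i] <- cday
  out$run_length[i] <- run
  out
}

#' Organ-dysfunction flags for one admission
#'
#' Six booleans derived from events anywhere in the stay: vasopressor use;
#' respiratory support (mechanical ventilation or oxygen supplementation);
#' kidney injury (diuretic use, renal-dysfunction codes, or renal
#' replacement therapy); liver injury; thrombocytopenia; metabolic
#' acidosis. `any_dysfunction` is their OR.
#'
#' @param events Events tibble of one admission.
#' @return Named list of the six flags plus `any_dysfunction`.
#' @export
organ_dysfunction_flags <- function(events) {
  map <- dysfunction_flag_map()
  hit <- unique(unname(map[intersect(unique(events$event_type), names(map))]))
  flags <- stats::setNames(dysfunction_flag_names() %in% hit,
                           dysfunction_flag_names())
  c(as.list(flags), list(any_dysfunction = any(flags)))
}

#' Collapse a set of infection-site codes to a single site label
#'
#' Zero recorded codes give `"missing"`; the explicit code `"unknown"` alone
#' gives `"unknown"`; exactly one site code gives that site; two or more
#' distinct codes collapse to `"multiple"`.
#'
#' @param codes Character vector of site codes (possibly empty); tokens must
#'   be site codes or `"unknown"`.
#' @return One of [site_labels()].
#' @export
#' @examples
#' assign_site(c("respiratory", "urogenital"))  # "multiple"
#' assign_site(character(0))                    # "missing"
assign_site <- function(codes) {
  codes <- unique(codes)
  bad <- setdiff(codes, c(site_codes(), "unknown"))
  if (length(bad))
    stop("unrecognized infection-site code: ", bad[1], call. = FALSE)
  if (length(codes) == 0L) return("missing")
  if (length(codes) >= 2L) return("multiple")
  codes
}

#' Classify one admission against the sepsis case definition
#'
#' An admission is sepsis iff a presumed-serious-infection episode is found
#' ([detect_infection_episode()]) AND at least one organ-dysfunction flag is
#' set ([organ_dysfunction_flags()]). The episode, flags, and site label are
#' returned regardless of the verdict, for audit.
#'
#' @param admission One-row admissions tibble.
#' @param events Events of that admission.
#' @inheritParams detect_infection_episode
#' @return List with `is_sepsis`, `episode` (or `NULL`), `flags`, `site`.
#' @export
classify_admission <- function(admission, events, lookback_days = 2L,
                               allow_censored_run = FALSE) {
  stopifnot(nrow(admission) == 1L)
  events <- events[events$admission_id == admission$admission_id, ]
  events <- events[order(events$day_index), ]
  ep <- detect_infection_episode(
    events, lookback_days = lookback_days,
    allow_censored_run = allow_censored_run,
    length_of_stay = admission$length_of_stay)
  flags <- organ_dysfunction_flags(events)
  list(is_sepsis = !is.null(ep) && flags$any_dysfunction,
       episode = ep, flags = flags,
       site = assign_site(admission$infection_site_codes[[1]]))
}

#' Build the sepsis cohort from screened admissions
#'
#' Screens every admission and applies, in order: the age filter
#' (`age >= age_threshold`; the published cohort includes patients aged 20
#' and over), the two-part sepsis classification (infection episode, then
#' organ dysfunction), and the missing-site exclusion. The exclusion tally
#' partitions the screened set: `included + below_age_threshold +
#' no_presumed_infection + no_organ_dysfunction + missing_site = screened`.
#'
#' @param admissions,events Validated claims tables.
#' @param age_threshold Minimum age for inclusion (default 20).
#' @inheritParams detect_infection_episode
#' @return A `sepsis_cohort`: list with `included` (admissions joined with
#'   episode fields, dysfunction flags — including the specific
#'   `mechanical_ventilation`, `vasopressor` and
#'   `renal_replacement_therapy` indicators used in subgroup analyses — and
#'   `site_label`), `audit` (the same columns for every screened admission
#'   with an `exclusion` column), `n_screened`, and `exclusions` (named
#'   counts).
#' @export
#' @examples
#' sim <- generate_claims(default_generator_config(scale = 1 / 1000), seed = 1)
#' cohort <- build_cohort(sim$admissions, sim$events)
#' cohort$exclusions
build_cohort <- function(admissions, events, age_threshold = 20L,
                         lookback_days = 2L, allow_censored_run = FALSE) {
  adm <- admissions
  los <- stats::setNames(adm$length_of_stay, adm$admission_id)
  ep <- episode_scan(events, lookback_days = lookback_days,
                     allow_censored_run = allow_censored_run,
                     los = los, ids = adm$admission_id)

  # dysfunction flags, vectorized over admissions
  map <- dysfunction_flag_map()
  dys <- events[events$event_type %in% names(map), ]
  flag_of <- unname(map[dys$event_type])
  flag_tab <- table(factor(dys$admission_id, levels = adm$admission_id),
                    factor(flag_of, levels = dysfunction_flag_names()))
  flags <- tibble::as_tibble(as.matrix(flag_tab) > 0)
  names(flags) <- colnames(flag_tab)
  has_type <- function(type) {
    adm$admission_id %in% dys$admission_id[dys$event_type == type]
  }

  audit <- dplyr::bind_cols(adm, ep[match(adm$admission_id, ep$admission_id),
                                    c("initiation_day", "culture_day",
                                      "run_length")],
                            flags)
  audit$any_dysfunction <- Reduce(`|`, flags)
  audit$mechanical_ventilation <- has_type("mechanical_ventilation")
  audit$renal_replacement_therapy <- has_type("renal_replacement_therapy")
  audit$site_label <- vapply(adm$infection_site_codes, assign_site,
                             character(1))
  audit$is_sepsis <- !is.na(audit$initiation_day) & audit$any_dysfunction

  excl <- rep(NA_character_, nrow(audit))
  excl[is.na(excl) & audit$age < age_threshold] <- "below_age_threshold"
  excl[is.na(excl) & is.na(audit$initiation_day)] <- "no_presumed_infection"
  excl[is.na(excl) & !audit$any_dysfunction] <- "no_organ_dysfunction"
  excl[is.na(excl) & audit$site_label == "missing"] <- "missing_site"
  audit$exclusion <- excl

  tally <- stats::setNames(
    vapply(c("below_age_threshold", "no_presumed_infection",
             "no_organ_dysfunction", "missing_site"),
           function(r) sum(excl == r, na.rm = TRUE), integer(1)),
    c("below_age_threshold", "no_presumed_infection",
      "no_organ_dysfunction", "missing_site"))

  structure(
    list(included = audit[is.na(excl), ],
         audit = audit,
         n_screened = nrow(audit),
         exclusions = tally),
    class = "sepsis_cohort"
  )
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  cat("Sepsis cohort:", nrow(x$included), "included of", x$n_screened,
      "screened admissions\n")
  cat("Exclusions:\n")
  for (nm in names(x$exclusions))
    cat(sprintf("  %-22s %d\n", nm, x$exclusions[[nm]]))
  invisible(x)
}
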
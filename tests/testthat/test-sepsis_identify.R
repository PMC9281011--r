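test_that("the infection rule's three clauses are enforced as traced", {
  # all clauses hold: culture day 3, agent first given day 4, covered 4..7
  ep <- detect_infection_episode(timeline(ab = 4:7, cultures = 3))
  expect_equal(ep, list(initiation_day = 4L, culture_day = 3L,
                        run_length = 4L))
  # run of three days is too short
  expect_null(detect_infection_episode(timeline(ab = 4:6, cultures = 3)))
  # culture more than two days from initiation
  expect_null(detect_infection_episode(timeline(ab = 4:7, cultures = 1)))
  # no events at all
  expect_null(detect_infection_episode(timeline()))
})

test_that("only a newly initiated agent can anchor an episode", {
  # X already given within the 2-day lookback of day 4: not new
  old_x <- timeline(ab = c(2, 4, 5, 6, 7), cultures = 5)
  expect_null(detect_infection_episode(old_x))
  # a different agent starting on day 4 is new
  switch_agent <- timeline(
    ab = data.frame(day = c(2, 4, 5, 6, 7), agent = c("X", "Y", "Y", "Y", "Y")),
    cultures = 5)
  ep <- detect_infection_episode(switch_agent)
  expect_equal(ep$initiation_day, 4L)
  # X given 3+ days before day 6 counts as new again (2-day lookback)
  gap <- timeline(ab = c(1, 6, 7, 8, 9), cultures = 6)
  expect_equal(detect_infection_episode(gap)$initiation_day, 6L)
})

test_that("run coverage may switch agents and the earliest day wins", {
  mixed <- timeline(ab = data.frame(day = 4:7, agent = c("X", "Y", "X", "Z")),
                    cultures = 4)
  expect_equal(detect_infection_episode(mixed)$run_length, 4L)
  two_starts <- timeline(ab = 3:10, cultures = c(4, 9))
  expect_equal(detect_infection_episode(two_starts)$initiation_day, 3L)
  expect_equal(detect_infection_episode(two_starts)$run_length, 8L)
})

test_that("the censored-run waiver only applies at discharge", {
  ev <- timeline(ab = 4:5, cultures = 4)
  expect_null(detect_infection_episode(ev))
  ep <- detect_infection_episode(ev, allow_censored_run = TRUE,
                                 length_of_stay = 5)
  expect_equal(ep$initiation_day, 4L)
  # a gap inside the stay is never waived
  ev2 <- timeline(ab = c(2, 4, 5), cultures = 2)
  expect_null(detect_infection_episode(ev2, allow_censored_run = TRUE,
                                       length_of_stay = 5))
})

test_that("organ-dysfunction flags map event types to organ systems", {
  expect_true(organ_dysfunction_flags(
    timeline(dys_type = "vasopressor", dys_day = 2))$vasopressor)
  kidney <- organ_dysfunction_flags(
    timeline(dys_type = "diuretic", dys_day = 2))
  expect_true(kidney$kidney_injury)
  expect_true(kidney$any_dysfunction)
  resp <- organ_dysfunction_flags(
    timeline(dys_type = "oxygen_supplementation", dys_day = 1))
  expect_true(resp$respiratory_support)
  none <- organ_dysfunction_flags(timeline())
  expect_false(none$any_dysfunction)
  expect_false(any(unlist(none[setdiff(names(none), "any_dysfunction")])))
  # every dysfunction event type raises exactly one of the six flags
  for (tp in setdiff(event_types(), c("iv_antibiotic", "blood_culture"))) {
    fl <- organ_dysfunction_flags(timeline(dys_type = tp, dys_day = 1))
    expect_equal(sum(unlist(fl[setdiff(names(fl), "any_dysfunction")])), 1,
                 info = tp)
  }
})

test_that("site codes collapse to a single label", {
  expect_equal(assign_site("respiratory"), "respiratory")
  expect_equal(assign_site(c("respiratory", "urogenital")), "multiple")
  expect_equal(assign_site(character(0)), "missing")
  expect_equal(assign_site("unknown"), "unknown")
  expect_equal(assign_site(c("respiratory", "unknown")), "multiple")
  expect_error(assign_site("lung"), "unrecognized infection-site code")
})

test_that("sepsis requires both an episode and organ dysfunction", {
  adm <- adm_row()
  pos <- timeline(ab = 4:7, cultures = 3, dys_type = "vasopressor",
                  dys_day = 5)
  expect_true(classify_admission(adm, pos)$is_sepsis)
  no_dys <- timeline(ab = 4:7, cultures = 3)
  expect_false(classify_admission(adm, no_dys)$is_sepsis)
  dys_only <- timeline(dys_type = "vasopressor", dys_day = 5)
  cls <- classify_admission(adm, dys_only)
  expect_false(cls$is_sepsis)
  expect_true(cls$flags$any_dysfunction)
})

test_that("cohort screening applies the exclusion cascade in order", {
  adm <- dplyr::bind_rows(
    adm_row("A1", age = 19),                       # under age, despite events
    adm_row("A2"),                                 # full sepsis, kept
    adm_row("A3"),                                 # no infection episode
    adm_row("A4"),                                 # episode, no dysfunction
    adm_row("A5", sites = list(character(0))))     # sepsis but missing site
  ev <- dplyr::bind_rows(
    timeline("A1", ab = 4:7, cultures = 3, dys_type = "vasopressor",
             dys_day = 2),
    timeline("A2", ab = 4:7, cultures = 3, dys_type = "vasopressor",
             dys_day = 2),
    timeline("A3", ab = 4:6, cultures = 3, dys_type = "diuretic",
             dys_day = 2),
    timeline("A4", ab = 4:7, cultures = 3),
    timeline("A5", ab = 4:7, cultures = 3, dys_type = "vasopressor",
             dys_day = 2))
  cohort <- build_cohort(adm, ev)
  expect_equal(cohort$exclusions,
               c(below_age_threshold = 1L, no_presumed_infection = 1L,
                 no_organ_dysfunction = 1L, missing_site = 1L))
  expect_equal(cohort$included$admission_id, "A2")
  expect_equal(nrow(cohort$included) + sum(cohort$exclusions),
               cohort$n_screened)
  # age >= 20 is included: the published cohort starts at age 20
  cohort20 <- build_cohort(adm_row("B1", age = 20),
                           timeline("B1", ab = 1:4, cultures = 1,
                                    dys_type = "vasopressor", dys_day = 1))
  expect_equal(cohort20$exclusions[["below_age_threshold"]], 0L)
})

test_that("helpful monotonicity holds: cultures and duplicates never hurt", {
  withr::local_seed(505)
  for (i in 1:60) {
    ev <- random_timeline()
    ep <- detect_infection_episode(ev)
    if (!is.null(ep)) {
      # adding a blood culture can only help
      plus_cult <- timeline(ab = ev[ev$event_type == "iv_antibiotic",
                                    c("day_index", "agent")] |>
                              (\(d) data.frame(day = d$day_index,
                                               agent = d$agent))(),
                            cultures = c(ev$day_index[ev$event_type ==
                                                        "blood_culture"],
                                         sample(30, 1)))
      expect_false(is.null(detect_infection_episode(plus_cult)))
      # duplicating an existing antibiotic row changes nothing
      ab_rows <- which(ev$event_type == "iv_antibiotic")
      dup <- ev[c(seq_len(nrow(ev)), sample(ab_rows, 1)), ]
      dup <- dup[order(dup$day_index), ]
      expect_equal(detect_infection_episode(dup), ep)
    }
    # removing dysfunction events can only remove a sepsis label
    adm <- adm_row(los = 30L)
    no_dys <- ev[!ev$event_type %in% setdiff(event_types(),
                                             c("iv_antibiotic",
                                               "blood_culture")), ]
    if (!classify_admission(adm, ev)$is_sepsis)
      expect_false(classify_admission(adm, no_dys)$is_sepsis)
  }
})

test_that("bulk cohort classification matches per-admission classification", {
  withr::local_seed(77)
  n <- 120
  evs <- lapply(seq_len(n), function(i) {
    ev <- random_timeline()
    ev$admission_id <- sprintf("A%03d", i)
    ev
  })
  adm <- adm_row(sprintf("A%03d", seq_len(n)), los = 30L)
  cohort <- build_cohort(adm, dplyr::bind_rows(evs))
  for (i in seq_len(n)) {
    single <- classify_admission(adm[i, ], evs[[i]])
    expect_equal(cohort$audit$is_sepsis[i], single$is_sepsis, info = i)
    expect_equal(cohort$audit$initiation_day[i],
                 if (is.null(single$episode)) NA_integer_ else
                   single$episode$initiation_day, info = i)
  }
})
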
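# Brute-force oracle for the presumed-serious-infection rule: enumerates
# every candidate initiation day and checks the three clauses literally,
# independently of the package's scan implementation.

oracle_initiation_day <- function(events, lookback = 2, window = 2,
                                  min_run = 4) {
  ab <- events[events$event_type == "iv_antibiotic", ]
  cultures <- events$day_index[events$event_type == "blood_culture"]
  if (nrow(ab) == 0) return(NULL)
  for (d in seq_len(max(events$day_index))) {
    # (a) some agent given on d and absent on the lookback days
    new_start <- FALSE
    for (a in unique(ab$agent[ab$day_index == d])) {
      prior <- ab$agent[ab$day_index >= d - lookback & ab$day_index <= d - 1]
      if (!(a %in% prior)) new_start <- TRUE
    }
    if (!new_start) next
    # (b) a culture within the window
    culture_ok <- FALSE
    for (cd in cultures) if (abs(cd - d) <= window) culture_ok <- TRUE
    if (!culture_ok) next
    # (c) any-agent coverage on min_run consecutive days from d
    run_ok <- TRUE
    for (k in 0:(min_run - 1)) {
      if (!any(ab$day_index == d + k)) run_ok <- FALSE
    }
    if (run_ok) return(d)
  }
  NULL
}

# Random timelines of bounded length; roughly half get a plausible
# antibiotic run so positives and negatives are both well represented.
random_timeline <- function(max_day = 30) {
  agents <- c("A", "B", "C")
  n_ab <- stats::rpois(1, 3)
  days <- if (n_ab) sample(max_day, n_ab, replace = TRUE) else integer(0)
  ag <- if (n_ab) sample(agents, n_ab, replace = TRUE) else character(0)
  cultures <- integer(0)
  if (stats::runif(1) < 0.6) {
    start <- sample(max_day - 6, 1)
    len <- sample(3:6, 1)   # straddles the 4-day run threshold
    days <- c(days, start:(start + len - 1))
    ag <- c(ag, rep(sample(agents, 1), len))
    if (stats::runif(1) < 0.7)  # culture near the start, straddling +-2
      cultures <- max(1, min(max_day, start + sample(-4:4, 1)))
  }
  n_cult <- stats::rpois(1, 0.8)
  if (n_cult) cultures <- c(cultures, sample(max_day, n_cult, replace = TRUE))
  n_dys <- stats::rpois(1, 0.8)
  dys <- if (n_dys) sample(setdiff(event_types(),
                                   c("iv_antibiotic", "blood_culture")),
                           n_dys, replace = TRUE) else character(0)
  timeline(ab = data.frame(day = days, agent = ag), cultures = cultures,
           dys_type = dys,
           dys_day = if (n_dys) sample(max_day, n_dys, replace = TRUE)
                     else integer(0))
}
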
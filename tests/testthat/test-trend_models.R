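test_that("linear_trend handles exact, constant, and degenerate inputs", {
  exact <- linear_trend(c(0, 1, 2, 3), 2010:2013)
  expect_equal(exact$slope, 1)
  expect_true(exact$degenerate)
  expect_true(is.na(exact$p_value))

  const <- linear_trend(rep(7, 5), 2010:2014)
  expect_equal(const$slope, 0)
  expect_true(const$degenerate)

  noisy <- linear_trend(c(1, 3, 2, 5, 4), 2010:2014)
  expect_false(noisy$degenerate)
  expect_true(noisy$ci_low <= noisy$slope && noisy$slope <= noisy$ci_high)
  expect_true(noisy$p_value >= 0 && noisy$p_value <= 1)

  expect_error(linear_trend(c(1, 2), 2010:2011), "at least 3 yearly points")
  expect_error(linear_trend(c(1, 2, 3), c(2012, 2011, 2013)),
               "strictly increasing")
})

test_that("trend estimates are equivariant under year shifts and scaling", {
  withr::local_seed(404)
  for (i in 1:20) {
    y <- rnorm(8)
    yrs <- 2010:2017
    base <- linear_trend(y, yrs)
    shifted <- linear_trend(y, yrs + 57)
    expect_equal(shifted$slope, base$slope)
    expect_equal(shifted$p_value, base$p_value)
    k <- runif(1, 0.1, 50)
    scaled <- linear_trend(k * y, yrs)
    expect_equal(scaled$slope, k * base$slope)
    expect_equal(scaled$ci_low, k * base$ci_low)
    expect_equal(scaled$ci_high, k * base$ci_high)
  }
})

test_that("the primary trend rejects years with undefined cost-effectiveness", {
  summaries <- tibble::tibble(year = 2010:2013,
                              effective_cost_per_survivor = c(1, NA, 3, NA))
  expect_error(effective_cost_trend(summaries), "2011, 2013")
})

test_that("age bands split at 65 and 75 with age 20 included", {
  g <- sepsiscost:::grouping_values(adm_row("A", age = c(20, 64, 65, 74, 75, 99)),
                                    "age_band")
  expect_equal(as.character(g),
               c("adults", "adults", "early_elderly", "early_elderly",
                 "late_elderly", "late_elderly"))
})

test_that("a sex-symmetric cohort gives identical trends per sex", {
  years <- rep(2010:2017, each = 6)
  male <- adm_row(sprintf("M%03d", seq_along(years)),
                  patient = sprintf("PM%03d", seq_along(years)),
                  year = years, sex = "male",
                  cost = 1000 - 10 * (years - 2010),
                  status = rep(c("home", "home", "death"), length.out =
                                 length(years)))
  female <- male
  female$admission_id <- sub("^M", "F", male$admission_id)
  female$patient_id <- sub("^PM", "PF", male$patient_id)
  female$sex <- "female"
  cohort <- manual_cohort(dplyr::bind_rows(male, female))
  tr <- subgroup_trends(cohort, flat_series(), "sex")
  expect_equal(tr$slope[1], tr$slope[2])
  expect_equal(tr$p_value[1], tr$p_value[2])
})

test_that("subgroup trends cover every level of the grouping", {
  sim <- generate_claims(default_generator_config(scale = 1 / 250), seed = 31)
  cohort <- build_cohort(sim$admissions, sim$events)
  s <- default_series_config()
  tr_age <- subgroup_trends(cohort, s, "age_band")
  expect_setequal(tr_age$level, c("adults", "early_elderly", "late_elderly"))
  expect_true(all(tr_age$slope < 0, na.rm = TRUE))
  tr_mv <- subgroup_trends(cohort, s, "mechanical_ventilation")
  expect_setequal(tr_mv$level, c("yes", "no"))
  expect_error(subgroup_trends(cohort, s, "eye_colour"), "unknown grouping")
})

test_that("adjusted subgroup means equal geometric means without confounding", {
  withr::local_seed(88)
  n <- 400
  adm <- adm_row(sprintf("A%04d", 1:n), patient = sprintf("P%04d", 1:n),
                 year = 2015L, age = sample(30:90, n, TRUE),
                 sex = sample(sexes(), n, TRUE),
                 icu = sample(c(TRUE, FALSE), n, TRUE),
                 cost = NA_real_)
  # zero noise, cost driven by ICU only: covariates are independent
  adm$total_cost <- exp(10 + log(1.74) * adm$icu_admission)
  cohort <- manual_cohort(adm)
  out <- adjusted_subgroup_costs(cohort, flat_series(), "icu",
                                 covariates = "age")
  geo <- tapply(log(adm$total_cost), ifelse(adm$icu_admission, "yes", "no"),
                mean)
  expect_equal(out$adjusted_mean[out$level == "yes"],
               unname(exp(geo["yes"])), tolerance = 1e-8)
  expect_equal(out$adjusted_mean[out$level == "no"],
               unname(exp(geo["no"])), tolerance = 1e-8)
})

test_that("adjustment removes age confounding of the ICU cost effect", {
  withr::local_seed(99)
  n <- 4000
  age <- sample(30:95, n, TRUE)
  icu <- runif(n) < ifelse(age > 70, 0.45, 0.05)   # older patients go to ICU
  cost <- exp(10 + log(1.74) * icu + log(0.99) * age + rnorm(n, 0, 0.1))
  adm <- adm_row(sprintf("A%04d", 1:n), patient = sprintf("P%04d", 1:n),
                 year = 2015L, age = age, icu = icu, cost = cost)
  cohort <- manual_cohort(adm)
  out <- adjusted_subgroup_costs(cohort, flat_series(), "icu",
                                 covariates = "age")
  adj_ratio <- out$adjusted_mean[out$level == "yes"] /
    out$adjusted_mean[out$level == "no"]
  raw_ratio <- exp(mean(log(cost[icu])) - mean(log(cost[!icu])))
  expect_lt(abs(adj_ratio - 1.74), 0.05)
  expect_gt(abs(raw_ratio - 1.74), 0.15)  # the naive contrast is biased
  expect_error(adjusted_subgroup_costs(
    manual_cohort(adm[adm$icu_admission, ]), flat_series(), "icu",
    covariates = "age"), "fewer than 2 observed levels")
})

test_that("univariable screening retains the true cost drivers", {
  sim <- generate_claims(default_generator_config(scale = 1 / 250), seed = 14)
  cohort <- build_cohort(sim$admissions, sim$events)
  sc <- screen_variables(cohort, default_series_config())
  expect_true(all(sc$retained[sc$variable %in%
                                c("icu_admission", "surgery", "site",
                                  "length_of_stay", "chronic_disease_count")]))
  expect_error(screen_variables(cohort, default_series_config(),
                                candidates = character(0)), "empty")
  expect_error(screen_variables(cohort, default_series_config(),
                                candidates = "shoe_size"), "unknown candidate")
})

test_that("the log-cost model recovers noiseless multipliers exactly", {
  withr::local_seed(123)
  n <- 600
  sites <- setdiff(site_labels(), "missing")
  adm <- adm_row(sprintf("A%04d", 1:n), patient = sprintf("P%04d", 1:n),
                 year = sample(2010:2017, n, TRUE),
                 age = sample(25:95, n, TRUE),
                 sex = sample(sexes(), n, TRUE),
                 los = sample(3:80, n, TRUE),
                 icu = runif(n) < 0.3, surgery = runif(n) < 0.3,
                 chronic = sample(0:8, n, TRUE), cost = NA_real_)
  site <- sample(sites, n, TRUE)
  mult <- c(abdominal = 1, blood = 2.028, bone_soft_tissue = 1.186,
            heart = 1.620, meninges_brain_spinal = 1.482,
            respiratory = 1.096, urogenital = 1.049, multiple = 1.324,
            unknown = 1.419)
  adm$total_cost <- exp(9 + log(0.998) * adm$age +
                          log(1.047) * (adm$sex == "male") +
                          log(1.078) * adm$chronic_disease_count +
                          log(1.740) * adm$icu_admission +
                          log(2.138) * adm$surgery +
                          log(1.003) * adm$length_of_stay +
                          log(0.966) * (adm$admission_year - 2010) +
                          log(mult[site]))
  inc <- adm
  inc$site_label <- site
  cohort <- manual_cohort(inc)
  fit <- suppressWarnings(fit_cost_model(cohort, flat_series()))
  est <- stats::setNames(fit$table$estimate, fit$table$term)
  expect_equal(unname(est["icu_admissionTRUE"]), 1.740, tolerance = 1e-8)
  expect_equal(unname(est["surgeryTRUE"]), 2.138, tolerance = 1e-8)
  expect_equal(unname(est["siteblood"]), 2.028, tolerance = 1e-8)
  expect_equal(unname(est["admission_year"]), 0.966, tolerance = 1e-8)
  expect_equal(unname(est["age"]), 0.998, tolerance = 1e-8)
  expect_true(all(fit$table$vif[c(1, 2)] < 1.2))
})

test_that("a constant predictor makes the design singular and is reported", {
  adm <- adm_row(sprintf("A%03d", 1:50), patient = sprintf("P%03d", 1:50),
                 year = 2015L, age = sample(30:90, 50, TRUE),
                 cost = exp(rnorm(50, 10, 0.2)))
  cohort <- manual_cohort(adm)  # surgery and icu are constant here
  expect_error(
    suppressWarnings(fit_cost_model(cohort, flat_series(),
                                    variables = c("age", "icu_admission"))),
    "singular design.*icu_admission")
})

test_that("percent change converts multiplicative coefficients", {
  expect_equal(percent_change(1.740), 74)
  expect_equal(percent_change(1), 0)
  expect_equal(percent_change(0.966), -3.4)
  expect_error(percent_change(-0.5), "must be > 0")
})

test_that("variance inflation follows its closed form", {
  orth <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(unname(vif(orth)), c(1, 1))

  expect_warning(v <- vif(cbind(a = 1:10, b = 1:10)), "variance inflation")
  expect_true(all(is.infinite(v)))

  # two columns with sample correlation exactly 0.9 -> VIF = 1/(1-0.81)
  x <- scale(1:20)[, 1]
  z <- stats::resid(stats::lm(rnorm(20) ~ x))
  z <- z / sqrt(sum(z^2) / 19)
  y <- 0.9 * x + sqrt(1 - 0.81) * z
  expect_equal(unname(vif(cbind(x, y))), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-8)
  expect_error(vif(matrix(1:5)), "at least 2 columns")
})
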
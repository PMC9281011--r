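# Yearly linear trend tests, subgroup cost-effectiveness trends,
# covariate-adjusted subgroup costs, and the multivariable log-cost model
# with multicollinearity diagnostics.

#' Linear trend of a yearly aggregate
#'
#' Ordinary least squares of a yearly aggregate on calendar year, with a
#' two-sided t test on the slope (n - 2 degrees of freedom) and a 95%
#' confidence interval from the t quantile. Series with zero residual
#' variance (constant or perfectly linear) return the slope with
#' `degenerate = TRUE` and `p_value = NA` rather than a fabricated p-value.
#'
#' @param values Numeric yearly aggregates (>= 3 points).
#' @param years Strictly increasing calendar years.
#' @param conf_level Confidence level (default 0.95).
#' @return A `trend_result`: list with `slope` (change per calendar year in
#'   the aggregate's units), `ci_low`, `ci_high`, `p_value`, `n_years`,
#'   `degenerate`.
#' @export
#' @examples
#' ref <- dpc_yearly_reference()
#' linear_trend(ref$los_mean, ref$year)  # about -1.7 days/year
linear_trend <- function(values, years, conf_level = 0.95) {
  if (length(values) != length(years))
    stop("values and years must have equal length", call. = FALSE)
  keep <- !is.na(values)
  values <- values[keep]; years <- years[keep]
  if (length(values) < 3L)
    stop("linear_trend() needs at least 3 yearly points", call. = FALSE)
  if (any(diff(years) <= 0))
    stop("years must be strictly increasing", call. = FALSE)
  fit <- stats::lm(values ~ years)
  est <- unname(stats::coef(fit)["years"])
  s <- summary(fit)
  degenerate <- s$sigma < 1e-10 * (max(abs(values)) + 1e-300)
  if (degenerate) {
    res <- list(slope = est, ci_low = est, ci_high = est, p_value = NA_real_,
                n_years = length(values), degenerate = TRUE)
  } else {
    ci <- stats::confint(fit, "years", level = conf_level)
    res <- list(slope = est, ci_low = ci[1], ci_high = ci[2],
                p_value = s$coefficients["years", "Pr(>|t|)"],
                n_years = length(values), degenerate = FALSE)
  }
  structure(res, class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("slope %.4g per year [95%% CI %.4g to %.4g], p = %.4g (n = %d%s)\n",
              x$slope, x$ci_low, x$ci_high,
              if (is.na(x$p_value)) NA else x$p_value, x$n_years,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

trend_as_row <- function(tr) {
  tibble::tibble(slope = tr$slope, ci_low = tr$ci_low, ci_high = tr$ci_high,
                 p_value = tr$p_value, n_years = tr$n_years,
                 degenerate = tr$degenerate)
}

#' Trend of the effective cost per survivor
#'
#' The pipeline's primary outcome: [linear_trend()] applied to the yearly
#' effective-cost-per-survivor series of a [yearly_summary()] table.
#'
#' @param summaries A tibble from [yearly_summary()] (a total row, if
#'   present, is ignored).
#' @return A `trend_result`.
#' @export
effective_cost_trend <- function(summaries) {
  s <- summaries[!is.na(summaries$year), ]
  bad <- s$year[is.na(s$effective_cost_per_survivor)]
  if (length(bad))
    stop("effective cost per survivor undefined for year(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  linear_trend(s$effective_cost_per_survivor, s$year)
}

#' Available subgroup grouping variables
#'
#' @return Character vector of groupings accepted by [subgroup_trends()]
#'   and [adjusted_subgroup_costs()].
#' @export
subgroup_variables <- function() {
  c("age_band", "sex", "site", "single_vs_multiple_site", "icu", "transfer",
    "mechanical_ventilation", "vasopressor", "rrt")
}

grouping_values <- function(adm, grouping) {
  yn <- function(x) factor(ifelse(x, "yes", "no"), levels = c("yes", "no"))
  switch(grouping,
    age_band = cut(adm$age, breaks = c(20, 65, 75, Inf), right = FALSE,
                   labels = c("adults", "early_elderly", "late_elderly")),
    sex = factor(adm$sex, levels = sexes()),
    site = factor(adm$site_label,
                  levels = setdiff(site_labels(), "missing")),
    single_vs_multiple_site = factor(
      ifelse(adm$site_label == "multiple", "multiple", "single"),
      levels = c("single", "multiple")),
    icu = yn(adm$icu_admission),
    transfer = yn(adm$discharge_status == "transfer"),
    mechanical_ventilation = yn(adm$mechanical_ventilation),
    vasopressor = yn(adm$vasopressor),
    rrt = yn(adm$renal_replacement_therapy),
    stop("unknown grouping '", grouping, "'; use one of: ",
         paste(subgroup_variables(), collapse = ", "), call. = FALSE)
  )
}

#' Subgroup trends of the effective cost per survivor
#'
#' Splits the cohort by one grouping variable, recomputes the yearly
#' effective cost per survivor within each level, and applies
#' [linear_trend()] per level. Levels observed in fewer years than the full
#' span are analysed on their available years (`n_years` records how many).
#'
#' @param cohort A `sepsis_cohort` from [build_cohort()].
#' @param series A [series_config()].
#' @param grouping One of `"age_band"` (20-64 / 65-74 / >= 75), `"sex"`,
#'   `"site"`, `"single_vs_multiple_site"`, `"icu"`, `"transfer"`,
#'   `"mechanical_ventilation"`, `"vasopressor"`, `"rrt"`.
#' @param ecs_uses_adjusted_gross Passed to [yearly_summary()].
#' @return Tibble with `grouping`, `level`, `slope`, `ci_low`, `ci_high`,
#'   `p_value`, `n_years`, `degenerate`.
#' @export
subgroup_trends <- function(cohort, series, grouping,
                            ecs_uses_adjusted_gross = FALSE) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  adm <- cohort$included
  g <- grouping_values(adm, grouping)
  rows <- lapply(levels(droplevels(g)), function(lv) {
    ys <- suppressWarnings(yearly_summary(
      adm[which(g == lv), ], series,
      ecs_uses_adjusted_gross = ecs_uses_adjusted_gross))
    ys <- ys[!is.na(ys$effective_cost_per_survivor), ]
    row <- if (nrow(ys) < 3L) {
      # level too sparse for a trend: flagged, not an error
      tibble::tibble(slope = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, p_value = NA_real_,
                     n_years = nrow(ys), degenerate = NA)
    } else {
      trend_as_row(linear_trend(ys$effective_cost_per_survivor, ys$year))
    }
    dplyr::bind_cols(tibble::tibble(grouping = grouping, level = lv), row)
  })
  dplyr::bind_rows(rows)
}

model_frame <- function(adm, series) {
  df <- tibble::tibble(
    cost_usd = adjusted_usd(adm$total_cost, adm$admission_year, series),
    age = adm$age,
    sex = factor(adm$sex, levels = sexes()[c(2, 1)]),  # female reference
    chronic_disease_count = adm$chronic_disease_count,
    site = stats::relevel(droplevels(
      factor(adm$site_label, levels = setdiff(site_labels(), "missing"))),
      ref = "abdominal"),
    icu_admission = adm$icu_admission,
    surgery = adm$surgery,
    length_of_stay = adm$length_of_stay,
    admission_year = adm$admission_year
  )
  df
}

drop_nonpositive_cost <- function(df) {
  bad <- !(df$cost_usd > 0)
  if (any(bad))
    warning(sum(bad), " row(s) with non-positive cost excluded from the ",
            "log-cost model", call. = FALSE)
  df[!bad, ]
}

#' Covariate-adjusted mean cost per subgroup level
#'
#' Fits a linear model on log-transformed adjusted cost with the target
#' grouping plus covariates, then reports, per target level, the
#' back-transformed prediction at the covariate means (marginal
#' standardization) with a delta-method confidence interval. Without a
#' smearing correction the back-transformed value estimates a geometric
#' rather than arithmetic mean.
#'
#' @param cohort A `sepsis_cohort`.
#' @param series A [series_config()].
#' @param target One of [subgroup_variables()].
#' @param covariates Adjustment variables among `"sex"`, `"age"`,
#'   `"chronic_disease_count"`, `"site"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `level`, `adjusted_mean`, `ci_low`, `ci_high`, `n`.
#' @export
adjusted_subgroup_costs <- function(cohort, series, target,
                                    covariates = c("sex", "age",
                                                   "chronic_disease_count",
                                                   "site"),
                                    conf_level = 0.95) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  adm <- cohort$included
  df <- model_frame(adm, series)
  df$.g <- grouping_values(adm, target)
  df <- drop_nonpositive_cost(df)
  df$.g <- droplevels(df$.g)
  if (nlevels(df$.g) < 2L)
    stop("target grouping '", target, "' has fewer than 2 observed levels",
         call. = FALSE)
  covariates <- match.arg(covariates, c("sex", "age",
                                        "chronic_disease_count", "site"),
                          several.ok = TRUE)
  # the target must not reappear among the covariates
  covariates <- setdiff(covariates, switch(target, sex = "sex",
                                           site = "site", character(0)))
  fml <- stats::as.formula(paste("log(cost_usd) ~ .g +",
                                 paste(covariates, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("singular design; aliased column(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  X <- stats::model.matrix(fit)
  xbar <- colMeans(X)
  target_cols <- which(attr(X, "assign") == 1L)
  V <- stats::vcov(fit)
  z <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  rows <- lapply(seq_along(levels(df$.g)), function(i) {
    lv <- levels(df$.g)[i]
    x <- xbar
    x[target_cols] <- 0
    if (i > 1L) x[target_cols[i - 1L]] <- 1  # first level is the reference
    mu <- sum(x * beta)
    se <- sqrt(drop(t(x) %*% V %*% x))
    tibble::tibble(level = lv, adjusted_mean = exp(mu),
                   ci_low = exp(mu - z * se), ci_high = exp(mu + z * se),
                   n = sum(df$.g == lv))
  })
  dplyr::bind_rows(rows)
}

#' Univariable screening of cost-model candidates
#'
#' Regresses log-transformed adjusted cost on each candidate variable alone
#' and retains candidates with an F-test p-value below `alpha` (default
#' 0.10), the screening step preceding the multivariable model.
#'
#' @param cohort A `sepsis_cohort`.
#' @param series A [series_config()].
#' @param candidates Character vector among `"age"`, `"sex"`,
#'   `"chronic_disease_count"`, `"site"`, `"icu_admission"`, `"surgery"`,
#'   `"length_of_stay"`, `"admission_year"`.
#' @param alpha Retention threshold (default 0.10).
#' @return Tibble with `variable`, `p_value`, `retained`.
#' @export
screen_variables <- function(cohort, series,
                             candidates = cost_model_variables(),
                             alpha = 0.10) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  if (length(candidates) == 0L)
    stop("candidate list is empty", call. = FALSE)
  bad <- setdiff(candidates, cost_model_variables())
  if (length(bad))
    stop("unknown candidate variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df <- drop_nonpositive_cost(model_frame(cohort$included, series))
  rows <- lapply(candidates, function(v) {
    fit <- stats::lm(stats::as.formula(paste("log(cost_usd) ~", v)),
                     data = df)
    a <- stats::anova(fit)
    tibble::tibble(variable = v, p_value = a[["Pr(>F)"]][1])
  })
  out <- dplyr::bind_rows(rows)
  out$retained <- out$p_value < alpha
  out
}

#' @rdname fit_cost_model
#' @export
cost_model_variables <- function() {
  c("age", "sex", "chronic_disease_count", "site", "icu_admission",
    "surgery", "length_of_stay", "admission_year")
}

#' Multivariable log-linear model of hospitalization cost
#'
#' Ordinary least squares on the natural log of CPI-adjusted USD cost with
#' age (per year), sex (male vs female), chronic-disease count, infection
#' site (abdominal reference), ICU admission, surgery, length of stay (per
#' day) and admission year (continuous) as predictors. Coefficients and
#' confidence limits are exponentiated, so each is the multiplicative
#' effect on cost; `100 * (coefficient - 1)` is the percent change
#' ([percent_change()]). A variance inflation factor is reported per design
#' column ([vif()]); rows with non-positive cost are dropped with a warning.
#'
#' @param cohort A `sepsis_cohort`.
#' @param series A [series_config()].
#' @param variables Predictors to include (default all of
#'   `cost_model_variables()`, e.g. after [screen_variables()]).
#' @param conf_level Confidence level (default 0.95).
#' @return A `cost_model_result`: list with `table` (tibble: `term`,
#'   `estimate` = exponentiated coefficient, `ci_low`, `ci_high`,
#'   `p_value`, `vif`), `fit` (the `lm` object), `n_used`, `n_dropped`,
#'   `reference` (named reference levels).
#' @export
#' @examples
#' sim <- generate_claims(default_generator_config(scale = 1 / 500), seed = 1)
#' cohort <- build_cohort(sim$admissions, sim$events)
#' fit_cost_model(cohort, default_series_config())$table
fit_cost_model <- function(cohort, series,
                           variables = cost_model_variables(),
                           conf_level = 0.95) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  bad <- setdiff(variables, cost_model_variables())
  if (length(bad))
    stop("unknown model variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df0 <- model_frame(cohort$included, series)
  df <- drop_nonpositive_cost(df0)
  fml <- stats::as.formula(paste("log(cost_usd) ~",
                                 paste(variables, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("singular design; aliased column(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  ci <- stats::confint(fit, level = conf_level)
  p <- summary(fit)$coefficients[, "Pr(>|t|)"]
  X <- stats::model.matrix(fit)[, -1, drop = FALSE]
  v <- if (ncol(X) >= 2L) vif(X) else stats::setNames(NA_real_, colnames(X))
  keep <- setdiff(names(beta), "(Intercept)")
  tab <- tibble::tibble(
    term = keep,
    estimate = exp(unname(beta[keep])),
    ci_low = exp(unname(ci[keep, 1])),
    ci_high = exp(unname(ci[keep, 2])),
    p_value = unname(p[keep]),
    vif = unname(v[keep])
  )
  structure(list(table = tab, fit = fit, n_used = nrow(df),
                 n_dropped = nrow(df0) - nrow(df),
                 reference = c(site = "abdominal", sex = "female")),
            class = "cost_model_result")
}

#' @export
print.cost_model_result <- function(x, ...) {
  cat("Multivariable log-cost model (n =", x$n_used, ")\n")
  cat("Reference levels:",
      paste(names(x$reference), x$reference, sep = " = ", collapse = ", "),
      "\n")
  print(x$table, n = nrow(x$table), ...)
  invisible(x)
}

#' Percent change implied by a multiplicative coefficient
#'
#' `100 * (coefficient - 1)`: the percent change in cost per unit of the
#' predictor on an exponentiated log-model coefficient.
#'
#' @param coefficient Exponentiated coefficient(s), > 0.
#' @return Percent change(s).
#' @export
#' @examples
#' percent_change(1.740)  # 74
percent_change <- function(coefficient) {
  if (any(coefficient <= 0))
    stop("exponentiated coefficients must be > 0", call. = FALSE)
  100 * (coefficient - 1)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from regressing design column
#' `j` on all other columns (with intercept). Reported per column; a
#' constant column has infinite VIF; values above 10 trigger a warning but
#' no column is excluded automatically.
#'
#' @param x Numeric matrix or data frame with >= 2 columns (a design
#'   matrix without intercept).
#' @param warn_threshold Warn when any VIF exceeds this (default 10).
#' @return Named numeric vector of VIFs.
#' @export
#' @examples
#' vif(cbind(a = rnorm(50), b = rnorm(50)))
vif <- function(x, warn_threshold = 10) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (ncol(X) < 2L) stop("vif() needs at least 2 columns", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    ss_tot <- sum((yj - mean(yj))^2)
    if (ss_tot == 0) return(Inf)
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), yj)
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  if (any(is.infinite(out) | out > warn_threshold))
    warning("variance inflation above ", warn_threshold, " for: ",
            paste(names(out)[is.infinite(out) | out > warn_threshold],
                  collapse = ", "), call. = FALSE)
  out
}
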
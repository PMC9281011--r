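---
title: "Claims-based sepsis cohorts and cost-effectiveness trends: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claims-based sepsis cohorts and cost-effectiveness trends: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sepsiscost` implements a complete claims-to-inference pipeline for studying
temporal trends in the medical costs and cost-effectiveness of sepsis care,
of the kind run on Japan's Diagnosis Procedure Combination (DPC) bundled-payment
claims system. Because patient-level DPC extracts are not public, the package
pairs the analysis stages with a synthetic claims generator whose ground
truth is known, so every stage is testable at desk scale. This vignette is
the package's own account of the methods: the case definition, the cost and
cost-effectiveness metrics, the statistical models, what the generator does
and does not emulate, and the numerical and design choices that were
genuinely open.

## The sepsis case definition

Administrative claims carry no laboratory values, so sepsis is identified
from treatment signals rather than from Sepsis-3/SOFA criteria. An admission
is classified as sepsis when both components hold **anywhere during the
stay**:

1. **Presumed serious infection.** There is a day $d$ on which a *new*
   intravenous antibiotic agent is started, a blood culture is drawn on some
   day $c$ with $|c - d| \le 2$, and intravenous antibiotics (any agent —
   switches allowed) are administered on at least four consecutive calendar
   days starting at $d$.
2. **Organ dysfunction.** At least one claims-level dysfunction marker:
   vasopressor use; mechanical ventilation or oxygen supplementation;
   kidney-injury markers (diuretic use, renal-dysfunction codes, renal
   replacement therapy); liver-dysfunction codes; thrombocytopenia codes;
   metabolic-acidosis codes.

All temporal logic runs on 1-based integer day indices (day 1 = admission
day); a same-day stay has length of stay 1. The source rule is day-level
("within ± 2 days"), so no timestamps are modelled.

Several aspects of the rule are underdetermined by its usual prose
statement; the package fixes them as follows, and exposes the load-bearing
ones as parameters:

* **"New" antibiotic** (`lookback_days`, default 2): agent $a$ is newly
  initiated on day $d$ iff $a$ was not administered on days $d-2 \dots d-1$.
  This is the narrowest self-consistent reading, on the same scale as the
  ±2-day culture window. A longer lookback makes the rule stricter about
  re-starts; it is a single integer parameter.
* **Run coverage**: the four-day clause requires coverage by *any*
  intravenous antibiotic, not the same agent, since empirical regimens are
  frequently escalated or narrowed mid-course.
* **Symmetric window**: the ±2-day window is symmetric, so no ordering of
  culture versus initiation is enforced. The reported `initiation_day`
  anchors on the antibiotic day; the reported `culture_day` is the
  qualifying culture closest to initiation (earlier day on ties).
* **Censored runs** (`allow_censored_run`, default `FALSE`): whether a
  patient who dies or is discharged before day $d+3$ can still satisfy the
  run clause is not determined by the rule's prose. The default is strict
  (no waiver); setting the flag waives coverage beyond the recorded stay,
  the behaviour of some other claims-based surveillance definitions. The
  choice moves a small number of short fatal stays in or out of the cohort.
* **Ties**: when several days qualify, the earliest is reported.
* **Dysfunction timing**: markers count anywhere in the stay, matching the
  "during hospital stay" framing; they are not restricted to a window
  around the infection episode.

One property worth recording: the rule is *not* monotone in the antibiotic
events. Adding an administration of agent $a$ on day $d-1$ can destroy the
newness of a qualifying start at $d$ without creating another qualifying
day, and deleting early administrations can create a new start. This is
intrinsic to any "new antibiotic" definition with a lookback, not an
implementation artifact; the test suite therefore checks the detector
against a brute-force clause-by-clause enumeration on random timelines
rather than against monotonicity.

### Cohort construction

Screening applies, in order: the age filter (age ≥ 20; the cohort's
"adults" subgroup starts at 20, so "over the age of 20" is implemented
inclusively), the infection-episode test, the organ-dysfunction test, and
the missing-site exclusion. The four exclusion tallies partition the
screened set — an invariant the tests enforce on every generated dataset.
Site codes collapse to a single label: zero codes → `missing` (excluded);
the explicit `unknown` code alone → `unknown` (retained as its own
category); one site code → that site; two or more distinct codes →
`multiple`.

## Cost metrics

Costs are stored in nominal JPY in the claims tables and adjusted only in
the analysis layer, in a fixed order chosen for bit-reproducibility:
CPI-deflate to reference-year (2017) prices, convert to USD at 115.25
JPY/USD, then aggregate. Deflation and conversion are scalar
multiplications, so the order is mathematically immaterial.

* `cpi_adjust`: cost × CPI(reference year) / CPI(admission year).
* `registrant_adjust`: yearly gross cost × registrants(reference year) /
  registrants(year), correcting for the growing coverage of the claims
  system. Applied to gross costs only.
* `daily_cost`: adjusted cost / length of stay.
* **Effective cost per survivor (ECS)**: yearly gross cost of *all*
  admissions (no deduplication — the metric charges the year for everyone
  treated, survivors and non-survivors) divided by the number of unique
  surviving patients. Repeat admissions are removed from the denominator
  only: the first admission per patient (earliest year, then admission-id
  order) determines both the year a patient is counted in and their vital
  status. First-admission retention is used because the deduplication
  window is otherwise unspecified and this choice is reproducible.
  Whether the ECS numerator should use raw or registrant-adjusted gross
  cost is genuinely open; the default is raw gross
  (`ecs_uses_adjusted_gross = FALSE`), consistent with treating ECS as a
  within-cohort efficiency measure rather than a coverage-corrected
  budget; the flag switches it.
* Quartiles throughout use Tukey hinges (median-of-halves), so printed
  interquartile ranges can be matched exactly on small fixtures.

## Statistical models

**Yearly trends** are ordinary least squares of a yearly aggregate on
calendar year — eight points in the reference study design — with a
two-sided t test (n − 2 df) and a t-based 95% CI. This matches the
aggregate-level "rate per year" reporting style. Degenerate inputs (zero
residual variance) return the slope with a `degenerate` flag and `p = NA`
rather than a fabricated p-value. Note that admission-level regressions of
the same quantities generally give different slopes and much smaller
p-values; the package deliberately reports the aggregate-level test as the
primary trend and leaves admission-level modelling to the multivariable
stage.

**Subgroup trends** recompute the yearly ECS within each level of one
grouping (age band 20–64 / 65–74 / ≥ 75, sex, site, single-vs-multiple
site, ICU, transfer, mechanical ventilation, vasopressor, renal
replacement therapy) and apply the same trend test per level. In the
single-vs-multiple contrast, `unknown` counts as single (it is one
recorded category); levels observed in fewer than three years are flagged
rather than tested.

**Adjusted subgroup costs** fit a linear model on log cost with the target
grouping plus sex, age, chronic-disease count and site, and report each
level's back-transformed prediction at the covariate means with a
delta-method CI (marginal standardization). No smearing correction is
applied, so the back-transformed value estimates a geometric mean; this is
a known, documented bias relative to arithmetic means and is the
appropriate scale for multiplicative comparisons.

**The multivariable cost model** is OLS on natural-log cost with age (per
year), sex, chronic-disease count, site (abdominal reference), ICU
admission, surgery, length of stay (per day) and admission year
(continuous). Log transformation is used because hospital-cost residuals
are strongly right-skewed; on the log scale the generator and the
inferential model are conjugate, which makes parameter recovery a
meaningful end-to-end test. Exponentiated coefficients are multiplicative
effects; `percent_change()` converts them to percent. A univariable screen
(`screen_variables`, retain at p < 0.10) reproduces the screening step of
the reference analysis; variance inflation factors (1/(1 − R²), computed
per design column) are reported with a warning above 10 but never trigger
automatic exclusion. Rows with non-positive cost are dropped with a
logged count. No multiple-testing correction is applied anywhere, matching
the reference analysis; reporting uses two-sided α = 0.05.

## The synthetic claims generator

The generator emulates the *statistical shape* of the published 2010–2017
cohort so that downstream stages face realistic inputs:

* yearly admission targets equal the published counts (67,318 … 233,825)
  times a scale factor (default 1/100, ~12,800 admissions — the full
  eight-year simulation runs in under a second);
* per-year death probabilities follow the published mortality series
  (24.1% falling to 16.9%);
* length of stay is log-normal per year, with the log-mean set to the
  published median and the log-sd derived from the published mean/median
  ratio (declining from median 34 to 26 days);
* cost is multiplicative log-normal. On the CPI-adjusted 2017-price USD
  scale, log cost = base + Σ log(multipliers) + N(0, σ²), with the
  published multivariable coefficients as ground-truth multipliers (age
  0.998/year, male 1.047, chronic disease 1.078, ICU 1.740, surgery 2.138,
  LOS 1.003/day, admission year 0.966, and the site multipliers with
  abdominal as reference). The stored `total_cost` is converted back to
  nominal JPY through the CPI and exchange-rate series, so the claims
  tables remain currency-honest while the adjusted-cost regression can
  recover the multipliers exactly.

Calibration choices that the published tables do not determine were fixed
once and are listed here: base log cost 9.30 (set so realized yearly mean
per-hospitalization costs track the published scale, ≈ \$25.7k in 2010
falling to ≈ \$18.7k; the naive intercept ignores the convexity
contribution of the heavy-tailed LOS term); residual σ = 0.40 (dispersion
after conditioning on stay length and case mix); male fraction 0.589 and
age ≈ N(75, 13²) truncated to [20, 105] with 2% of admissions drawn under
age 20 to exercise the age filter (median ≈ 77); ICU 15.6%; surgery 30%;
chronic-disease count Binomial(8, 0.25); site mixture matching the
published respiratory/multiple/abdominal shares (34.6/29.2/13.6%) with
realistic small shares for the rare sites and 2% missing; survivor
discharge destinations 60.5/10/29.5% home/nursing/transfer (matching the
23.9% overall transfer share); repeat-admission fraction 0.145, calibrated
to the published ratio of admissions to unique patients (1.1166), with
repeats generated only for first-admission survivors so no admission
follows a death. The CPI series is the Japanese national index (2015 =
100) and the yearly registrant counts are reconstructed from the published
gross/adjusted-gross cost ratios, rescaled to sum to the published
screened-adult total — those counts are synthetic calibration values, not
published data, and `default_series_config()` documents them as such.

Event timelines are **rule-exact**: every true sepsis case receives a
timeline satisfying all three infection clauses plus at least one
dysfunction event, and every non-sepsis case receives an adversarial
timeline violating exactly one clause (no events; a three-day run; a
culture three days from initiation; or a complete episode with no
dysfunction event). `perturb_to_negative()` applies the same single-clause
edits to any positive timeline, giving each clause a dedicated
discriminating fixture. Classifier output therefore must agree with ground
truth label-for-label — a property the tests assert exactly.

What the generator does **not** emulate: ICD-10 coding, tariff line items,
within-stay cost structure, correlation between covariates (age, ICU, site
and so on are drawn independently, so the synthetic data contain no
confounding unless a test constructs it), transfer networks, seasonal
effects, or any distributional claim about real DPC costs and stays beyond
the published moments (log-normality is a generator assumption, not a
statement about the source data). Passing tests on synthetic data
therefore demonstrate correctness of the *pipeline logic and inference
under the assumed model*, not fidelity of any real-data estimate.

## Verification design and problem sizes

The test suite runs at sizes chosen to keep the full suite around a
minute while leaving Monte-Carlo error well inside the asserted
tolerances:

* printed-aggregate identities and the −1.7 days/year LOS trend are exact
  arithmetic on the published series;
* detector vs brute-force oracle: 1,000 random ≤30-day timelines, plus
  per-clause perturbation fixtures from 50 generated positives;
* parameter recovery: one generated cohort of ≈ 61,000 admissions
  (scale 1/21), all fifteen exponentiated coefficients within ±5%
  (observed maximum error ≈ 1–2%);
* type-I calibration: 1,500 replicates of an eight-year no-trend cohort
  (200 admissions/year), rejection rate within two Monte-Carlo standard
  errors of 5%;
* marginal calibration of the generator at scale 1/25: per-year mortality
  within three binomial standard errors, and monotone decline of the
  yearly mean log real cost.

## Known limitations

* The sepsis definition is a claims surrogate; without laboratory data it
  cannot implement consensus criteria, and its agreement with
  chart-reviewed sepsis is outside what synthetic data can establish.
* The ECS numerator/denominator populations differ by construction (all
  admissions vs deduplicated survivors); the metric is a ratio of
  aggregates, not a per-patient cost.
* Aggregate-level trend tests on eight points have limited power and their
  p-values differ from admission-level regressions of the same series.
* Back-transformed adjusted means are geometric, not arithmetic.
* The generator's independence of covariates means recovery tests do not
  probe confounding robustness except where a test constructs confounding
  explicitly.

```{r}
library(sepsiscost)
sim <- generate_claims(default_generator_config(scale = 1 / 100), seed = 1)
cohort <- build_cohort(sim$admissions, sim$events)
series <- default_series_config()
summaries <- yearly_summary(cohort, series, include_total = TRUE)
effective_cost_trend(summaries)
fit_cost_model(cohort, series)
```
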
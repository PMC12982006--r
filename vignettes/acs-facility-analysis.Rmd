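---
title: "Facility-level ACS metrics: models, generator calibration, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facility-level ACS metrics: models, generator calibration, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsmetrics)
```

## The analysis this package implements

Antenatal corticosteroids (ACS) mature the fetal lungs when preterm birth is
anticipated, but their benefit concentrates in deliveries that occur within
about 7 days of administration, and exposure of pregnancies that go on to
deliver at term carries possible neurodevelopmental cost.  Coverage and
overtreatment are therefore *facility-level* proportions:

* ACS/34w rate: ACS recipients / deliveries before 34+0 weeks;
* optimal-ACS/34w rate: recipients with an administration-to-delivery
  interval within 7 days / deliveries before 34+0 weeks;
* term/ACS proportion: recipients delivering at ≥ 37+0 weeks / all
  recipients;
* ACS rate among all deliveries.

The package reconstructs these metrics from patient-level registry rows,
regresses them on facility characteristics, and projects the consequences of
raising coverage.  Gestational age is stored in days; "< 34 weeks" means
strictly before 238 days and "term" means ≥ 259 days.  The registry never
defines term in weeks, so the standard obstetric ≥ 37+0 convention is
assumed.

## Cohort construction

**ACS recipiency.** A record counts as a recipient if the ACS checkbox is
ticked *or* a total dose *or* an interval category is documented — detail
fields override an unticked checkbox, because the checkbox is the least
reliably completed field.

**Exclusion cascade.**  Duplicates (exact row equality by default; a key
subset can be supplied), stillbirths or perinatal deaths of unknown timing
(known-timing stillbirths are retained — the cascade reads the rule
literally), neonates other than the first-born of a multiple pregnancy, and
records missing a mandatory obstetric field (no imputation: these are
treated as entry errors).  Steps apply in that fixed order; each record is
counted at its first failing step, so counts always sum to the input.  The
*retained set* is order-invariant — only the attribution of counts to steps
depends on order — and a test asserts this.

**Filters.**  Facility-years with fewer than 10 deliveries before 34 weeks
are dropped (small denominators produce unstable rates), then facility-year
ACS/34w rates — pooled across years, one observation per facility-year —
pass the MAD outlier rule: exclude values farther than 2.5 raw MADs from the
median.  Numerical choices, all exposed as arguments:

* the MAD carries **no** 1.4826 Gaussian-consistency constant (`constant`);
* the rule is **two-sided** by default (`side = "lower"` restricts it to
  anomalously low rates, the reporting-artifact direction);
* if the MAD is zero, any value different from the median is an outlier;
* a rate with a zero denominator is `NA`, never 0-by-convention, and `NA`
  rates are dropped from means and from the outlier rule rather than
  imputed.

Filter order is fixed: exclusions → minimum-volume → MAD.  Annual-mean
profiles average the retained facility-years *unweighted* — "annual means",
not delivery-weighted means — and a facility retains a profile with a single
retained year.

## The outcome models

One OLS model per metric, one observation per facility.  Covariates: care
level grouped as comprehensive perinatal care center vs. other, location in
a government-designated city, annual deliveries, annual deliveries < 34w,
the seven condition prevalences among births < 34w (threatened preterm
labor, hypertensive disorders, preterm PROM, placenta previa, multiple
pregnancy, growth restriction, abruption), maternal transfer and cesarean
rates among births < 34w — 13 terms — plus the ACS/34w rate itself in the
three models where it is not the outcome (14 terms).  Continuous covariates
are standardized to sample mean 0 / SD 1, binaries stay 0/1, the outcome
stays in percentage points, so coefficients compare as *pp of outcome per 1
SD of factor*.  De-standardized slopes (`estimate / sd`) are carried
alongside and satisfy `raw × sd = standardized` to numerical precision.

Confidence intervals are classical t-based with n − p − 1 degrees of
freedom; whether the original analysis used t or normal CIs, or robust
standard errors, is not stated anywhere, so the plain classical choice is
made and exposed via `level`.  Significance is "CI excludes zero"; no
multiple-testing correction is applied because none is part of the analysis
being implemented.  Fits are unweighted: no volume or years-contributed
weighting is described, and `n_years_retained` is reported for transparency
instead of imposing a minimum.

VIF is computed as the diagonal of the inverse covariate correlation matrix,
identical to 1/(1 − R²) from regressing each covariate on the rest; tests
verify both identities.  The volume terms and the all-deliveries ACS rate
are mathematically interrelated, so the suite warns (rather than fails) when
any VIF reaches 3.

The sensitivity variant removes abruptions and Grade 1 cesareans — cases
with no opportunity to treat — and *rebuilds the entire pipeline* from the
subset (tallies, filters, profiles, fits); it does not merely refit the main
profiles.

## The scenario engine

Raising a facility from rate `R` to target `R*` (ΔR pp, increases only — no
downward extrapolation) propagates linearly through three slopes, and the
projected term-exposed count composes multiplicatively:

* Δtreated<34w = n34 · ΔR/100 — exact arithmetic, no slope;
* Δoptimal<34w = n34 · s_opt · ΔR/100;
* Δrecipients = N · s_all · ΔR/100;
* term births after = (A + ΔA)(p_term + s_term·ΔR)/100.

The term delta therefore splits into a linear part and a quadratic part
ΔA·s_term·ΔR/100; tests assert the identity ΔT(λΔR) = λ·linear + λ²·quadratic
exactly.  This is the structural reason term exposure *accelerates* with
more ambitious targets, and why projections here stop at an 80% cap: very
few facilities exceed 90%, and slopes fitted on the observed range should
not be extrapolated far beyond it.

Default slopes divide the standardized coefficients (11.5 pp/SD for optimal
timing, 1.6 for overall recipiency, 2.0 for term proportion) by the 16.3 pp
SD of the ACS/34w rate.  This is a *derivation*, not a measured per-unit
slope; when exact non-normalized coefficients are available they should be
passed to `simulation_slopes()` directly.  Population projections take each
facility's baseline from its own profile and raise every facility below the
cap to exactly the cap.  Rounding to one decimal happens only in the
reporting layer (`report_scenarios()`, `print`); all arithmetic keeps full
precision.

`risk_benefit()` multiplies a chosen delta by externally supplied absolute
risk differences.  The benefit denominator defaults to the additional
treated < 34w births and can be switched to the optimally timed delta; the
harm side always uses the term-exposed delta.  The risk differences
themselves are configuration inputs from the treatment-effect literature —
this package does not estimate them, and their choice dominates any
risk–benefit conclusion.

## What the synthetic generator emulates — and what it does not

`registry_config()` defaults describe the study conditions the package is
calibrated to: 244 facilities over three years; care-level mix 104/137/3
(comprehensive/regional/nondesignated); 36.9% in government-designated
cities; annual volumes lognormal with mean 583.2 and SD 335.3, truncated at
50 (moment-matched — only mean ± SD are published); a gestational-age mix
with 6.3% of deliveries before 34 weeks; condition prevalences among births
< 34w at their published means with between-facility spread; transfer
(49.8%) and cesarean (73.0%) rates among births < 34w; ACS propensity among
births < 34w with mean 63.4% and a Gaussian facility effect (SD 0.134 on the
probability scale) chosen so facility-year rates spread ~16 pp once binomial
noise is added; interval and dose category mixes; and ~12% of recipients
delivering at term.

Choices worth knowing about:

* **Case-mix dispersion.** Each facility's preterm strata are scaled by a
  lognormal multiplier (mean 1, CV 0.58, `preterm_dispersion`), the term
  stratum absorbing the difference.  This reproduces the published
  between-facility SD of the < 34w prevalence (≈ 3.8 pp at a 6.3% mean) and
  is what keeps delivery volume and preterm volume from being collinear in
  the models — with a homogeneous mix their VIF exceeds 25; with the
  published dispersion all VIFs sit below 3.  The term-ACS propensity scales
  with the same multiplier (ACS at term is anticipated-but-averted preterm
  birth), which is also what holds the mean term/ACS proportion near 12%
  across facilities of different risk profiles.
* **Two timing mixes.**  A single interval distribution cannot reproduce
  both the pooled interval table (30.2/26.2/21.9/17.6/4.0% across all
  recipients) and a 46.9% mean optimal-ACS/34w rate at 63.4% coverage; the
  within-7-days share must be ~74% among < 34w recipients.  The generator
  therefore draws intervals from `timing_mix_lt34` and `timing_mix_other`,
  calibrated so their mixture matches the pooled table.
* **Linear-probability planting.**  Planted facility-level slopes act on the
  probability scale: propensity = base + Σ slope·(x − μ)/100 + facility
  effect, clamped to [0, 1].  A logit-scale plant has no closed-form truth
  in the percentage-point units the recovery experiments check once the
  facility effect is integrated out; the linear plant makes
  `planted_truth()` exact by construction.
* **Independence assumptions.**  Conditions are drawn independently per
  record (multiple pregnancy first); timing categories are independent of
  covariates; no transfer networks, tocolysis, or gestational-age dynamics.
  No patient-level joint distribution is published, so these are stand-ins,
  not estimates of the real joint law.
* **Reproducibility.**  One integer seed; each facility has its own derived
  RNG stream, so facility F007 is identical whether 10 or 244 facilities are
  generated, and the record-level and aggregate modes share the same
  facility latents.

**Aggregate mode.**  `generate_facility_year_counts()` draws the
facility-year sufficient statistics (stratum counts, condition counts, ACS
counts) directly from the same law — distributionally equivalent to
generating ~420 000 rows and tallying, but ~50× faster.  The replicated
recovery experiments use it; a test checks the two modes agree.

**What passing tests do not show.**  The generator contains none of the
features the data-quality filters exist for: no under-reporting facilities,
no zero-rate spike, no correlated missingness, no case-mix confounding
beyond what is planted.  Recovery results on synthetic cohorts demonstrate
that the *estimator* is sound under the calibrated conditions, not that real
registry estimates are unbiased.

## Estimator behaviour worth knowing

Two effects, both reproducible with `recovery_experiment()`:

* **The MAD trim is not innocent on clean data.**  At 2.5 raw MADs the rule
  cuts roughly at ±1.69 SD of the facility-year rate distribution.  On real
  data this removes a reporting-artifact spike; on artifact-free synthetic
  data it is truncation on the outcome, which attenuates a planted contrast
  by roughly a third and (because the rate distribution is left-skewed)
  shifts the filtered cohort mean up by 1–2 pp.  The recovery experiments
  therefore run with the outlier filter off (`apply_mad = FALSE`), while
  the ordinary pipeline keeps it on by default.
* **Prevalence covariates are measured with error.**  A facility's TPL
  prevalence enters the model as a 3-year sample proportion with binomial
  noise, so its coefficient is attenuated ~10–13% at typical preterm
  volumes (errors-in-variables).  Sign and significance recovery are
  unaffected; unbiasedness checks plant on an exactly measured factor
  (care-level designation) instead.

A small demonstration (20 replicates here; the test suite runs 200):

```{r recovery, eval = FALSE}
rec <- recovery_experiment("is_comprehensive", slope = 5, n_reps = 20,
                           seed = 1)
attr(rec, "bias_raw")   # close to 0
attr(rec, "coverage")   # near 0.95
```

## The synthetic facility-level table

`synthetic_facility_profiles()` is a *deterministic, synthetic* stand-in for
a deposited facility-level aggregate table: marginal columns are
Gaussian/gamma quantile grids recentered to the published cohort means
(ACS/34w 63.4 ± 16.3, optimal 46.9 ± 14.5, term/ACS 12.0 ± 9.3, all-delivery
6.3 ± 4.0, and the factor summaries), cross-column pairing uses fixed
decorrelating permutations, and a single tilt parameter is root-found so the
population-scenario margins hold exactly: facilities below an 80% rate
jointly hold 6 577 preterm < 34w births in 123 234 deliveries and would
treat 1 211 additional women at the cap.  Joint structure beyond those
calibrated margins is invented; the table demonstrates and tests the
aggregate-input code paths (`read_facility_table()`, `summarize_cohort()`,
`simulate_population()`), it is not data.

## Problem sizes and limitations

The test suite generates cohorts of 25–244 facilities (one full-size
record-level registry of ~420 000 rows for calibration; 200-replicate
recovery at 244 facilities in aggregate mode) and completes in about a
minute.  Known limitations: classical (non-robust) standard errors under
mildly heteroskedastic binomial noise give CI coverage a little above
nominal rather than exactly 95%; the scenario engine is a point projection
with no uncertainty interval (none is defined for it); projections above a
90% coverage target are deliberately unsupported; and the generator's
independence assumptions mean interaction structure (e.g. TPL × timing)
cannot be studied with it.
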
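#' Configuration of the synthetic perinatal registry
#'
#' Builds and validates the configuration object that drives
#' [generate_registry()] and [generate_facility_year_counts()].  The defaults
#' describe a nationwide Japanese-style perinatal registry cohort: 244
#' facilities over 2020--2022, annual delivery volumes with mean 583 and SD
#' 335, 6.3\% of deliveries before 34 weeks, facility-heterogeneous ACS
#' coverage among births `<34w` with mean 63.4\% and between-facility-year SD
#' about 16 percentage points, and about 12\% of ACS recipients delivering at
#' term.
#'
#' @param n_facilities Number of facilities.
#' @param years Calendar years covered (integer vector).
#' @param care_level_mix Probabilities over care levels
#'   `comprehensive`/`regional`/`nondesignated` (must sum to 1).
#' @param city_prob Probability a facility sits in a government-designated
#'   city.
#' @param volume_law Named numeric `c(mean=, sd=)` of annual deliveries per
#'   facility; facilities follow a lognormal law moment-matched to these,
#'   truncated below at `volume_min`.
#' @param volume_min Minimum annual delivery volume.
#' @param ga_mix Probabilities over gestational-age strata
#'   `lt28`/`w28_31`/`w32_33`/`w34_36`/`term`.
#' @param preterm_dispersion Between-facility coefficient of variation of the
#'   preterm case mix: each facility's preterm strata are scaled by a
#'   lognormal multiplier with mean 1 and this CV (referral skew), the term
#'   stratum absorbing the difference.  The default 0.58 reproduces a
#'   between-facility SD of the `<34w` prevalence near 3.8 pp at a 6.3\%
#'   mean; 0 disables case-mix heterogeneity.
#' @param complication_prevalence Mean prevalence of each maternal condition
#'   among births `<34w` (`tpl`, `hdp`, `pprom`, `previa`, `multiple`, `fgr`,
#'   `abruption`), probabilities.
#' @param complication_facility_sd Between-facility SD of the true per-facility
#'   prevalence of each condition (probability scale, same names).
#' @param acs_model List with `base_rate` (mean ACS propensity among births
#'   `<34w`), `facility_sd` (SD of the Gaussian facility effect on the
#'   propensity, probability scale), and `slopes` (named numeric: planted
#'   change in ACS/34w propensity, in percentage points, per unit of the named
#'   facility-level factor; see [planted_truth()]).
#' @param timing_mix_lt34,timing_mix_other Probabilities over
#'   administration-to-delivery interval categories
#'   (`lt48h`/`h48_7d`/`d7_1mo`/`gt1mo`/`missing`) given ACS receipt, for
#'   recipients delivering `<34w` and all other recipients respectively.
#' @param dose_mix Probabilities over total-dose categories
#'   (`d12`/`d24`/`d36`/`d48`/`missing`) given ACS receipt.
#' @param term_acs_rate Probability that a term (`>=37w`) delivery received ACS.
#' @param late_preterm_acs_rate Probability that a 34--36w delivery received
#'   ACS.
#' @param transfer_prob,transfer_facility_sd Mean and between-facility SD of
#'   the maternal transfer probability among births `<34w`.
#' @param cs_prob,cs_facility_sd Mean and between-facility SD of the cesarean
#'   probability among births `<34w`.
#' @param grade1_given_cs_lt34,grade1_given_cs_other Probability a cesarean is
#'   Grade 1 (most urgent), `<34w` births and others.
#' @param term_transfer_prob,term_cs_prob Transfer and cesarean probabilities
#'   for births `>=34w`.
#' @param stillbirth_known_prob Probability of a stillbirth with known timing.
#' @param unknown_timing_prob Probability of a stillbirth/perinatal death of
#'   unknown timing (these rows are later dropped by the exclusion cascade).
#' @param missingness List with `acs_checkbox` (probability the checkbox is
#'   left unticked in a true recipient) and `mandatory` (per-record probability
#'   that one mandatory obstetric field is blank).
#' @param twin_prob_given_multiple Probability a multiple pregnancy is a twin
#'   (rather than triplet).
#' @param emit_later_born If `TRUE`, later-born neonates of multiple
#'   pregnancies are emitted as extra rows (exercises the first-born-only
#'   exclusion); default emits first-borns only, as registry analyses retain.
#' @param seed Integer seed; generation is deterministic given the full
#'   configuration.
#'
#' @return An object of class `registry_config` (a validated list).
#' @seealso [generate_registry()], [planted_truth()]
#' @export
registry_config <- function(
  n_facilities = 244L,
  years = 2020:2022,
  care_level_mix = c(comprehensive = 104 / 244, regional = 137 / 244,
                     nondesignated = 3 / 244),
  city_prob = 90 / 244,
  volume_law = c(mean = 583.2, sd = 335.3),
  volume_min = 50,
  ga_mix = c(lt28 = 0.014, w28_31 = 0.022, w32_33 = 0.027,
             w34_36 = 0.106, term = 0.831),
  preterm_dispersion = 0.58,
  complication_prevalence = c(tpl = 0.488, hdp = 0.192, pprom = 0.293,
                              previa = 0.048, multiple = 0.114, fgr = 0.143,
                              abruption = 0.059),
  complication_facility_sd = c(tpl = 0.154, hdp = 0.070, pprom = 0.102,
                               previa = 0.028, multiple = 0.044, fgr = 0.061,
                               abruption = 0.067),
  acs_model = list(base_rate = 0.634, facility_sd = 0.134, slopes = numeric(0)),
  timing_mix_lt34 = c(lt48h = 0.40, h48_7d = 0.34, d7_1mo = 0.15,
                      gt1mo = 0.07, missing = 0.04),
  timing_mix_other = c(lt48h = 0.132, h48_7d = 0.127, d7_1mo = 0.339,
                       gt1mo = 0.359, missing = 0.043),
  dose_mix = c(d12 = 0.177, d24 = 0.764, d36 = 0.002, d48 = 0.010,
               missing = 0.047),
  term_acs_rate = 0.0091,
  late_preterm_acs_rate = 0.146,
  transfer_prob = 0.498, transfer_facility_sd = 0.167,
  cs_prob = 0.730, cs_facility_sd = 0.103,
  grade1_given_cs_lt34 = 0.12, grade1_given_cs_other = 0.04,
  term_transfer_prob = 0.02, term_cs_prob = 0.19,
  stillbirth_known_prob = 0.004, unknown_timing_prob = 0.001,
  missingness = list(acs_checkbox = 0.05, mandatory = 0.002),
  twin_prob_given_multiple = 0.97,
  emit_later_born = FALSE,
  seed = 1L
) {
  # canonical category order (generation indexes strata positionally)
  reorder_named <- function(x, want, field) {
    if (!setequal(names(x), want))
      stop_config(field, sprintf("must have exactly the categories: %s",
                                 paste(want, collapse = ", ")))
    x[want]
  }
  ga_mix <- reorder_named(ga_mix, c("lt28", "w28_31", "w32_33", "w34_36",
                                    "term"), "ga_mix")
  care_level_mix <- reorder_named(care_level_mix,
                                  c("comprehensive", "regional",
                                    "nondesignated"), "care_level_mix")
  tm <- c("lt48h", "h48_7d", "d7_1mo", "gt1mo", "missing")
  timing_mix_lt34 <- reorder_named(timing_mix_lt34, tm, "timing_mix_lt34")
  timing_mix_other <- reorder_named(timing_mix_other, tm, "timing_mix_other")
  dose_mix <- reorder_named(dose_mix, c("d12", "d24", "d36", "d48",
                                        "missing"), "dose_mix")
  cfg <- structure(
    list(
      n_facilities = as.integer(n_facilities), years = as.integer(years),
      care_level_mix = care_level_mix, city_prob = city_prob,
      volume_law = volume_law, volume_min = volume_min, ga_mix = ga_mix,
      preterm_dispersion = preterm_dispersion,
      complication_prevalence = complication_prevalence,
      complication_facility_sd = complication_facility_sd,
      acs_model = acs_model,
      timing_mix_lt34 = timing_mix_lt34, timing_mix_other = timing_mix_other,
      dose_mix = dose_mix,
      term_acs_rate = term_acs_rate,
      late_preterm_acs_rate = late_preterm_acs_rate,
      transfer_prob = transfer_prob, transfer_facility_sd = transfer_facility_sd,
      cs_prob = cs_prob, cs_facility_sd = cs_facility_sd,
      grade1_given_cs_lt34 = grade1_given_cs_lt34,
      grade1_given_cs_other = grade1_given_cs_other,
      term_transfer_prob = term_transfer_prob, term_cs_prob = term_cs_prob,
      stillbirth_known_prob = stillbirth_known_prob,
      unknown_timing_prob = unknown_timing_prob,
      missingness = missingness,
      twin_prob_given_multiple = twin_prob_given_multiple,
      emit_later_born = isTRUE(emit_later_born),
      seed = as.integer(seed)
    ),
    class = "registry_config"
  )
  validate_registry_config(cfg)
}

#' Validate a registry configuration
#'
#' Checks probability vectors (non-negative, summing to 1 within `1e-9`),
#' scalar probabilities, and structural fields; errors name the offending
#' field.
#'
#' @param cfg A `registry_config`.
#' @return `cfg`, invisibly classed, if valid; otherwise an error.
#' @export
validate_registry_config <- function(cfg) {
  if (cfg$n_facilities < 1L) stop_config("n_facilities", "must be >= 1")
  if (length(cfg$years) == 0L) stop_config("years", "must be non-empty")
  for (f in c("care_level_mix", "ga_mix", "timing_mix_lt34",
              "timing_mix_other", "dose_mix"))
    check_prob_vector(cfg[[f]], f)
  for (f in c("city_prob", "term_acs_rate", "late_preterm_acs_rate",
              "transfer_prob", "cs_prob", "grade1_given_cs_lt34",
              "grade1_given_cs_other", "term_transfer_prob", "term_cs_prob",
              "stillbirth_known_prob", "unknown_timing_prob",
              "twin_prob_given_multiple")) {
    p <- cfg[[f]]
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop_config(f, "must be a single probability in [0, 1]")
  }
  if (any(cfg$complication_prevalence < 0) ||
      any(cfg$complication_prevalence > 1))
    stop_config("complication_prevalence", "probabilities must lie in [0, 1]")
  if (!setequal(names(cfg$complication_prevalence),
                names(cfg$complication_facility_sd)))
    stop_config("complication_facility_sd",
                "must carry the same condition names as complication_prevalence")
  if (!is.numeric(cfg$preterm_dispersion) || cfg$preterm_dispersion < 0)
    stop_config("preterm_dispersion", "must be a non-negative CV")
  if (cfg$volume_law[["mean"]] <= 0) stop_config("volume_law", "mean must be > 0")
  if (cfg$volume_law[["sd"]] < 0) stop_config("volume_law", "sd must be >= 0")
  am <- cfg$acs_model
  if (is.null(am$base_rate) || am$base_rate < 0 || am$base_rate > 1)
    stop_config("acs_model", "base_rate must lie in [0, 1]")
  if (is.null(am$facility_sd) || am$facility_sd < 0)
    stop_config("acs_model", "facility_sd must be >= 0")
  if (length(am$slopes) && is.null(names(am$slopes)))
    stop_config("acs_model", "slopes must be a named numeric vector")
  bad <- setdiff(names(am$slopes), factor_names())
  if (length(bad))
    stop_config("acs_model",
                sprintf("unknown factor(s) in slopes: %s", paste(bad, collapse = ", ")))
  for (f in c("acs_checkbox", "mandatory")) {
    p <- cfg$missingness[[f]]
    if (is.null(p) || p < 0 || p > 1)
      stop_config("missingness", sprintf("`%s` must be a probability", f))
  }
  invisible(cfg)
}

# facility-level factors the metrics stage can compute; planted slopes must
# name one of these
factor_names <- function() {
  c("is_comprehensive", "in_designated_city", "n_total", "n_lt34",
    "tpl", "hdp", "pprom", "previa", "multiple", "fgr", "abruption",
    "transfer", "cesarean")
}

#' Ground truth planted in a synthetic registry
#'
#' Returns the exact facility-level slopes implied by the configuration's
#' `acs_model` (percentage points of ACS/34w propensity per unit of each
#' factor) together with the marginal rates the configuration targets.  Used
#' by parameter-recovery tests.
#'
#' @param cfg A `registry_config`.
#' @return A list with `slope_per_pp` (named numeric over all factor names,
#'   zero where nothing was planted) and `base_rates`.
#' @export
planted_truth <- function(cfg) {
  validate_registry_config(cfg)
  s <- stats::setNames(numeric(length(factor_names())), factor_names())
  s[names(cfg$acs_model$slopes)] <- cfg$acs_model$slopes
  list(
    slope_per_pp = s,
    base_rates = c(
      acs34 = 100 * cfg$acs_model$base_rate,
      optimal34 = 100 * cfg$acs_model$base_rate *
        sum(cfg$timing_mix_lt34[c("lt48h", "h48_7d")]),
      term_acs = 100 * cfg$term_acs_rate,
      preterm34 = 100 * sum(cfg$ga_mix[c("lt28", "w28_31", "w32_33")])
    )
  )
}

#' @export
print.registry_config <- function(x, ...) {
  cat("Synthetic perinatal registry configuration\n")
  cat(sprintf("  facilities: %d, years: %s\n", x$n_facilities,
              paste(range(x$years), collapse = "-")))
  cat(sprintf("  annual volume: mean %.1f, sd %.1f (lognormal, min %g)\n",
              x$volume_law[["mean"]], x$volume_law[["sd"]], x$volume_min))
  cat(sprintf("  deliveries <34w: %.1f%%; ACS/34w propensity: %.1f%% (facility sd %.1f pp)\n",
              100 * sum(x$ga_mix[c("lt28", "w28_31", "w32_33")]),
              100 * x$acs_model$base_rate, 100 * x$acs_model$facility_sd))
  if (length(x$acs_model$slopes))
    cat("  planted slopes (pp per unit):",
        paste(sprintf("%s=%.3g", names(x$acs_model$slopes), x$acs_model$slopes),
              collapse = ", "), "\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read / write a registry configuration as YAML
#'
#' Round-trips the configuration through a plain YAML file so a pipeline run
#' can be described by a single text document.
#'
#' @param path File path.
#' @param cfg A `registry_config`.
#' @return `read_registry_config()` returns a validated `registry_config`;
#'   `write_registry_config()` returns `path` invisibly.
#' @export
read_registry_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("care_level_mix", "ga_mix", "timing_mix_lt34",
              "timing_mix_other", "dose_mix", "complication_prevalence",
              "complication_facility_sd", "volume_law"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  if (!is.null(raw$acs_model$slopes))
    raw$acs_model$slopes <- unlist(raw$acs_model$slopes)
  do.call(registry_config, raw)
}

#' @rdname read_registry_config
#' @export
write_registry_config <- function(cfg, path) {
  validate_registry_config(cfg)
  out <- unclass(cfg)
  out$acs_model$slopes <- as.list(out$acs_model$slopes)
  for (f in c("care_level_mix", "ga_mix", "timing_mix_lt34",
              "timing_mix_other", "dose_mix", "complication_prevalence",
              "complication_facility_sd", "volume_law"))
    out[[f]] <- as.list(out[[f]])
  yaml::write_yaml(out, path)
  invisible(path)
}
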
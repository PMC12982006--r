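#' Baseline state of a facility for scenario projection
#'
#' Captures, for one facility (or one hypothetical "typical" facility), the
#' annual delivery volume, deliveries before 34 weeks, the baseline ACS/34w
#' rate `R`, and the baseline counts of treated, optimally timed, overall and
#' term-delivering ACS recipients.  Counts left `NULL` default to the values
#' implied by the rates/volumes.
#'
#' @param n_deliveries Annual deliveries `N`.
#' @param n_preterm34 Annual deliveries before 34 weeks.
#' @param acs34_rate Baseline ACS/34w rate `R`, percentage points.
#' @param treated34 Baseline ACS recipients delivering `<34w` (default
#'   `n_preterm34 * R / 100`).
#' @param optimal34 Baseline optimally timed recipients `<34w`.
#' @param acs_all Baseline ACS recipients overall (`A`).
#' @param term_acs Baseline term births among recipients (`T`).
#' @return Object of class `scenario_baseline`.
#' @export
scenario_baseline <- function(n_deliveries, n_preterm34, acs34_rate,
                              treated34 = NULL, optimal34 = NULL,
                              acs_all = NULL, term_acs = NULL) {
  treated34 <- treated34 %||% (n_preterm34 * acs34_rate / 100)
  optimal34 <- optimal34 %||% NA_real_
  acs_all <- acs_all %||% NA_real_
  term_acs <- term_acs %||% NA_real_
  b <- structure(list(N = n_deliveries, n34 = n_preterm34, R = acs34_rate,
                      treated34 = treated34, optimal34 = optimal34,
                      A = acs_all, T = term_acs,
                      p_term = 100 * term_acs / acs_all),
                 class = "scenario_baseline")
  with(b, {
    if (any(c(N, n34, R, treated34) < 0, na.rm = TRUE))
      stop("scenario baseline values must be non-negative", call. = FALSE)
    if (!is.na(optimal34) && optimal34 > treated34 + 1e-9)
      stop("optimal34 cannot exceed treated34", call. = FALSE)
    if (!is.na(T) && !is.na(A) && T > A + 1e-9)
      stop("term births among recipients cannot exceed recipients",
           call. = FALSE)
    if (abs(treated34 - n34 * R / 100) > 0.5 + 1e-9)
      warning("treated34 is not n34 * R / 100 within rounding", call. = FALSE)
  })
  b
}

#' Per-percentage-point simulation slopes
#'
#' The three facility-level responses to a 1 pp increase of the ACS/34w rate:
#' `s_opt` (pp of the optimal-ACS/34w rate), `s_all` (pp of the ACS rate
#' among all deliveries), `s_term` (pp of the term/ACS proportion).
#' [default_simulation_slopes()] derives them from the fitted standardized
#' coefficients (11.5, 1.6 and 2.0 pp per SD respectively) divided by the
#' 16.3 pp SD of the ACS/34w rate; pass exact per-unit coefficients (e.g.
#' from [destandardize()]) to replace the derivation.
#'
#' @param s_opt,s_all,s_term Slopes, pp per pp.
#' @param coef_opt,coef_all,coef_term Standardized coefficients (pp per SD).
#' @param sd_r SD of the ACS/34w rate used for de-standardization.
#' @return Object of class `simulation_slopes`.
#' @export
simulation_slopes <- function(s_opt, s_all, s_term) {
  stopifnot(is.finite(s_opt), is.finite(s_all), is.finite(s_term))
  structure(list(s_opt = s_opt, s_all = s_all, s_term = s_term),
            class = "simulation_slopes")
}

#' @rdname simulation_slopes
#' @export
default_simulation_slopes <- function(coef_opt = 11.5, coef_all = 1.6,
                                      coef_term = 2.0, sd_r = 16.3) {
  simulation_slopes(coef_opt / sd_r, coef_all / sd_r, coef_term / sd_r)
}

#' Project one facility to a higher ACS/34w rate
#'
#' Raises the facility's ACS/34w rate from its baseline `R` to `target_rate`
#' (`dR = target - R`, pp) and propagates:
#' \itemize{
#' \item additional treated `<34w` births: `n34 * dR / 100` (exact);
#' \item additional optimally timed: `n34 * s_opt * dR / 100`;
#' \item additional recipients overall: `dA = N * s_all * dR / 100`;
#' \item term births among recipients: post count
#'   `(A + dA) * (p_term + s_term * dR) / 100`, whose delta decomposes into a
#'   part linear in `dR` and a quadratic part `dA * s_term * dR / 100` -- term
#'   exposure accelerates as the target rises.
#' }
#'
#' @param baseline A [scenario_baseline()].
#' @param slopes A [simulation_slopes()].
#' @param target_rate Target ACS/34w rate, pp; must be `>=` baseline `R`
#'   (projection is for increases only).
#' @return Object of class `acs_scenario`: `baseline`, `target`, `dR`,
#'   `delta` and `post` (named: `treated34`, `optimal34`, `acs_all`,
#'   `term_acs`), and `term_decomposition` (`linear`, `quadratic`).  Full
#'   precision is kept; rounding to 1 decimal happens only in reporting.
#' @examples
#' sc <- simulate_facility(
#'   scenario_baseline(500, 30, 60, treated34 = 18, optimal34 = 14,
#'                     acs_all = 40, term_acs = 5),
#'   default_simulation_slopes(), 80)
#' print(sc)
#' @export
simulate_facility <- function(baseline, slopes, target_rate) {
  stopifnot(inherits(baseline, "scenario_baseline"),
            inherits(slopes, "simulation_slopes"))
  if (target_rate < baseline$R)
    stop("target rate below baseline: projection is for increases only",
         call. = FALSE)
  dR <- target_rate - baseline$R
  d_treated <- baseline$n34 * dR / 100
  d_opt <- baseline$n34 * slopes$s_opt * dR / 100
  d_all <- baseline$N * slopes$s_all * dR / 100
  if (!is.na(baseline$p_term)) {
    post_term <- (baseline$A + d_all) *
      (baseline$p_term + slopes$s_term * dR) / 100
    d_term <- post_term - baseline$T
    quad <- d_all * slopes$s_term * dR / 100
    lin <- d_all * baseline$p_term / 100 + baseline$A * slopes$s_term * dR / 100
  } else {
    post_term <- d_term <- quad <- lin <- NA_real_
  }
  delta <- c(treated34 = d_treated, optimal34 = d_opt, acs_all = d_all,
             term_acs = d_term)
  post <- c(treated34 = baseline$treated34 + d_treated,
            optimal34 = baseline$optimal34 + d_opt,
            acs_all = baseline$A + d_all,
            term_acs = post_term)
  structure(list(baseline = baseline, target = target_rate, dR = dR,
                 delta = delta, post = post,
                 term_decomposition = c(linear = lin, quadratic = quad)),
            class = "acs_scenario")
}

#' Population-wide projection over facility profiles
#'
#' Applies [simulate_facility()] to every facility whose annual-mean ACS/34w
#' rate is below `cap`, raising each exactly to `cap`; facilities at or above
#' `cap` are untouched.  Facility baselines come from the profile's own
#' annual means (`n_total`, `n_lt34` and the four metric rates).  Deltas are
#' summed; the eligibility summary reports the eligible facilities' total
#' deliveries and preterm `<34w` count.
#'
#' @param profiles Facility profiles (see [build_profiles()] or
#'   [synthetic_facility_profiles()]).
#' @param slopes A [simulation_slopes()].
#' @param cap Target ACS/34w rate, pp (default 80).
#' @return Object of class `acs_scenario` (aggregated deltas and posts) with
#'   an extra `eligibility` component: `n_facilities`, `n_deliveries`,
#'   `n_preterm34`.
#' @export
simulate_population <- function(profiles, slopes, cap = 80) {
  ok <- !is.na(profiles$acs34_rate)
  if (!all(ok)) {
    warning(sprintf("%d facilit(ies) without a defined ACS/34w rate skipped",
                    sum(!ok)), call. = FALSE)
    profiles <- profiles[ok, , drop = FALSE]
  }
  elig <- profiles$acs34_rate < cap
  zero <- c(treated34 = 0, optimal34 = 0, acs_all = 0, term_acs = 0)
  delta <- zero; post <- zero; lin <- 0; quad <- 0
  base_tot <- zero
  for (i in which(elig)) {
    p <- profiles[i, ]
    b <- scenario_baseline(
      n_deliveries = p$n_total, n_preterm34 = p$n_lt34,
      acs34_rate = p$acs34_rate,
      optimal34 = p$n_lt34 * p$optimal34_rate / 100,
      acs_all = p$n_total * p$acs_all_rate / 100,
      term_acs = p$n_total * p$acs_all_rate / 100 * p$term_acs_prop / 100)
    sc <- simulate_facility(b, slopes, cap)
    delta <- delta + ifelse(is.na(sc$delta), 0, sc$delta)
    post <- post + ifelse(is.na(sc$post), 0, sc$post)
    lin <- lin + sc$term_decomposition[["linear"]]
    quad <- quad + sc$term_decomposition[["quadratic"]]
    base_tot <- base_tot + c(treated34 = b$treated34, optimal34 = b$optimal34,
                             acs_all = b$A, term_acs = b$T)
  }
  structure(list(
    baseline = base_tot, target = cap, dR = NA_real_,
    delta = delta, post = post,
    term_decomposition = c(linear = lin, quadratic = quad),
    eligibility = c(n_facilities = sum(elig),
                    n_deliveries = sum(profiles$n_total[elig]),
                    n_preterm34 = sum(profiles$n_lt34[elig]))),
    class = "acs_scenario")
}

scenario_metric_labels <- c(
  treated34 = "ACS recipients delivering <34w",
  optimal34 = "Optimally timed ACS, delivering <34w",
  acs_all = "ACS recipients (overall)",
  term_acs = "ACS recipients delivering at term")

#' @export
print.acs_scenario <- function(x, ...) {
  if (!is.null(x$eligibility)) {
    cat(sprintf("Population scenario: %d facilities below %g%% raised to the cap\n",
                x$eligibility[["n_facilities"]], x$target))
    cat(sprintf("  eligible: %.0f deliveries / %.0f preterm <34w per year\n",
                x$eligibility[["n_deliveries"]], x$eligibility[["n_preterm34"]]))
  } else {
    cat(sprintf("Facility scenario: ACS/34w rate %g%% -> %g%% (dR = %g pp)\n",
                x$baseline$R, x$target, x$dR))
  }
  base <- if (is.null(x$eligibility))
    c(treated34 = x$baseline$treated34, optimal34 = x$baseline$optimal34,
      acs_all = x$baseline$A, term_acs = x$baseline$T) else x$baseline
  for (m in names(x$delta)) {
    if (is.na(x$delta[[m]])) next
    cat(sprintf("  %-38s %s\n", scenario_metric_labels[[m]],
                format_scenario_delta(x$delta[[m]], base[[m]], x$post[[m]])))
  }
  invisible(x)
}

# "+6.0 (18 -> 24)" -- one decimal, baseline/post trimmed of trailing zeros
format_scenario_delta <- function(delta, base, post) {
  fmt1 <- function(v) {
    s <- sprintf("%.1f", v)
    sub("\\.0$", "", s)
  }
  if (is.na(base) || is.na(post)) sprintf("%+.1f", delta)
  else sprintf("%+.1f (%s -> %s)", delta, fmt1(base), fmt1(post))
}

#' Tabulate scenario results
#'
#' One row per scenario and metric, with baseline, post and delta at full
#' precision plus the one-decimal display label, e.g. `"+6.0 (18 -> 24)"`.
#' The data frame is the machine-readable twin of the printed table and
#' round-trips through [utils::write.table()] / [utils::read.table()].
#'
#' @param results A single `acs_scenario` or a (possibly named) list of them.
#' @param path Optional path to write the table (TSV).
#' @return Data frame with columns `scenario`, `metric`, `baseline`, `post`,
#'   `delta`, `label`.
#' @export
report_scenarios <- function(results, path = NULL) {
  if (inherits(results, "acs_scenario")) results <- list(results)
  if (is.null(names(results)))
    names(results) <- sprintf("scenario_%d", seq_along(results))
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    base <- if (is.null(x$eligibility))
      c(treated34 = x$baseline$treated34, optimal34 = x$baseline$optimal34,
        acs_all = x$baseline$A, term_acs = x$baseline$T) else x$baseline
    data.frame(scenario = nm, metric = names(x$delta),
               baseline = as.numeric(base[names(x$delta)]),
               post = as.numeric(x$post[names(x$delta)]),
               delta = as.numeric(x$delta),
               label = vapply(names(x$delta), function(m)
                 format_scenario_delta(x$delta[[m]], base[[m]], x$post[[m]]),
                 ""),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}

#' Absolute-risk effect estimates for the risk-benefit translation
#'
#' The projection translates additional treated or term-exposed births into
#' outcome counts using externally supplied absolute risk differences (per
#' additional exposed birth); these effect sizes come from the treatment
#' literature and are configuration inputs, not estimates of this package.
#'
#' @param benefits Named numeric of risk differences in `[0, 1]` applied to
#'   the benefit denominator (additional treated -- or optimally timed --
#'   `<34w` births), e.g. `c(perinatal_death = ..., ivh = ...,
#'   developmental_delay = ...)`.
#' @param harms Named numeric of risk differences in `[0, 1]` applied per
#'   additional term-exposed birth, e.g. `c(mental_behavioral_disorder = ...)`.
#' @return Object of class `effect_estimates`.
#' @export
effect_estimates <- function(benefits = numeric(0), harms = numeric(0)) {
  stopifnot(all(benefits >= 0 & benefits <= 1),
            all(harms >= 0 & harms <= 1))
  structure(list(benefits = benefits, harms = harms),
            class = "effect_estimates")
}

#' Translate scenario deltas into outcome counts
#'
#' `prevented = benefit_denominator_delta x risk_difference` for every benefit
#' outcome and `additional = delta_term_acs x risk_difference` for every harm
#' outcome; linear in the deltas.
#'
#' @param result An `acs_scenario`.
#' @param effects An [effect_estimates()].
#' @param denominator Which delta the benefit risk differences multiply:
#'   `"treated34"` (additional treated `<34w` births, default) or
#'   `"optimal34"` (additional optimally timed).
#' @return Data frame: `outcome`, `type` (benefit/harm), `delta_used`,
#'   `risk_difference`, `cases`.
#' @export
risk_benefit <- function(result, effects,
                         denominator = c("treated34", "optimal34")) {
  stopifnot(inherits(result, "acs_scenario"),
            inherits(effects, "effect_estimates"))
  denominator <- match.arg(denominator)
  dben <- result$delta[[denominator]]
  dharm <- result$delta[["term_acs"]]
  rows <- list()
  if (length(effects$benefits))
    rows$b <- data.frame(outcome = names(effects$benefits), type = "benefit",
                         delta_used = dben,
                         risk_difference = as.numeric(effects$benefits),
                         cases = dben * as.numeric(effects$benefits),
                         stringsAsFactors = FALSE)
  if (length(effects$harms))
    rows$h <- data.frame(outcome = names(effects$harms), type = "harm",
                         delta_used = dharm,
                         risk_difference = as.numeric(effects$harms),
                         cases = dharm * as.numeric(effects$harms),
                         stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
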
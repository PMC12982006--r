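# derived rates (percent); zero denominators give NA, never 0-by-convention
add_metric_rates <- function(m) {
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  m$acs34_rate <- pct(m$n_acs_lt34, m$n_lt34)
  m$optimal34_rate <- pct(m$n_acs_optimal_lt34, m$n_lt34)
  m$term_acs_prop <- pct(m$n_acs_term, m$n_acs_all)
  m$acs_all_rate <- pct(m$n_acs_all, m$n_total)
  for (cn in c("tpl", "hdp", "pprom", "previa", "multiple", "fgr",
               "abruption"))
    m[[cn]] <- pct(m[[paste0("n_", cn, "_lt34")]], m$n_lt34)
  m$transfer <- pct(m$n_transfer_lt34, m$n_lt34)
  m$cesarean <- pct(m$n_cs_lt34, m$n_lt34)
  m
}

#' Tally facility-year ACS metrics from patient-level records
#'
#' Aggregates retained delivery records into one row per facility-year:
#' delivery counts by gestational-age stratum, complication / transfer /
#' cesarean counts among births `<34w`, ACS recipient counts (per
#' [is_acs_recipient()]) overall, among births `<34w`, optimally timed
#' (interval within 7 days, i.e. categories `lt48h` and `48h_7d`), and at
#' term, plus the four derived rates in percent: `acs34_rate`,
#' `optimal34_rate`, `term_acs_prop`, `acs_all_rate`.  Rates with a zero
#' denominator are `NA`.
#'
#' @param records Delivery-record data frame (post-exclusion), or an
#'   `acs_registry`.
#' @return Data frame of facility-year metrics.
#' @export
compute_facility_year_metrics <- function(records) {
  if (inherits(records, "acs_registry")) records <- records$records
  g <- interaction(records$facility_id, records$year, drop = TRUE, sep = "\r")
  ga <- records$ga_days
  acs <- is_acs_recipient(records)
  lt34 <- ga < .ga_days[["lt34"]]
  term <- ga >= .ga_days[["lt37"]]
  optimal <- acs & !is.na(records$acs_interval) &
    records$acs_interval %in% c("lt48h", "48h_7d")
  flag01 <- function(x) as.numeric(!is.na(x) & x == 1L)
  ind <- cbind(
    n_total = 1,
    n_lt37 = as.numeric(ga < .ga_days[["lt37"]]),
    n_lt34 = as.numeric(lt34),
    n_lt32 = as.numeric(ga < .ga_days[["lt32"]]),
    n_lt28 = as.numeric(ga < .ga_days[["lt28"]]),
    n_term = as.numeric(term),
    n_acs_all = as.numeric(acs),
    n_acs_lt34 = as.numeric(acs & lt34),
    n_acs_optimal_lt34 = as.numeric(optimal & lt34),
    n_acs_term = as.numeric(acs & term),
    n_tpl_lt34 = flag01(records$tpl) * lt34,
    n_hdp_lt34 = flag01(records$hdp) * lt34,
    n_pprom_lt34 = flag01(records$pprom) * lt34,
    n_previa_lt34 = flag01(records$previa) * lt34,
    n_multiple_lt34 = flag01(records$multiple) * lt34,
    n_fgr_lt34 = flag01(records$fgr) * lt34,
    n_abruption_lt34 = flag01(records$abruption) * lt34,
    n_transfer_lt34 = flag01(records$transfer_in) * lt34,
    n_cs_lt34 = flag01(records$cesarean) * lt34
  )
  agg <- rowsum(ind, g)
  key <- strsplit(rownames(agg), "\r", fixed = TRUE)
  m <- data.frame(facility_id = vapply(key, `[`, "", 1L),
                  year = as.integer(vapply(key, `[`, "", 2L)),
                  agg, row.names = NULL, stringsAsFactors = FALSE)
  m <- m[order(m$facility_id, m$year), , drop = FALSE]
  rownames(m) <- NULL
  add_metric_rates(m)
}

#' Minimum preterm-volume filter
#'
#' Drops facility-years with fewer than `min_lt34` deliveries before 34
#' weeks; small denominators yield unstable rate estimates.
#'
#' @param metrics Facility-year metrics.
#' @param min_lt34 Threshold (default 10, i.e. retain `n_lt34 >= 10`).
#' @return List with `retained` and `removed` metric data frames.
#' @export
filter_min_preterm <- function(metrics, min_lt34 = 10) {
  keep <- metrics$n_lt34 >= min_lt34
  list(retained = metrics[keep, , drop = FALSE],
       removed = metrics[!keep, , drop = FALSE])
}

#' Median-absolute-deviation outlier rule
#'
#' Flags values more than `k` raw median absolute deviations from the median:
#' `mad = median(|x - median(x)|)` with no Gaussian consistency constant
#' (set `constant = 1.4826` for the consistent version).  Two-sided by
#' default; `side = "lower"` flags only anomalously low values.  If the MAD is
#' zero, any value different from the median is flagged.
#'
#' @param values Numeric vector (e.g. facility-year ACS/34w rates).
#' @param k Multiplier (default 2.5).
#' @param constant Scale constant multiplying the MAD (default 1).
#' @param side `"both"` or `"lower"`.
#' @return List with `kept` and `excluded` (integer indices into `values`),
#'   `center` (median), `mad`, and `threshold` (`k * constant * mad`).
#' @export
mad_filter <- function(values, k = 2.5, constant = 1,
                       side = c("both", "lower")) {
  side <- match.arg(side)
  if (length(values) == 0L) stop("mad_filter: empty input", call. = FALSE)
  if (anyNA(values)) stop("mad_filter: values contain NA", call. = FALSE)
  med <- stats::median(values)
  m <- stats::median(abs(values - med)) * constant
  thr <- k * m
  dev <- if (side == "both") abs(values - med) else med - values
  out <- if (m > 0) dev > thr else
    if (side == "both") values != med else values < med
  list(kept = which(!out), excluded = which(out), center = med, mad = m,
       threshold = thr)
}

#' Apply the MAD outlier rule to facility-year metrics
#'
#' Pools the `acs34_rate` of every facility-year (one observation each) and
#' removes outliers per [mad_filter()]; facility-years with an undefined rate
#' (zero `<34w` denominator) are removed with their own count, since the
#' outlier rule cannot assess them.
#'
#' @param metrics Facility-year metrics (normally after
#'   [filter_min_preterm()]).
#' @inheritParams mad_filter
#' @return List with `retained`, `removed`, `undefined` (rows lacking a rate)
#'   and `filter` (the [mad_filter()] result).
#' @export
apply_mad_filter <- function(metrics, k = 2.5, constant = 1,
                             side = c("both", "lower")) {
  ok <- !is.na(metrics$acs34_rate)
  def <- metrics[ok, , drop = FALSE]
  f <- mad_filter(def$acs34_rate, k = k, constant = constant,
                  side = match.arg(side))
  list(retained = def[f$kept, , drop = FALSE],
       removed = def[f$excluded, , drop = FALSE],
       undefined = metrics[!ok, , drop = FALSE],
       filter = f)
}

#' Build annual-mean facility profiles
#'
#' Collapses retained facility-years to one observation per facility: the
#' unweighted mean across years of each count and rate (undefined rates are
#' dropped from their mean, not treated as zero), joined with the facility
#' attributes.  `is_comprehensive` groups comprehensive perinatal care
#' centers against all others.
#'
#' @param metrics Retained facility-year metrics.
#' @param facilities Facility attribute table (`facility_id`, `care_level`,
#'   `designated_city`).
#' @return Data frame of facility profiles, one regression observation per
#'   facility, with `n_years_retained`.
#' @export
build_profiles <- function(metrics, facilities) {
  if (nrow(metrics) == 0L) stop("build_profiles: no retained facility-years",
                                call. = FALSE)
  num <- c("n_total", "n_lt37", "n_lt34", "n_lt32", "n_lt28", "n_term",
           "acs34_rate", "optimal34_rate", "term_acs_prop", "acs_all_rate",
           "tpl", "hdp", "pprom", "previa", "multiple", "fgr", "abruption",
           "transfer", "cesarean")
  vals <- as.matrix(metrics[num])
  ok <- !is.na(vals)
  vals[!ok] <- 0
  sums <- rowsum(vals, metrics$facility_id)
  cnts <- rowsum(ok + 0, metrics$facility_id)
  pm <- sums / cnts                      # NaN where a rate is never defined
  pm[cnts == 0] <- NA_real_
  yrs <- rowsum(rep(1L, nrow(metrics)), metrics$facility_id)
  prof <- data.frame(facility_id = rownames(sums),
                     n_years_retained = as.integer(yrs[, 1L]),
                     pm, row.names = NULL, stringsAsFactors = FALSE)
  i <- match(prof$facility_id, facilities$facility_id)
  if (anyNA(i))
    stop("build_profiles: facility attributes missing for some facilities",
         call. = FALSE)
  prof$care_level <- facilities$care_level[i]
  prof$is_comprehensive <- as.integer(prof$care_level == "comprehensive")
  prof$in_designated_city <- as.integer(as.logical(facilities$designated_city[i]))
  prof
}

#' Descriptive cohort summary
#'
#' Mean and sample SD (n-1 denominator) of every facility-level factor and
#' ACS metric over the profiles, plus counts and percentages for the
#' categorical attributes.  Columns with undefined values in some facilities
#' report the number of facilities contributing.
#'
#' @param profiles Facility profiles from [build_profiles()].
#' @return Object of class `cohort_summary` (data frame: `item`, `mean`,
#'   `sd`, `n_facilities`, `label`).
#' @export
summarize_cohort <- function(profiles) {
  num <- c(n_total = "Annual total deliveries",
           n_term = "Full-term deliveries",
           n_lt37 = "Deliveries <37 weeks",
           n_lt34 = "Deliveries <34 weeks",
           n_lt32 = "Deliveries <32 weeks",
           n_lt28 = "Deliveries <28 weeks",
           tpl = "TPL among <34w (%)",
           hdp = "HDP among <34w (%)",
           pprom = "Preterm PROM among <34w (%)",
           previa = "Placenta previa among <34w (%)",
           multiple = "Multiple pregnancy among <34w (%)",
           fgr = "FGR among <34w (%)",
           abruption = "Placental abruption among <34w (%)",
           transfer = "Maternal transfer among <34w (%)",
           cesarean = "Cesarean among <34w (%)",
           acs34_rate = "ACS/34w rate (%)",
           optimal34_rate = "Optimal-ACS/34w rate (%)",
           term_acs_prop = "Term/ACS proportion (%)",
           acs_all_rate = "ACS rate, all deliveries (%)")
  rows <- lapply(names(num), function(cn) {
    x <- profiles[[cn]]
    x <- x[!is.na(x)]
    data.frame(item = cn, mean = mean(x), sd = stats::sd(x),
               n_facilities = length(x), label = num[[cn]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cat_rows <- data.frame(
    item = c("comprehensive", "regional", "nondesignated", "designated_city"),
    mean = 100 * c(mean(profiles$care_level == "comprehensive", na.rm = TRUE),
                   mean(profiles$care_level == "regional", na.rm = TRUE),
                   mean(profiles$care_level == "nondesignated", na.rm = TRUE),
                   mean(profiles$in_designated_city, na.rm = TRUE)),
    sd = NA_real_, n_facilities = nrow(profiles),
    label = c("Comprehensive perinatal care centers (%)",
              "Regional perinatal care centers (%)",
              "Nondesignated facilities (%)",
              "Located in government-designated city (%)"),
    stringsAsFactors = FALSE)
  structure(rbind(cat_rows, out), class = c("cohort_summary", "data.frame"))
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  cat(sprintf("Cohort summary (%d facilities)\n", max(x$n_facilities)))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$sd[i]))
      cat(sprintf("  %-42s %6.*f%%\n", x$label[i], digits, x$mean[i]))
    else
      cat(sprintf("  %-42s %6.*f (+/-%.*f)%s\n", x$label[i], digits, x$mean[i],
                  digits, x$sd[i],
                  if (x$n_facilities[i] < max(x$n_facilities))
                    sprintf("  [n=%d]", x$n_facilities[i]) else ""))
  }
  invisible(x)
}

#' Run the full cohort-construction pipeline
#'
#' Convenience wrapper: exclusion cascade, facility-year tally,
#' minimum-preterm filter, MAD outlier filter (optional), annual-mean
#' profiles.
#'
#' @param registry An `acs_registry` (records + facility attributes), or the
#'   output of [generate_facility_year_counts()] (metrics + facility
#'   attributes), in which case the patient-level stages are skipped.
#' @param min_lt34 Minimum `<34w` deliveries per facility-year.
#' @param mad_k MAD multiplier; `Inf` (or `apply_mad = FALSE`) disables the
#'   outlier filter.
#' @param apply_mad Apply the MAD outlier filter?
#' @return List with `profiles`, `metrics` (retained facility-years),
#'   `exclusions` (log, `NULL` for aggregate input), and `filters` (counts
#'   removed at each stage).
#' @export
build_cohort <- function(registry, min_lt34 = 10, mad_k = 2.5,
                         apply_mad = TRUE) {
  if (!is.null(registry$records)) {
    ex <- apply_exclusions(registry$records)
    m <- compute_facility_year_metrics(ex$records)
    exlog <- ex$log
  } else if (!is.null(registry$metrics)) {
    m <- registry$metrics
    exlog <- NULL
  } else {
    stop("registry must carry `records` or `metrics`", call. = FALSE)
  }
  f1 <- filter_min_preterm(m, min_lt34)
  if (apply_mad && is.finite(mad_k)) {
    f2 <- apply_mad_filter(f1$retained, k = mad_k)
    kept <- f2$retained
    mad_removed <- nrow(f2$removed) + nrow(f2$undefined)
    mad_info <- f2$filter
  } else {
    kept <- f1$retained[!is.na(f1$retained$acs34_rate), , drop = FALSE]
    mad_removed <- sum(is.na(f1$retained$acs34_rate))
    mad_info <- NULL
  }
  list(profiles = build_profiles(kept, registry$facilities),
       metrics = kept,
       exclusions = exlog,
       filters = list(min_preterm_removed = nrow(f1$removed),
                      mad_removed = mad_removed, mad = mad_info))
}
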
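#' Ingest an external facility-level table
#'
#' Reads a facility-level aggregate table (one row per facility with annual
#' means) directly, bypassing the patient-level stages, so that published
#' facility-level data can feed [summarize_cohort()],
#' [fit_outcome_model()] and [simulate_population()].  Required columns:
#' `facility_id`, `n_total`, `n_lt34`, `acs34_rate`, `optimal34_rate`,
#' `term_acs_prop`, `acs_all_rate`; factor and attribute columns are used
#' when present.
#'
#' @param path Delimited text file.
#' @param sep Field delimiter (default tab).
#' @return Data frame of facility profiles.
#' @export
read_facility_table <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("facility_id", "n_total", "n_lt34", "acs34_rate",
            "optimal34_rate", "term_acs_prop", "acs_all_rate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("schema error: missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!is.null(d$care_level) && is.null(d$is_comprehensive))
    d$is_comprehensive <- as.integer(d$care_level == "comprehensive")
  d
}

# deterministic permutation of 1..n by a multiplier coprime to n; used to
# pair quantile grids with controlled (near-zero) rank correlation
perm_grid <- function(n, a) (seq_len(n) * a) %% n + 1L

#' Synthetic reconstruction of the deposited facility-level table
#'
#' Builds a deterministic 244-facility profile table calibrated to the
#' published facility-level summaries of the cohort this package models: the
#' four ACS metrics with mean (SD) 63.4 (16.3) / 46.9 (14.5) / 12.0 (9.3) /
#' 6.3 (4.0) percent, the factor summaries (complication
#' prevalences, transfer and cesarean rates among births `<34w`, care-level
#' and city mix), and the population-scenario margins: facilities below an
#' 80\% ACS/34w rate jointly hold 6577 preterm `<34w` births in 123 234
#' deliveries per year and would treat 1211 additional women at the cap.
#'
#' This is a *synthetic stand-in*, not the deposited data: marginal
#' distributions are Gaussian/gamma quantile grids re-centered to the
#' published means, cross-column pairing uses fixed decorrelating
#' permutations, and a single tilt parameter (weighting preterm volume by the
#' ACS/34w rate) is root-found so the scenario margins hold exactly.  Joint
#' structure beyond these calibrated margins is invented.
#'
#' @param n_facilities Number of facilities (default 244; calibration targets
#'   are only guaranteed at the default).
#' @return Data frame of facility profiles (same columns as
#'   [build_profiles()]).
#' @export
synthetic_facility_profiles <- function(n_facilities = 244L) {
  n <- as.integer(n_facilities)
  p <- (seq_len(n) - 0.5) / n
  z <- stats::qnorm(p)
  recenter <- function(x, m) x - mean(x) + m

  gauss <- function(m, s, a, lo = 0.2, hi = 99.8)
    recenter(clamp(m + s * z[perm_grid(n, a)], lo, hi), m)
  gam <- function(m, s, a, lo = 0.05) {
    # gamma with mean m, sd s: shape = (m/s)^2, scale = s^2/m
    recenter(clamp(stats::qgamma(p[perm_grid(n, a)], shape = (m / s)^2,
                                 scale = s^2 / m), lo, Inf), m)
  }

  acs34 <- recenter(clamp(63.4 + 16.3 * z, 0.5, 99.5), 63.4)
  # timing quality tracks coverage closely but not deterministically
  optimal34 <- recenter(clamp(46.9 + (14.1 / 16.3) * (acs34 - 63.4) +
                                3 * z[perm_grid(n, 199L)], 0.5, Inf), 46.9)
  optimal34 <- pmin(optimal34, acs34 - 1)
  term_acs <- gam(12.0, 9.3, 151L)
  acs_all <- gam(6.3, 4.0, 107L)

  # preterm <34w volume: gamma base sizes paired quasi-independently of the
  # rate, then tilted toward high-rate facilities by theta, root-found so the
  # sub-80% facilities hold 6577 preterm births and a +1211 treated delta
  m_base <- pmax(stats::qgamma(p[perm_grid(n, 59L)], shape = (31.7 / 17.6)^2,
                               scale = 17.6^2 / 31.7), 10)
  elig <- acs34 < 80
  target_n34 <- 6577 * n / 244
  target_delta <- 1211 * n / 244
  total_n34 <- 31.7 * n
  # every facility keeps the 10-per-year floor; the excess above it is
  # distributed by base size tilted toward high-rate facilities, theta
  # root-found so the treated delta at the cap comes out at the target
  ne <- sum(elig)
  base_delta <- sum(10 * (80 - acs34[elig]) / 100)
  excess <- target_n34 - 10 * ne
  f <- function(theta) {
    w <- m_base[elig] * exp(theta * (acs34[elig] - 63.4) / 16.3)
    base_delta + sum(excess * w / sum(w) * (80 - acs34[elig]) / 100) -
      target_delta
  }
  theta <- stats::uniroot(f, c(-5, 25), tol = 1e-12)$root
  n_lt34 <- numeric(n)
  w <- m_base[elig] * exp(theta * (acs34[elig] - 63.4) / 16.3)
  n_lt34[elig] <- 10 + excess * w / sum(w)
  n_lt34[!elig] <- 10 + (m_base[!elig] - 10) *
    (total_n34 - target_n34 - 10 * sum(!elig)) / sum(m_base[!elig] - 10)

  # per-facility preterm-<34w prevalence (6.3% +/- 3.8) decouples total
  # volume from preterm volume; group totals rescaled to the published
  # delivery margins (123 234 among sub-80% facilities, 583.2 mean overall)
  p34 <- clamp(stats::qgamma(p[perm_grid(n, 163L)], shape = (6.3 / 3.8)^2,
                             scale = 3.8^2 / 6.3) / 100, 0.012, 0.30)
  n_total <- n_lt34 / p34
  target_N_elig <- 123234 * n / 244
  target_N_all <- 583.2 * n
  n_total[elig] <- n_total[elig] * target_N_elig / sum(n_total[elig])
  n_total[!elig] <- n_total[!elig] * (target_N_all - target_N_elig) /
    sum(n_total[!elig])

  prof <- data.frame(
    facility_id = sprintf("S%03d", seq_len(n)),
    n_years_retained = 3L,
    n_total = n_total,
    n_lt37 = n_total * 0.169,
    n_lt34 = n_lt34,
    n_lt32 = n_lt34 * (18.3 / 31.7),
    n_lt28 = n_lt34 * (7.0 / 31.7),
    n_term = n_total * 0.831,
    acs34_rate = acs34,
    optimal34_rate = optimal34,
    term_acs_prop = term_acs,
    acs_all_rate = acs_all,
    tpl = gauss(48.8, 16.2, 23L),
    hdp = gauss(19.2, 8.1, 37L),
    pprom = gauss(29.3, 11.2, 53L),
    previa = gauss(4.8, 3.6, 71L, lo = 0.1),
    multiple = gauss(11.4, 5.5, 89L, lo = 0.1),
    fgr = gauss(14.3, 7.1, 103L, lo = 0.1),
    abruption = gauss(5.9, 7.1, 127L, lo = 0.1),
    transfer = gauss(49.8, 17.5, 139L),
    cesarean = gauss(73.0, 11.3, 149L),
    stringsAsFactors = FALSE
  )
  # care level tracks volume only loosely (designation weighs staffing and
  # NICU criteria besides size): rank facilities by a noisy volume score
  score <- scale(log(prof$n_total))[, 1L] +
    1.1 * z[perm_grid(n, 181L)]
  ord_vol <- order(score, decreasing = TRUE)
  care <- rep("regional", n)
  care[ord_vol[seq_len(round(n * 104 / 244))]] <- "comprehensive"
  care[ord_vol[seq(n - round(n * 3 / 244) + 1L, n)]] <- "nondesignated"
  prof$care_level <- care
  prof$is_comprehensive <- as.integer(care == "comprehensive")
  prof$in_designated_city <- as.integer(perm_grid(n, 113L) <=
                                          round(n * 90 / 244))
  prof
}
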
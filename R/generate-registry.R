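# Facility-level latent state is drawn first on each facility's own RNG
# stream, so facility f is reproducible regardless of n_facilities and shared
# between the record-level and aggregate generation modes.

facility_seed <- function(cfg, i) {
  as.integer((as.double(cfg$seed) * 10007 + i * 7919) %% 2147483647L) + 1L
}

# truncated lognormal moment-matched to mean/sd, resampled above the floor
r_volume <- function(n, law, lo) {
  m <- law[["mean"]]; s <- law[["sd"]]
  if (s == 0) return(rep(max(m, lo), n))
  sig2 <- log(1 + (s / m)^2)
  mu <- log(m) - sig2 / 2
  v <- stats::rlnorm(n, mu, sqrt(sig2))
  while (any(v < lo)) v[v < lo] <- stats::rlnorm(sum(v < lo), mu, sqrt(sig2))
  v
}

draw_facility_latents <- function(cfg, i) {
  set.seed(facility_seed(cfg, i))
  care <- rcat(1L, cfg$care_level_mix)
  city <- stats::runif(1) < cfg$city_prob
  vol <- r_volume(1L, cfg$volume_law, cfg$volume_min)
  prev <- clamp(stats::rnorm(length(cfg$complication_prevalence),
                             cfg$complication_prevalence,
                             cfg$complication_facility_sd), 0, 0.998)
  names(prev) <- names(cfg$complication_prevalence)
  transfer <- clamp(stats::rnorm(1, cfg$transfer_prob, cfg$transfer_facility_sd), 0, 1)
  cs <- clamp(stats::rnorm(1, cfg$cs_prob, cfg$cs_facility_sd), 0, 1)
  eps <- stats::rnorm(1, 0, cfg$acs_model$facility_sd)

  # facility case-mix: referral centers concentrate preterm deliveries, so
  # the preterm strata are scaled by a lognormal multiplier with mean 1 and
  # CV preterm_dispersion, the term stratum absorbing the difference
  cv <- cfg$preterm_dispersion
  g <- if (cv > 0) {
    sig <- sqrt(log(1 + cv^2))
    clamp(stats::rlnorm(1, -sig^2 / 2, sig), 0.1,
          0.95 / sum(cfg$ga_mix[c("lt28", "w28_31", "w32_33", "w34_36")]))
  } else 1
  ga_mix <- cfg$ga_mix
  ga_mix[c("lt28", "w28_31", "w32_33", "w34_36")] <-
    g * ga_mix[c("lt28", "w28_31", "w32_33", "w34_36")]
  ga_mix[["term"]] <- 1 - sum(ga_mix[c("lt28", "w28_31", "w32_33", "w34_36")])

  # planted linear-probability structure: propensity shifts by slope (pp of
  # ACS/34w rate) per unit deviation of the factor from its configured mean
  p_lt34 <- sum(ga_mix[c("lt28", "w28_31", "w32_33")])
  x <- c(is_comprehensive = as.numeric(care == "comprehensive"),
         in_designated_city = as.numeric(city),
         n_total = vol,
         n_lt34 = vol * p_lt34,
         100 * prev, transfer = 100 * transfer, cesarean = 100 * cs)
  mu <- c(is_comprehensive = cfg$care_level_mix[["comprehensive"]],
          in_designated_city = cfg$city_prob,
          n_total = cfg$volume_law[["mean"]],
          n_lt34 = cfg$volume_law[["mean"]] *
            sum(cfg$ga_mix[c("lt28", "w28_31", "w32_33")]),
          100 * cfg$complication_prevalence,
          transfer = 100 * cfg$transfer_prob, cesarean = 100 * cfg$cs_prob)
  s <- cfg$acs_model$slopes
  shift <- if (length(s)) sum(s * (x[names(s)] - mu[names(s)])) / 100 else 0
  p_acs <- clamp(cfg$acs_model$base_rate + shift + eps, 0, 1)

  # ACS at term reflects anticipated-but-averted preterm birth, so it scales
  # with the facility's preterm case mix; the 34-36w stratum is already
  # case-mix-scaled, so its per-delivery ACS rate is not scaled again
  list(care_level = care, designated_city = city, volume = vol,
       ga_mix = ga_mix, prevalence = prev, transfer = transfer, cs = cs,
       p_acs = p_acs,
       term_acs_rate = clamp(g * cfg$term_acs_rate, 0, 1),
       late_acs_rate = cfg$late_preterm_acs_rate)
}

ga_stratum_days <- function(stratum) {
  lo <- c(lt28 = 154L, w28_31 = 196L, w32_33 = 224L, w34_36 = 238L, term = 259L)
  hi <- c(lt28 = 195L, w28_31 = 223L, w32_33 = 237L, w34_36 = 258L, term = 293L)
  lo[stratum] + floor(stats::runif(length(stratum)) *
                        (hi[stratum] - lo[stratum] + 1L))
}

#' Generate a synthetic patient-level perinatal registry
#'
#' Draws one row per first-born neonate per delivery (optionally also
#' later-born neonates of multiple pregnancies) with gestational age,
#' complication flags, mode of delivery, transfer status, and the three ACS
#' documentation fields (checkbox, total dose, administration-to-delivery
#' interval), together with a facility attributes table.  Facility-level
#' structure (care level, volume, condition prevalences, ACS propensity with
#' an optional planted association) is drawn per facility on an independent
#' RNG stream, so output is deterministic given the configuration and stable
#' per facility when `n_facilities` changes.
#'
#' @param cfg A [registry_config()].
#' @return An object of class `acs_registry`: list with `records` (data frame,
#'   one row per neonate; see [registry_columns()]) and `facilities`
#'   (facility_id, care_level, designated_city).
#' @seealso [generate_facility_year_counts()] for the aggregate mode drawing
#'   facility-year counts from the same law.
#' @export
generate_registry <- function(cfg) {
  validate_registry_config(cfg)
  out <- vector("list", cfg$n_facilities)
  fac <- data.frame(facility_id = sprintf("F%03d", seq_len(cfg$n_facilities)),
                    care_level = NA_character_, designated_city = NA)
  for (i in seq_len(cfg$n_facilities)) {
    lat <- draw_facility_latents(cfg, i)   # also seeds this facility's stream
    fac$care_level[i] <- lat$care_level
    fac$designated_city[i] <- lat$designated_city
    out[[i]] <- generate_facility_records(cfg, fac$facility_id[i], lat)
  }
  structure(list(records = do.call(rbind, out), facilities = fac),
            class = "acs_registry")
}

generate_facility_records <- function(cfg, fid, lat) {
  yrs <- lapply(cfg$years, function(yr) {
    n <- stats::rpois(1L, lat$volume)
    if (n == 0L) return(NULL)
    stratum <- rcat(n, lat$ga_mix)
    ga <- ga_stratum_days(stratum)
    lt34 <- ga < .ga_days[["lt34"]]
    term <- ga >= .ga_days[["lt37"]]

    # complications: multiple pregnancy first, then the rest independently
    prev <- lat$prevalence
    # the configured prevalences are among <34w births; later births carry a
    # proportional background (about one seventh)
    comp <- matrix(0L, n, length(prev), dimnames = list(NULL, names(prev)))
    comp[, "multiple"] <- stats::rbinom(n, 1L,
      ifelse(lt34, prev[["multiple"]], 0.15 * prev[["multiple"]]))
    for (cn in setdiff(names(prev), "multiple"))
      comp[, cn] <- stats::rbinom(n, 1L,
        ifelse(lt34, prev[[cn]], 0.15 * prev[[cn]]))
    n_fetuses <- ifelse(comp[, "multiple"] == 1L,
                        2L + stats::rbinom(n, 1L, 1 - cfg$twin_prob_given_multiple),
                        1L)

    transfer <- stats::rbinom(n, 1L,
      ifelse(lt34, lat$transfer, cfg$term_transfer_prob))
    cs <- stats::rbinom(n, 1L, ifelse(lt34, lat$cs, cfg$term_cs_prob))
    g1 <- cs * stats::rbinom(n, 1L, ifelse(lt34, cfg$grade1_given_cs_lt34,
                                           cfg$grade1_given_cs_other))

    p_acs <- ifelse(lt34, lat$p_acs,
                    ifelse(term, lat$term_acs_rate, lat$late_acs_rate))
    acs <- stats::rbinom(n, 1L, p_acs) == 1L
    dose <- rep(NA_real_, n)
    interval <- rep(NA_character_, n)
    checkbox <- rep(0L, n)
    if (any(acs)) {
      k <- sum(acs)
      dcat <- rcat(k, cfg$dose_mix)
      dose[acs] <- c(d12 = 12, d24 = 24, d36 = 36, d48 = 48, missing = NA)[dcat]
      icat <- character(k)
      pre <- lt34[acs]
      icat[pre] <- rcat(sum(pre), cfg$timing_mix_lt34)
      icat[!pre] <- rcat(sum(!pre), cfg$timing_mix_other)
      # config category names are valid R names; data labels follow the
      # column dictionary
      lab <- c(lt48h = "lt48h", h48_7d = "48h_7d", d7_1mo = "7d_1mo",
               gt1mo = "gt1mo", missing = NA_character_)
      interval[acs] <- lab[icat]
      checkbox[acs] <- stats::rbinom(k, 1L, 1 - cfg$missingness$acs_checkbox)
    }

    still <- rcat(n, c(livebirth = 1 - cfg$stillbirth_known_prob -
                         cfg$unknown_timing_prob,
                       stillbirth_known = cfg$stillbirth_known_prob,
                       unknown_timing = cfg$unknown_timing_prob))

    bw_mu <- clamp(-3328 + 22.6 * ga, 350, 3900)
    rec <- data.frame(
      facility_id = fid, year = yr, ga_days = ga,
      birth_order = 1L, n_fetuses = n_fetuses,
      stillbirth_status = still,
      parity = stats::rpois(n, 0.8),
      infertility_treatment = stats::rbinom(n, 1L, 0.12),
      neonatal_sex = ifelse(stats::runif(n) < 0.515, "M", "F"),
      maternal_age = clamp(round(stats::rnorm(n, 32, 5)), 16, 52),
      birth_weight = round(clamp(stats::rnorm(n, bw_mu, 320), 150, 5200)),
      blood_loss = round(stats::rlnorm(n, log(400), 0.6)),
      maternal_survival = stats::rbinom(n, 1L, 0.9998),
      tpl = comp[, "tpl"], hdp = comp[, "hdp"], pprom = comp[, "pprom"],
      previa = comp[, "previa"], multiple = comp[, "multiple"],
      fgr = comp[, "fgr"], abruption = comp[, "abruption"],
      transfer_in = transfer, cesarean = cs, cesarean_grade1 = g1,
      acs_checkbox = checkbox, acs_dose = dose, acs_interval = interval,
      stringsAsFactors = FALSE
    )

    # blank one mandatory field in a small fraction of rows (entry errors)
    miss <- which(stats::runif(n) < cfg$missingness$mandatory)
    if (length(miss)) {
      fields <- c("parity", "infertility_treatment", "neonatal_sex",
                  "maternal_age", "birth_weight", "blood_loss",
                  "maternal_survival")
      pick <- fields[1L + (miss %% length(fields))]
      for (j in seq_along(miss)) rec[miss[j], pick[j]] <- NA
    }

    if (cfg$emit_later_born) {
      mult <- which(rec$n_fetuses > 1L)
      if (length(mult)) {
        extra <- rec[rep(mult, rec$n_fetuses[mult] - 1L), , drop = FALSE]
        ord <- unlist(lapply(rec$n_fetuses[mult], function(k) 2:k))
        extra$birth_order <- as.integer(ord)
        extra$neonatal_sex <- ifelse(stats::runif(nrow(extra)) < 0.515, "M", "F")
        extra$birth_weight <- round(clamp(
          stats::rnorm(nrow(extra), bw_mu[rep(mult, rec$n_fetuses[mult] - 1L)] - 120,
                       320), 150, 5200))
        rec <- rbind(rec, extra)
      }
    }
    rec
  })
  do.call(rbind, yrs)
}

#' Generate facility-year counts directly (aggregate mode)
#'
#' Draws, for every facility-year, the sufficient statistics the metrics stage
#' would tally from a record-level registry -- delivery counts by
#' gestational-age stratum, complication/transfer/cesarean counts among births
#' `<34w`, ACS recipient counts overall, `<34w`, optimally timed, and at term
#' -- from the same generative law as [generate_registry()] (shared facility
#' latents and RNG streams).  Distributionally equivalent to generating
#' records and calling [compute_facility_year_metrics()], but orders of
#' magnitude faster; used by the replicated parameter-recovery experiments.
#'
#' @param cfg A [registry_config()].
#' @return A list with `metrics` (data frame in the [compute_facility_year_metrics()]
#'   schema) and `facilities`.
#' @export
generate_facility_year_counts <- function(cfg) {
  validate_registry_config(cfg)
  p_opt <- sum(cfg$timing_mix_lt34[c("lt48h", "h48_7d")])
  cols <- c("n_total", "n_lt37", "n_lt34", "n_lt32", "n_lt28", "n_term",
            "n_acs_all", "n_acs_lt34", "n_acs_optimal_lt34", "n_acs_term",
            "n_tpl_lt34", "n_hdp_lt34", "n_pprom_lt34", "n_previa_lt34",
            "n_multiple_lt34", "n_fgr_lt34", "n_abruption_lt34",
            "n_transfer_lt34", "n_cs_lt34")
  ny <- length(cfg$years)
  nf <- cfg$n_facilities
  M <- matrix(0, nf * ny, length(cols), dimnames = list(NULL, cols))
  fac_ids <- sprintf("F%03d", seq_len(nf))
  care <- character(nf); city <- logical(nf)
  for (i in seq_len(nf)) {
    lat <- draw_facility_latents(cfg, i)
    care[i] <- lat$care_level
    city[i] <- lat$designated_city
    n_total <- stats::rpois(ny, lat$volume)
    strat <- vapply(n_total, function(n)
      stats::rmultinom(1L, n, lat$ga_mix)[, 1L],
      numeric(length(lat$ga_mix)))  # strata x ny
    n_lt28 <- strat[1L, ]                 # lt28
    n_lt32 <- n_lt28 + strat[2L, ]        # + w28_31
    n_lt34 <- n_lt32 + strat[3L, ]        # + w32_33
    n_lt37 <- n_lt34 + strat[4L, ]        # + w34_36
    n_term <- strat[5L, ]
    comp <- vapply(names(lat$prevalence), function(cn)
      stats::rbinom(ny, n_lt34, lat$prevalence[[cn]]), numeric(ny))
    comp <- matrix(comp, nrow = ny,
                   dimnames = list(NULL, names(lat$prevalence)))
    acs34 <- stats::rbinom(ny, n_lt34, lat$p_acs)
    acs_late <- stats::rbinom(ny, strat[4L, ], lat$late_acs_rate)
    acs_term <- stats::rbinom(ny, n_term, lat$term_acs_rate)
    M[(i - 1L) * ny + seq_len(ny), ] <- cbind(
      n_total, n_lt37, n_lt34, n_lt32, n_lt28, n_term,
      acs34 + acs_late + acs_term, acs34,
      stats::rbinom(ny, acs34, p_opt), acs_term,
      comp[, c("tpl", "hdp", "pprom", "previa", "multiple", "fgr",
               "abruption"), drop = FALSE],
      stats::rbinom(ny, n_lt34, lat$transfer),
      stats::rbinom(ny, n_lt34, lat$cs))
  }
  m <- data.frame(facility_id = rep(fac_ids, each = ny),
                  year = rep(cfg$years, nf), M,
                  row.names = NULL, stringsAsFactors = FALSE)
  fac <- data.frame(facility_id = fac_ids, care_level = care,
                    designated_city = city, stringsAsFactors = FALSE)
  list(metrics = add_metric_rates(m), facilities = fac)
}

#' @export
print.acs_registry <- function(x, ...) {
  cat(sprintf("Synthetic perinatal registry: %d records, %d facilities, years %s\n",
              nrow(x$records), nrow(x$facilities),
              paste(range(x$records$year), collapse = "-")))
  invisible(x)
}
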
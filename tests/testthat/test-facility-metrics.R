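test_that("facility-year tallies match a direct hand count", {
  # 10 births <34w: 7 recipients, of whom 5 within the 7-day window;
  # plus 2 term births, one an ACS recipient
  rows <- c(
    lapply(1:5, function(i) make_record(ga_days = 230L, acs_checkbox = 1L,
                                        acs_interval = "lt48h",
                                        maternal_age = 20 + i)),
    lapply(1:2, function(i) make_record(ga_days = 225L, acs_checkbox = 1L,
                                        acs_interval = "7d_1mo",
                                        maternal_age = 40 + i)),
    lapply(1:3, function(i) make_record(ga_days = 220L, parity = i)),
    list(make_record(ga_days = 270L, acs_dose = 24),
         make_record(ga_days = 280L)))
  m <- compute_facility_year_metrics(do.call(rbind, rows))
  expect_equal(nrow(m), 1)
  expect_equal(m$n_total, 12)
  expect_equal(m$n_lt34, 10)
  expect_equal(m$n_acs_lt34, 7)
  expect_equal(m$n_acs_optimal_lt34, 5)
  expect_equal(m$acs34_rate, 70)
  expect_equal(m$optimal34_rate, 50)
  expect_equal(m$n_acs_all, 8)
  expect_equal(m$n_acs_term, 1)
  expect_equal(m$term_acs_prop, 100 / 8)
  expect_equal(m$acs_all_rate, 100 * 8 / 12)
})

test_that("zero denominators yield flagged (NA) rates, not zeros", {
  m <- compute_facility_year_metrics(make_records(
    make_record(ga_days = 270L), make_record(ga_days = 280L)))
  expect_equal(m$n_lt34, 0)
  expect_true(is.na(m$acs34_rate))
  expect_true(is.na(m$optimal34_rate))
  expect_true(is.na(m$term_acs_prop))   # no recipients at all
  expect_equal(m$acs_all_rate, 0)       # defined: denominator 2, count 0
})

test_that("tallies equal an independent per-record oracle on generated data", {
  cfg <- small_config(n_facilities = 6L, seed = 404L)
  reg <- generate_registry(cfg)
  r <- apply_exclusions(reg$records)$records
  m <- compute_facility_year_metrics(r)
  # brute force: loop record by record
  acs <- is_acs_recipient(r)
  for (i in seq_len(nrow(m))) {
    sub <- r$facility_id == m$facility_id[i] & r$year == m$year[i]
    expect_equal(m$n_total[i], sum(sub))
    expect_equal(m$n_lt34[i], sum(sub & r$ga_days < 238))
    expect_equal(m$n_lt32[i], sum(sub & r$ga_days < 224))
    expect_equal(m$n_lt28[i], sum(sub & r$ga_days < 196))
    expect_equal(m$n_lt37[i], sum(sub & r$ga_days < 259))
    expect_equal(m$n_term[i], sum(sub & r$ga_days >= 259))
    expect_equal(m$n_acs_lt34[i], sum(sub & acs & r$ga_days < 238))
    expect_equal(m$n_acs_optimal_lt34[i],
                 sum(sub & acs & r$ga_days < 238 &
                       !is.na(r$acs_interval) &
                       r$acs_interval %in% c("lt48h", "48h_7d")))
    expect_equal(m$n_acs_term[i], sum(sub & acs & r$ga_days >= 259))
    expect_equal(m$n_tpl_lt34[i], sum(sub & r$tpl == 1 & r$ga_days < 238))
    expect_equal(m$n_cs_lt34[i], sum(sub & r$cesarean == 1 & r$ga_days < 238))
  }
  # monotone nesting holds in every facility-year
  expect_true(all(m$n_lt28 <= m$n_lt32 & m$n_lt32 <= m$n_lt34 &
                    m$n_lt34 <= m$n_lt37 & m$n_lt37 <= m$n_total))
  expect_true(all(m$n_term == m$n_total - m$n_lt37))
  expect_true(all(m$n_acs_optimal_lt34 <= m$n_acs_lt34))
  expect_true(all(m$n_acs_lt34 <= pmin(m$n_lt34, m$n_acs_all)))
})

test_that("the minimum-preterm filter cuts exactly at the threshold", {
  m <- data.frame(facility_id = c("A", "B", "C"), year = 2020L,
                  n_lt34 = c(9, 10, 25))
  f <- filter_min_preterm(m)
  expect_identical(f$retained$facility_id, c("B", "C"))
  expect_identical(f$removed$facility_id, "A")
  expect_equal(nrow(filter_min_preterm(m, min_lt34 = 0)$removed), 0)
})

test_that("the MAD rule matches hand enumeration", {
  v <- c(60, 62, 64, 66, 10)
  f <- mad_filter(v)
  expect_equal(f$center, 62)
  expect_equal(f$mad, 2)
  expect_equal(f$threshold, 5)
  expect_equal(f$excluded, 5L)
  expect_equal(f$kept, 1:4)

  # constant vector: mad 0, nothing excluded
  f0 <- mad_filter(rep(50, 6))
  expect_equal(f0$mad, 0)
  expect_length(f0$excluded, 0)
  # mad 0 with one deviant value: only the deviant is excluded
  f1 <- mad_filter(c(50, 50, 50, 50, 51))
  expect_equal(f1$excluded, 5L)

  # k large: nothing excluded
  expect_length(mad_filter(v, k = 1e9)$excluded, 0)
  # one-sided variant only drops the low tail
  expect_equal(mad_filter(c(60, 62, 64, 66, 10, 99), side = "lower")$excluded, 5L)
  expect_error(mad_filter(numeric(0)), "empty")
})

test_that("the MAD rule is translation- and scale-equivariant", {
  set.seed(8)
  for (rep in 1:20) {
    x <- stats::rnorm(40, 60, 15)
    a <- stats::runif(1, 0.2, 5) * sample(c(-1, 1), 1)
    b <- stats::runif(1, -30, 30)
    f0 <- mad_filter(x)
    f1 <- mad_filter(a * x + b)
    expect_identical(f1$excluded, f0$excluded)
  }
})

test_that("profiles are unweighted annual means with NA-aware denominators", {
  m <- rbind(
    data.frame(facility_id = "A", year = 2020L, n_total = 100, n_lt37 = 20,
               n_lt34 = 10, n_lt32 = 6, n_lt28 = 2, n_term = 80,
               acs34_rate = 60, optimal34_rate = 40, term_acs_prop = NA,
               acs_all_rate = 6, tpl = 50, hdp = 20, pprom = 30, previa = 5,
               multiple = 10, fgr = 15, abruption = 5, transfer = 50,
               cesarean = 70),
    data.frame(facility_id = "A", year = 2021L, n_total = 200, n_lt37 = 30,
               n_lt34 = 20, n_lt32 = 10, n_lt28 = 4, n_term = 170,
               acs34_rate = 70, optimal34_rate = 50, term_acs_prop = 12,
               acs_all_rate = 8, tpl = 40, hdp = 25, pprom = 20, previa = 4,
               multiple = 12, fgr = 10, abruption = 6, transfer = 40,
               cesarean = 60))
  fac <- data.frame(facility_id = "A", care_level = "comprehensive",
                    designated_city = TRUE)
  p <- build_profiles(m, fac)
  expect_equal(p$acs34_rate, 65)          # (60 + 70) / 2, unweighted
  expect_equal(p$n_total, 150)
  expect_equal(p$term_acs_prop, 12)       # undefined year dropped from mean
  expect_equal(p$n_years_retained, 2L)
  expect_equal(p$is_comprehensive, 1L)
  # single retained year: profile equals that year
  p1 <- build_profiles(m[1, ], fac)
  expect_equal(p1$acs34_rate, 60)
  expect_equal(p1$n_total, 100)
})

test_that("profile means match a brute-force oracle on generated data", {
  cfg <- small_config(n_facilities = 10L, years = 2020:2022, seed = 55L)
  gen <- generate_facility_year_counts(cfg)
  kept <- filter_min_preterm(gen$metrics)$retained
  p <- build_profiles(kept, gen$facilities)
  for (i in seq_len(nrow(p))) {
    sub <- kept[kept$facility_id == p$facility_id[i], ]
    expect_equal(p$acs34_rate[i], mean(sub$acs34_rate, na.rm = TRUE))
    expect_equal(p$tpl[i], mean(sub$tpl, na.rm = TRUE))
    expect_equal(p$n_lt34[i], mean(sub$n_lt34))
    expect_true(p$acs34_rate[i] >= min(sub$acs34_rate, na.rm = TRUE) - 1e-12)
    expect_true(p$acs34_rate[i] <= max(sub$acs34_rate, na.rm = TRUE) + 1e-12)
  }
})

test_that("cohort summary reports sample SDs and per-item denominators", {
  prof <- build_profiles(
    rbind(
      data.frame(facility_id = "A", year = 2020L, n_total = 100, n_lt37 = 20,
                 n_lt34 = 10, n_lt32 = 5, n_lt28 = 1, n_term = 80,
                 acs34_rate = 50, optimal34_rate = 30, term_acs_prop = 10,
                 acs_all_rate = 5, tpl = 50, hdp = 20, pprom = 30, previa = 5,
                 multiple = 10, fgr = 15, abruption = 5, transfer = 50,
                 cesarean = 70),
      data.frame(facility_id = "B", year = 2020L, n_total = 300, n_lt37 = 40,
                 n_lt34 = 30, n_lt32 = 15, n_lt28 = 3, n_term = 260,
                 acs34_rate = 70, optimal34_rate = 55, term_acs_prop = NA,
                 acs_all_rate = 7, tpl = 45, hdp = 22, pprom = 28, previa = 6,
                 multiple = 11, fgr = 14, abruption = 4, transfer = 45,
                 cesarean = 65)),
    data.frame(facility_id = c("A", "B"),
               care_level = c("comprehensive", "regional"),
               designated_city = c(TRUE, FALSE)))
  s <- summarize_cohort(prof)
  row <- s[s$item == "acs34_rate", ]
  expect_equal(row$mean, 60)
  expect_equal(row$sd, stats::sd(c(50, 70)))   # 14.142...
  expect_equal(row$sd, 14.14, tolerance = 1e-3)
  # the undefined term/ACS proportion drops facility B from that row only
  expect_equal(s$n_facilities[s$item == "term_acs_prop"], 1)
  expect_equal(s$n_facilities[s$item == "acs34_rate"], 2)
  expect_equal(s$mean[s$item == "comprehensive"], 50)
})

test_that("the full pipeline recovers configured cohort means on synthetic data", {
  cfg <- registry_config(n_facilities = 150L, seed = 2024L)
  gen <- generate_facility_year_counts(cfg)
  co <- build_cohort(gen, apply_mad = FALSE)
  s <- summarize_cohort(co$profiles)
  get <- function(item) s$mean[s$item == item]
  se <- stats::sd(co$profiles$acs34_rate) / sqrt(nrow(co$profiles))
  expect_lt(abs(get("acs34_rate") - 63.4), 2 * se + 0.3)
  expect_lt(abs(get("optimal34_rate") - 46.9), 2.5)
  expect_lt(abs(get("term_acs_prop") - 12.0), 1.5)
  expect_lt(abs(get("acs_all_rate") - 6.3), 0.8)

  # the MAD outlier trim cuts the skewed lower tail harder than the upper,
  # so the filtered mean sits slightly above the configured truth
  co_mad <- build_cohort(gen, apply_mad = TRUE)
  s2 <- summarize_cohort(co_mad$profiles)
  expect_lt(abs(s2$mean[s2$item == "acs34_rate"] - 63.4), 4)
})
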
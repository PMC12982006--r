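# small synthetic cohort reused across model tests
model_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- registry_config(n_facilities = 120L, seed = 314L)
      gen <- generate_facility_year_counts(cfg)
      cache <<- build_profiles(filter_min_preterm(gen$metrics)$retained,
                               gen$facilities)
    }
    cache
  }
})

test_that("standardization maps continuous columns to mean 0 / SD 1, binaries untouched", {
  prof <- model_cohort()
  sdz <- standardize_design(prof, "acs34_rate")
  bin <- colnames(sdz$X) %in% c("is_comprehensive", "in_designated_city")
  expect_equal(unname(colMeans(sdz$X[, !bin])), rep(0, sum(!bin)),
               tolerance = 1e-12)
  expect_equal(unname(apply(sdz$X[, !bin], 2, stats::sd)), rep(1, sum(!bin)),
               tolerance = 1e-12)
  expect_true(all(sdz$X[, bin] %in% c(0, 1)))
  # closed form: (1, 2, 3) -> (-1, 0, 1)
  expect_equal(as.numeric(scale(c(1, 2, 3))), c(-1, 0, 1))

  # zero-SD covariate is refused by name
  prof2 <- prof
  prof2$previa <- 5
  expect_error(standardize_design(prof2, "acs34_rate"), "previa")
})

test_that("OLS matches a normal-equations oracle on random small designs", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(15:50, 1)
    p <- sample(2:6, 1)
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    y <- stats::rnorm(n)
    d <- data.frame(.y = y, X)
    fit <- stats::lm(.y ~ ., data = d)
    Xi <- cbind(1, X)
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)   # independent oracle
    expect_lt(max(abs(stats::coef(fit) - as.numeric(beta))), 1e-8)
  }
})

test_that("a noiseless linear outcome is fitted exactly with zero-width CIs", {
  prof <- model_cohort()
  prof$acs34_rate <- 40 + 7 * prof$is_comprehensive +
    0.5 * prof$tpl - 0.2 * prof$cesarean
  fit <- suppressWarnings(fit_outcome_model(prof, "acs34_rate"))
  tab <- fit$coefficients
  expect_equal(tab$raw_estimate[tab$term == "is_comprehensive"], 7,
               tolerance = 1e-8)
  expect_equal(tab$raw_estimate[tab$term == "tpl"], 0.5, tolerance = 1e-8)
  expect_equal(tab$raw_estimate[tab$term == "previa"], 0, tolerance = 1e-8)
  expect_lt(max(tab$ci_hi - tab$ci_lo), 1e-6)
  expect_lt(fit$sigma, 1e-8)
})

test_that("VIFs match the regress-each-column and closed-form oracles", {
  set.seed(4)
  X <- matrix(stats::rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  v <- compute_vif(X)
  # oracle: regress each column on the others
  for (j in 1:3) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(v[[j]], 1 / (1 - r2), tolerance = 1e-10)
  }
  expect_true(all(v >= 1))

  # two correlated columns: VIF = 1 / (1 - r^2) exactly
  z <- stats::rnorm(200)
  X2 <- cbind(x1 = z, x2 = 0.8 * z + sqrt(1 - 0.64) * stats::rnorm(200))
  r <- stats::cor(X2[, 1], X2[, 2])
  expect_equal(unname(compute_vif(X2)), rep(1 / (1 - r^2), 2),
               tolerance = 1e-10)

  # exactly uncorrelated columns: VIF 1
  u <- stats::rnorm(20)
  v <- stats::residuals(stats::lm(stats::rnorm(20) ~ u))
  U <- cbind(u = u - mean(u), v = v)
  expect_equal(unname(compute_vif(U)), c(1, 1), tolerance = 1e-8)

  # perfect collinearity reported as infinite
  X3 <- cbind(x = z, y = 2 * z)
  expect_true(all(!is.finite(compute_vif(X3))))
})

test_that("de-standardized coefficients reproduce a raw-scale fit", {
  prof <- model_cohort()
  fit_std <- fit_outcome_model(prof, "term_acs_prop", standardize = TRUE)
  fit_raw <- fit_outcome_model(prof, "term_acs_prop", standardize = FALSE)
  expect_equal(destandardize(fit_std),
               stats::setNames(fit_raw$coefficients$estimate,
                               fit_raw$coefficients$term),
               tolerance = 1e-10)
  # identity: std coef = raw coef * sd, to tight tolerance
  cont <- !is.na(fit_std$sds)
  expect_equal(fit_std$coefficients$estimate[cont],
               fit_std$coefficients$raw_estimate[cont] * fit_std$sds[cont],
               tolerance = 1e-10, ignore_attr = TRUE)
  # worked conversion: 11.5 pp per SD at SD 16.3 pp -> 0.7055 pp per pp
  expect_equal(round(11.5 / 16.3, 4), 0.7055)
})

test_that("standardized coefficients are invariant to covariate rescaling", {
  prof <- model_cohort()
  fit1 <- fit_outcome_model(prof, "acs34_rate")
  prof2 <- prof
  prof2$n_total <- prof2$n_total / 100    # deliveries in hundreds
  fit2 <- fit_outcome_model(prof2, "acs34_rate")
  expect_equal(fit2$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(fit2$coefficients$ci_lo, fit1$coefficients$ci_lo,
               tolerance = 1e-10)
  # raw coefficient rescales by the same factor
  i <- which(fit1$coefficients$term == "n_total")
  expect_equal(fit2$coefficients$raw_estimate[i],
               100 * fit1$coefficients$raw_estimate[i], tolerance = 1e-10)
})

test_that("the four-model suite has the specified covariate sets and sane VIFs", {
  suite <- run_analysis_suite(profiles = model_cohort())
  expect_named(suite$fits, c("acs34_rate", "term_acs_prop", "optimal34_rate",
                             "acs_all_rate"))
  expect_equal(nrow(suite$fits$acs34_rate$coefficients), 13)
  for (oc in c("term_acs_prop", "optimal34_rate", "acs_all_rate")) {
    expect_equal(nrow(suite$fits[[oc]]$coefficients), 14)
    expect_true("acs34_rate" %in% suite$fits[[oc]]$coefficients$term)
  }
  expect_false("acs34_rate" %in% suite$fits$acs34_rate$coefficients$term)
  expect_true(all(is.finite(forest_table(suite)$vif)))
  expect_true(all(forest_table(suite)$vif < 3))
})

test_that("a sensitivity run on a cohort without abruption or Grade-1 cesareans equals the main run", {
  cfg <- small_config(n_facilities = 20L, seed = 606L,
                      complication_prevalence = c(tpl = 0.488, hdp = 0.192,
                                                  pprom = 0.293, previa = 0.048,
                                                  multiple = 0.114, fgr = 0.143,
                                                  abruption = 0),
                      complication_facility_sd = c(tpl = 0.154, hdp = 0.070,
                                                   pprom = 0.102, previa = 0.028,
                                                   multiple = 0.044, fgr = 0.061,
                                                   abruption = 0),
                      grade1_given_cs_lt34 = 0, grade1_given_cs_other = 0)
  reg <- generate_registry(cfg)
  expect_true(all(reg$records$abruption == 0))
  expect_true(all(reg$records$cesarean_grade1 == 0))
  co_main <- build_cohort(reg, apply_mad = FALSE)
  reg_sens <- structure(list(records = sensitivity_subset(reg$records),
                             facilities = reg$facilities),
                        class = "acs_registry")
  co_sens <- build_cohort(reg_sens, apply_mad = FALSE)
  expect_equal(co_sens$profiles, co_main$profiles)
})

test_that("a planted TPL association is recovered in sign and significance", {
  rec <- recovery_experiment("tpl", 0.35, n_reps = 100, seed = 11)
  expect_gte(attr(rec, "sign_rate"), 0.95)
  expect_gte(mean(rec$significant), 0.90)
})
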
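# covariate list shared by the four outcome models; the ACS/34w rate joins as
# a covariate in every model where it is not the outcome
outcome_names <- function() {
  c("acs34_rate", "term_acs_prop", "optimal34_rate", "acs_all_rate")
}

model_covariates <- function(outcome) {
  base <- c("is_comprehensive", "in_designated_city", "n_total", "n_lt34",
            "tpl", "hdp", "pprom", "previa", "multiple", "fgr", "abruption",
            "transfer", "cesarean")
  if (outcome == "acs34_rate") base else c(base, "acs34_rate")
}

binary_covariates <- function() c("is_comprehensive", "in_designated_city")

#' Standardize the design for a facility-level outcome model
#'
#' Centers and scales every continuous covariate to sample mean 0 and SD 1;
#' binary covariates stay on their 0/1 scale so their coefficients read as a
#' level switch.  The outcome is left in its natural units (percentage
#' points), so standardized coefficients are percentage points of outcome per
#' 1 SD of covariate.
#'
#' @param profiles Facility profiles (see [build_profiles()]).
#' @param outcome One of `acs34_rate`, `term_acs_prop`, `optimal34_rate`,
#'   `acs_all_rate`.
#' @param standardize Scale continuous covariates? (default `TRUE`)
#' @return List with `y`, `X` (matrix, no intercept column), `means`, `sds`
#'   (named over covariates; `NA` for binaries), and `complete` (row filter
#'   applied).
#' @export
standardize_design <- function(profiles, outcome = outcome_names(),
                               standardize = TRUE) {
  outcome <- match.arg(outcome)
  covs <- model_covariates(outcome)
  d <- profiles[c(outcome, covs)]
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]
  if (nrow(d) < length(covs) + 2L)
    stop(sprintf("need at least %d complete profiles, got %d",
                 length(covs) + 2L, nrow(d)), call. = FALSE)
  X <- as.matrix(d[covs])
  means <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  bin <- colnames(X) %in% binary_covariates()
  if (standardize) {
    zero <- !bin & sds == 0
    if (any(zero))
      stop(sprintf("zero-SD covariate(s): %s",
                   paste(colnames(X)[zero], collapse = ", ")), call. = FALSE)
    X[, !bin] <- sweep(sweep(X[, !bin, drop = FALSE], 2L, means[!bin]),
                       2L, sds[!bin], "/")
  }
  means[bin] <- NA_real_
  sds[bin] <- NA_real_
  list(y = d[[outcome]], X = X, means = means, sds = sds, complete = ok)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, the diagonal of the inverse correlation matrix of
#' the covariates (intercept excluded).  Perfect collinearity yields `Inf`.
#'
#' @param X Covariate matrix (no intercept column).
#' @return Named numeric vector of VIFs (all `>= 1` for a full-rank design).
#' @export
compute_vif <- function(X) {
  R <- stats::cor(X)
  v <- tryCatch(diag(solve(R)), error = function(e) rep(Inf, ncol(X)))
  if (any(!is.finite(v)) || any(v < 0)) v <- rep(Inf, ncol(X))
  stats::setNames(as.numeric(v), colnames(X))
}

#' Fit a standardized facility-level outcome model
#'
#' Ordinary least squares of one ACS metric on the facility-level factors
#' (and, for the three non-coverage outcomes, the ACS/34w rate), with
#' continuous covariates standardized.  Confidence intervals are classical
#' t-based at the given level; a covariate is flagged significant when its
#' interval excludes zero.  De-standardized (per-natural-unit) coefficients
#' are carried alongside: `raw = estimate / sd(covariate)` for continuous
#' covariates, unchanged for binaries.
#'
#' @param profiles Facility profiles.
#' @param outcome Outcome metric name.
#' @param standardize Standardize continuous covariates? (default `TRUE`)
#' @param level Confidence level (default 0.95).
#' @return Object of class `acs_model` with components `coefficients` (table:
#'   `term`, `estimate`, `ci_lo`, `ci_hi`, `raw_estimate`, `vif`,
#'   `significant`), `outcome`, `n`, `sigma` (residual SD), `df_residual`,
#'   `means`, `sds`, `level`, and the underlying `lm` fit.  Methods:
#'   `print`, `summary`, `coef`, `confint`, `predict`, `residuals`,
#'   `fitted`, `simulate`, `plot` (forest plot).
#' @examples
#' cfg <- registry_config(n_facilities = 60, years = 2020:2021, seed = 7)
#' gen <- generate_facility_year_counts(cfg)
#' prof <- build_profiles(filter_min_preterm(gen$metrics)$retained,
#'                        gen$facilities)
#' fit <- fit_outcome_model(prof, "acs34_rate")
#' coef(fit)["tpl"]
#' @export
fit_outcome_model <- function(profiles, outcome = outcome_names(),
                              standardize = TRUE, level = 0.95) {
  outcome <- match.arg(outcome)
  sdz <- standardize_design(profiles, outcome, standardize = standardize)
  qrX <- qr(cbind(1, sdz$X))
  if (qrX$rank < ncol(sdz$X) + 1L) {
    drop <- colnames(sdz$X)[setdiff(seq_len(ncol(sdz$X)) + 1L,
                                    qrX$pivot[seq_len(qrX$rank)]) - 1L]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(drop, collapse = ", ")), call. = FALSE)
  }
  d <- data.frame(.y = sdz$y, sdz$X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = d)
  est <- stats::coef(fit)[colnames(sdz$X)]
  ci <- stats::confint(fit, level = level)[colnames(sdz$X), , drop = FALSE]
  vif <- compute_vif(sdz$X)
  raw <- ifelse(is.na(sdz$sds), est, est / sdz$sds)
  tab <- data.frame(term = colnames(sdz$X), estimate = as.numeric(est),
                    ci_lo = ci[, 1L], ci_hi = ci[, 2L],
                    raw_estimate = as.numeric(raw), vif = as.numeric(vif),
                    significant = ci[, 1L] > 0 | ci[, 2L] < 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab, outcome = outcome, n = length(sdz$y),
                 sigma = summary(fit)$sigma,
                 df_residual = fit$df.residual,
                 means = sdz$means, sds = sdz$sds, level = level,
                 standardized = standardize, lm = fit),
            class = "acs_model")
}

#' De-standardized coefficients of a fitted outcome model
#'
#' Converts coefficients from percentage points of outcome per 1 SD of
#' covariate to per natural unit (`estimate / sd`); binary covariates are
#' returned unchanged.
#'
#' @param fit An `acs_model` fitted with `standardize = TRUE`.
#' @return Named numeric vector of per-unit slopes.
#' @export
destandardize <- function(fit) {
  stopifnot(inherits(fit, "acs_model"))
  if (!fit$standardized)
    stop("model was fitted without standardization", call. = FALSE)
  stats::setNames(fit$coefficients$raw_estimate, fit$coefficients$term)
}

#' @export
coef.acs_model <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.acs_model <- function(object, parm, level, ...) {
  ci <- as.matrix(object$coefficients[c("ci_lo", "ci_hi")])
  rownames(ci) <- object$coefficients$term
  a <- (1 - object$level) / 2
  colnames(ci) <- sprintf("%.1f %%", 100 * c(a, 1 - a))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.acs_model <- function(object, ...) stats::residuals(object$lm)

#' @export
fitted.acs_model <- function(object, ...) stats::fitted(object$lm)

#' @export
predict.acs_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  X <- as.matrix(newdata[, object$coefficients$term, drop = FALSE])
  bin <- is.na(object$sds)
  X[, !bin] <- sweep(sweep(X[, !bin, drop = FALSE], 2L, object$means[!bin]),
                     2L, object$sds[!bin], "/")
  stats::predict(object$lm, newdata = as.data.frame(X))
}

#' @export
simulate.acs_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::fitted(object$lm)
  as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma)))
}

#' @export
print.acs_model <- function(x, digits = 2, ...) {
  cat(sprintf("Facility-level model: %s ~ %d facility factors (n = %d)\n",
              x$outcome, nrow(x$coefficients), x$n))
  cat(sprintf("Standardized OLS, %.0f%% t-based CIs, residual SD %.2f pp\n",
              100 * x$level, x$sigma))
  tab <- x$coefficients
  cat(sprintf("%-20s %8s  [%7s, %7s]  %5s %s\n",
              "term", "coef", "lo", "hi", "VIF", ""))
  for (i in seq_len(nrow(tab)))
    cat(sprintf("%-20s %8.*f  [%7.*f, %7.*f]  %5.2f %s\n",
                tab$term[i], digits, tab$estimate[i], digits, tab$ci_lo[i],
                digits, tab$ci_hi[i], tab$vif[i],
                if (tab$significant[i]) "*" else ""))
  invisible(x)
}

#' @export
summary.acs_model <- function(object, ...) {
  out <- object$coefficients
  out$se <- (out$ci_hi - out$ci_lo) /
    (2 * stats::qt(1 - (1 - object$level) / 2, object$df_residual))
  attr(out, "outcome") <- object$outcome
  attr(out, "n") <- object$n
  out
}

#' @export
plot.acs_model <- function(x, ...) {
  tab <- x$coefficients[rev(seq_len(nrow(x$coefficients))), ]
  k <- nrow(tab)
  rng <- range(0, tab$ci_lo, tab$ci_hi)
  old <- graphics::par(mar = c(4, 11, 3, 1))
  on.exit(graphics::par(old))
  plot(tab$estimate, seq_len(k), xlim = rng, ylim = c(0.5, k + 0.5),
       pch = 15, yaxt = "n", xlab = "coefficient (pp of outcome per SD)",
       ylab = "", main = sprintf("Outcome: %s", x$outcome),
       col = ifelse(tab$significant, "firebrick", "grey30"), ...)
  graphics::segments(tab$ci_lo, seq_len(k), tab$ci_hi, seq_len(k),
                     col = ifelse(tab$significant, "firebrick", "grey30"))
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(k), labels = tab$term, las = 1, cex.axis = 0.8)
  invisible(x)
}

#' Fit the four outcome models
#'
#' Fits the standardized model for each of the four ACS metrics on a shared
#' covariate ordering.  With `sensitivity = TRUE` the whole pipeline is
#' recomputed from [sensitivity_subset()] records (metrics and profiles are
#' rebuilt, not merely refitted).  Warns when any VIF reaches 3.
#'
#' @param registry An `acs_registry` (records + facilities); required in
#'   record form for sensitivity runs.  Alternatively pass `profiles` directly.
#' @param profiles Prebuilt facility profiles (skips cohort construction).
#' @param sensitivity Rerun on the sensitivity subset?
#' @param min_lt34,mad_k,apply_mad Passed to [build_cohort()].
#' @param level Confidence level.
#' @return Object of class `acs_model_suite`: list of four `acs_model` fits
#'   (named by outcome), `profiles`, and `sensitivity` flag.
#' @export
run_analysis_suite <- function(registry = NULL, profiles = NULL,
                               sensitivity = FALSE, min_lt34 = 10,
                               mad_k = 2.5, apply_mad = TRUE, level = 0.95) {
  if (is.null(profiles)) {
    stopifnot(!is.null(registry))
    if (sensitivity && is.null(registry$records))
      stop("sensitivity runs need patient-level records", call. = FALSE)
    if (sensitivity)
      registry <- structure(list(records = sensitivity_subset(registry$records),
                                 facilities = registry$facilities),
                            class = "acs_registry")
    cohort <- build_cohort(registry, min_lt34 = min_lt34, mad_k = mad_k,
                           apply_mad = apply_mad)
    profiles <- cohort$profiles
  } else if (sensitivity) {
    stop("sensitivity runs need patient-level records, not prebuilt profiles",
         call. = FALSE)
  }
  fits <- lapply(outcome_names(), function(oc)
    fit_outcome_model(profiles, oc, level = level))
  names(fits) <- outcome_names()
  vmax <- max(unlist(lapply(fits, function(f) f$coefficients$vif)))
  if (vmax >= 3)
    warning(sprintf("multicollinearity: maximum VIF %.2f >= 3", vmax),
            call. = FALSE)
  structure(list(fits = fits, profiles = profiles, sensitivity = sensitivity),
            class = "acs_model_suite")
}

#' @export
print.acs_model_suite <- function(x, ...) {
  cat(sprintf("Facility-level association models (%d facilities%s)\n",
              nrow(x$profiles),
              if (x$sensitivity) ", sensitivity subset" else ""))
  for (f in x$fits) {
    sig <- f$coefficients[f$coefficients$significant, ]
    cat(sprintf("- %s: %s\n", f$outcome,
                if (nrow(sig) == 0) "no significant factors" else
                  paste(sprintf("%s %+.1f [%.1f, %.1f]", sig$term,
                                sig$estimate, sig$ci_lo, sig$ci_hi),
                        collapse = "; ")))
  }
  invisible(x)
}

#' Forest-plot table for a model suite
#'
#' One row per outcome x covariate: standardized coefficient with CI, raw
#' (per-unit) coefficient, VIF and significance flag -- the machine-readable
#' companion of the forest plots.
#'
#' @param suite An `acs_model_suite`.
#' @return Data frame.
#' @export
forest_table <- function(suite) {
  stopifnot(inherits(suite, "acs_model_suite"))
  do.call(rbind, lapply(suite$fits, function(f)
    data.frame(outcome = f$outcome, f$coefficients, row.names = NULL)))
}

#' Replicated parameter-recovery experiment
#'
#' Plants a single facility-level slope in the generator, repeatedly draws a
#' cohort (aggregate mode), runs the cohort pipeline (exclusion-equivalent
#' counts, minimum-preterm filter; the MAD outlier filter is off by default
#' -- on artifact-free synthetic data it truncates the outcome and attenuates
#' coefficients, see the methods vignette) and fits the ACS/34w-rate model,
#' recording the planted factor's estimate and CI in each replicate.
#'
#' @param factor Name of the facility-level factor to plant on.
#' @param slope Planted slope (pp of ACS/34w propensity per unit of factor).
#' @param n_reps Number of replicates.
#' @param cfg Base configuration (defaults to study conditions).
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param apply_mad Apply the MAD outlier filter inside each replicate?
#' @return Data frame (one row per replicate: `estimate`, `ci_lo`, `ci_hi`,
#'   `significant`, `n`) with attributes `truth`, `bias`, `coverage`,
#'   `sign_rate`.
#' @export
recovery_experiment <- function(factor, slope, n_reps = 200,
                                cfg = registry_config(), seed = 1,
                                apply_mad = FALSE) {
  stopifnot(factor %in% factor_names())
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$acs_model$slopes <- stats::setNames(slope, factor)
    cfg_r$seed <- as.integer((seed + r) %% .Machine$integer.max)
    gen <- generate_facility_year_counts(cfg_r)
    f1 <- filter_min_preterm(gen$metrics)
    kept <- if (apply_mad) apply_mad_filter(f1$retained)$retained else
      f1$retained[!is.na(f1$retained$acs34_rate), , drop = FALSE]
    prof <- build_profiles(kept, gen$facilities)
    fit <- fit_outcome_model(prof, "acs34_rate")
    i <- match(factor, fit$coefficients$term)
    rows[[r]] <- data.frame(estimate = fit$coefficients$estimate[i],
                            raw_estimate = fit$coefficients$raw_estimate[i],
                            ci_lo = fit$coefficients$ci_lo[i],
                            ci_hi = fit$coefficients$ci_hi[i],
                            significant = fit$coefficients$significant[i],
                            n = fit$n)
  }
  out <- do.call(rbind, rows)
  # truth on the scale the model reports: binary factors report a level
  # switch; continuous factors report pp per SD, so scale by the covariate SD
  is_bin <- factor %in% binary_covariates()
  attr(out, "truth_per_unit") <- slope
  attr(out, "bias_raw") <- mean(out$raw_estimate) - slope
  if (is_bin) {
    attr(out, "coverage") <- mean(out$ci_lo <= slope & slope <= out$ci_hi)
  } else {
    # CIs live on the standardized (per-SD) scale; rescale each replicate's
    # bounds to per-unit using that replicate's own covariate SD
    sc <- out$raw_estimate / out$estimate
    attr(out, "coverage") <- mean(out$ci_lo * sc <= slope &
                                    slope <= out$ci_hi * sc)
  }
  attr(out, "sign_rate") <- mean(sign(out$estimate) == sign(slope))
  out
}
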
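# Gestational-age stratum boundaries in completed days.
# "< 34 weeks" means strictly before 34+0 (238 days); "term" is >= 37+0 (259 days).
.ga_days <- c(lt28 = 196L, lt32 = 224L, lt34 = 238L, lt37 = 259L)

#' Gestational-age stratum cut points (days)
#'
#' Boundaries used throughout the package: `<28w` = `<196` days,
#' `<32w` = `<224`, `<34w` = `<238`, `<37w` = `<259`; term is `>= 259` days
#' (37+0 weeks).
#'
#' @return Named integer vector of day cut points.
#' @export
ga_cutpoints <- function() .ga_days

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample from a categorical distribution, vectorized
rcat <- function(n, prob) {
  stopifnot(!is.null(names(prob)))
  names(prob)[1L + findInterval(stats::runif(n), cumsum(prob) / sum(prob),
                                rightmost.closed = TRUE)]
}

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in `%s`: %s", field, msg), call. = FALSE)
}

check_prob_vector <- function(p, field, tol = 1e-9) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_config(field, "probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > tol)
    stop_config(field, sprintf("probabilities must sum to 1 (got %.12f)", sum(p)))
  invisible(p)
}
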
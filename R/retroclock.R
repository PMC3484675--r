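#' Substitution-rate model with an uncertainty interval
#'
#' Rates are in substitutions fixed per site per year. Published
#' retropseudogene rates span roughly 0.5e-9 to 1.35e-9 depending on
#' assumptions about ancestral effective population size and the
#' hominin-panin divergence time; 1.25e-9 is the conventional point value.
#'
#' @param point Point rate.
#' @param low,high Interval bounds (default to `point`).
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(point = 1.25e-9, low = point, high = point) {
  if (!(0 < low && low <= point && point <= high))
    stop("rate model requires 0 < low <= point <= high")
  structure(list(point = point, low = low, high = high),
            class = "rate_model")
}

#' Molecular-clock point age
#'
#' Age in years of a neutrally evolving retrocopy showing `k` fixed
#' substitutions over `L` compared sites: `k / (L * rate)`. An optional
#' Jukes-Cantor correction (`-3/4 log(1 - 4d/3)` with `d = k/L`) is
#' available for larger divergences; at the divergences this package
#' targets (d ~ 0.001) the correction is negligible and the default is
#' the uncorrected linear form.
#'
#' @param k Fixed differences (integer >= 0).
#' @param L Compared sites (> 0).
#' @param rate Substitutions per site per year (> 0).
#' @param correction `"none"` (default) or `"jc69"`.
#' @return Age in years.
#' @examples
#' estimate_age(2, 1622, 1.25e-9)   # ~0.99 million years
#' @export
estimate_age <- function(k, L, rate, correction = c("none", "jc69")) {
  correction <- match.arg(correction)
  if (L <= 0) stop("input error: L must be positive")
  if (rate <= 0) stop("input error: rate must be positive")
  if (k < 0) stop("input error: k must be non-negative")
  d <- k / L
  if (correction == "jc69") {
    if (d >= 0.75) stop("divergence too large for JC69 correction")
    d <- -0.75 * log(1 - 4 * d / 3)
  }
  d / rate
}

#' Molecular-clock age with a rate interval
#'
#' The younger bound uses the fastest rate, the older bound the slowest:
#' `age_low = k/(L*high)`, `age_high = k/(L*low)`.
#'
#' @inheritParams estimate_age
#' @param rate A `rate_model`.
#' @return An object of class `age_estimate` with `k`, `L`, `point_age`,
#'   `age_low`, `age_high` (years).
#' @examples
#' age_interval(2, 1622, rate_model(1.25e-9, 0.5e-9, 1.35e-9))
#' @export
age_interval <- function(k, L, rate, correction = c("none", "jc69")) {
  stopifnot(inherits(rate, "rate_model"))
  correction <- match.arg(correction)
  est <- structure(list(
    k = as.integer(k), L = as.integer(L),
    point_age = estimate_age(k, L, rate$point, correction),
    age_low = estimate_age(k, L, rate$high, correction),
    age_high = estimate_age(k, L, rate$low, correction)),
    class = "age_estimate")
  stopifnot(est$age_low <= est$point_age, est$point_age <= est$age_high)
  est
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf(
    "<age_estimate> k=%d over L=%d sites: %s My (interval %s-%s My)\n",
    x$k, x$L, format_age_my(x$point_age), format_age_my(x$age_low),
    format_age_my(x$age_high)))
  invisible(x)
}

#' Format an age in years as millions of years, one decimal
#'
#' Display rounding is half-up to one decimal (0.9135 -> "0.9",
#' 2.466 -> "2.5"); raw years are always retained in the objects.
#'
#' @param years Age in years.
#' @return Character, e.g. `"1.0"`.
#' @export
format_age_my <- function(years) {
  sprintf("%.1f", floor(years / 1e6 * 10 + 0.5) / 10)
}

#' Phylogenetic presence/absence bounds on a retrocopy's age
#'
#' A retrocopy present in a sister lineage must predate the divergence from
#' that lineage; absence from a lineage places its origin after that
#' divergence. The lower bound is the maximum over present taxa of their
#' divergence interval, the upper bound the minimum over absent taxa (open
#' when no absent taxon is known). Because published divergence estimates
#' often conflict, the envelope policy is configurable: `"outer"` (default,
#' most permissive — interval minimum for the lower bound, maximum for the
#' upper) or `"inner"` (the reverse).
#'
#' @param table Data frame with columns `taxon`, `status`
#'   (`present`/`absent`/`unknown`), `div_low`, `div_high` (years of
#'   divergence from the focal lineage).
#' @param policy `"outer"` or `"inner"`.
#' @return List `lower`, `upper` (years; `Inf` when open), `conflict`
#'   (TRUE when a present taxon is older than an absent one under the
#'   chosen envelope).
#' @export
presence_bounds <- function(table, policy = c("outer", "inner")) {
  policy <- match.arg(policy)
  stopifnot(all(c("taxon", "status", "div_low", "div_high") %in%
                  names(table)))
  if (any(table$div_low > table$div_high) || any(table$div_low <= 0))
    stop("divergence intervals must be positive with low <= high")
  known <- table[table$status %in% c("present", "absent"), , drop = FALSE]
  if (!nrow(known)) stop("input error: no taxon with known status")
  pres <- known[known$status == "present", , drop = FALSE]
  abst <- known[known$status == "absent", , drop = FALSE]
  lower <- if (nrow(pres)) {
    if (policy == "outer") max(pres$div_low) else max(pres$div_high)
  } else 0
  upper <- if (nrow(abst)) {
    if (policy == "outer") min(abst$div_high) else min(abst$div_low)
  } else Inf
  list(lower = lower, upper = upper, conflict = lower > upper)
}

#' Reconcile a clock estimate with phylogenetic bounds
#'
#' Intersects the clock's age interval with the presence/absence bounds.
#' An empty intersection sets `consistent = FALSE` and returns both
#' intervals untouched.
#'
#' @param clock An `age_estimate`.
#' @param bounds Result of [presence_bounds()] (or a list with `lower`,
#'   `upper`).
#' @return List: `consensus_low`, `consensus_high` (NA when inconsistent),
#'   `consistent`, `clock`, `bounds`.
#' @export
combine_evidence <- function(clock, bounds) {
  lo <- max(clock$age_low, bounds$lower)
  hi <- min(clock$age_high, bounds$upper)
  if (lo > hi)
    list(consensus_low = NA_real_, consensus_high = NA_real_,
         consistent = FALSE, clock = clock, bounds = bounds)
  else
    list(consensus_low = lo, consensus_high = hi, consistent = TRUE,
         clock = clock, bounds = bounds)
}
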
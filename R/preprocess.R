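#' Box-Cox power transformation with profile-likelihood lambda selection
#'
#' Transforms a positive vector as `(x^lambda - 1)/lambda` (natural log at
#' `lambda = 0`). When `lambda` is not supplied it is chosen to maximize the
#' standard Box-Cox profile log-likelihood
#' `-n/2 log(sigma2_hat(lambda)) + (lambda - 1) sum(log x)` over the grid
#' `[-2, 2]` in steps of 0.01, with ties broken toward 0 (preferring the log
#' transform). Missing values are ignored for fitting and propagated.
#'
#' @param x positive numeric vector (NAs allowed).
#' @param lambda optional fixed power parameter.
#' @return list of class `boxcox_result`: `lambda`, `transformed` (same length
#'   as `x`), `loglik` (profile log-likelihood at the chosen lambda; NA when
#'   lambda was supplied by the caller on degenerate input).
#' @export
#' @examples
#' boxcox_transform(c(1, 2, 4), lambda = 1)$transformed  # 0 1 3
boxcox_transform <- function(x, lambda = NULL) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0) stop("no observed values")
  if (any(obs <= 0)) stop("Box-Cox requires strictly positive values")
  bc <- function(l) if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
  loglik <- function(l) {
    y <- if (abs(l) < 1e-12) log(obs) else (obs^l - 1) / l
    s2 <- mean((y - mean(y))^2)
    -length(obs) / 2 * log(s2) + (l - 1) * sum(log(obs))
  }
  if (is.null(lambda)) {
    grid <- seq(-2, 2, by = 0.01)
    ll <- vapply(grid, loglik, numeric(1))
    best <- ll >= max(ll) - 1e-9            # ties to the smallest |lambda|
    cand <- grid[best]
    lambda <- cand[which.min(abs(cand))]
  }
  structure(list(lambda = lambda, transformed = bc(lambda),
                 loglik = if (length(obs) > 1) loglik(lambda) else NA_real_),
            class = "boxcox_result")
}

#' Aggression score from approach latency
#'
#' Converts approach latency (seconds until the focal male approaches a
#' simulated territorial intruder) into an aggressiveness score: the latency
#' is Box-Cox transformed (lambda fitted on the observed positive latencies
#' unless supplied), multiplied by -1 so that higher values mean greater
#' aggressiveness, and expressed as the deviation from the mean score of the
#' bird's nest stage — removing the stage effect on latency. Missing latencies
#' propagate as missing.
#'
#' @param latency positive numeric vector, seconds.
#' @param stages nest-stage labels, same length as `latency`.
#' @param lambda optional fixed Box-Cox parameter (fitted when NULL).
#' @return Numeric vector of stage-centred scores (mean 0 within each stage).
#' @export
aggression_score <- function(latency, stages, lambda = NULL) {
  if (length(latency) != length(stages))
    stop("latency and stages must have the same length")
  stages <- as.character(stages)
  for (s in unique(stages[!is.na(stages)]))
    if (all(is.na(latency[stages == s])))
      stop("nest stage '", s, "' has no observed latencies")
  score <- -boxcox_transform(latency, lambda = lambda)$transformed
  centred <- stats::ave(score, stages, FUN = function(v) v - mean(v, na.rm = TRUE))
  centred
}

#' Mean hourly provisioning rate across the two observation days
#'
#' Feeding visits are counted over one 90-minute window per observation day
#' (nestling days 11 and 14); each day's rate is `visits * 60/90` feeds per
#' hour and the provisioning measure is the mean of the two daily rates. A
#' bird with one day missing uses the observed day alone; both missing yields
#' NA.
#'
#' @param visits_day1,visits_day2 non-negative visit counts per 90-min window.
#' @return Feeds per hour.
#' @export
#' @examples
#' mean_feed_rate(12, 12)   # 8 feeds/h
#' mean_feed_rate(12, 15)   # 9 feeds/h
mean_feed_rate <- function(visits_day1, visits_day2) {
  if (any(visits_day1 < 0, na.rm = TRUE) || any(visits_day2 < 0, na.rm = TRUE))
    stop("visit counts must be non-negative")
  r <- cbind(visits_day1 * 60 / 90, visits_day2 * 60 / 90)
  out <- rowMeans(r, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Derive analysis variables from raw assay columns
#'
#' Adds the derived columns used by the covariance/path stage to an
#' observation-scale trait table: `aggression_derived` (stage-centred Box-Cox
#' aggression score from `latency_s` and `nest_stage`), `feed_rate_own` and
#' `feed_rate_partner` (mean feeds per hour from the two daily 90-min visit
#' counts), and `exploration_mean` (mean of the repeated assay scores).
#' Columns whose inputs are absent are skipped.
#'
#' @param table data.frame in the layout written by [generate_population()]
#'   with `observation_scale = TRUE`.
#' @return The table with derived columns appended.
#' @export
derive_analysis_variables <- function(table) {
  if (all(c("latency_s", "nest_stage") %in% names(table)))
    table$aggression_derived <- aggression_score(table$latency_s, table$nest_stage)
  if (all(c("feed_own_visits_d11", "feed_own_visits_d14") %in% names(table)))
    table$feed_rate_own <- mean_feed_rate(table$feed_own_visits_d11,
                                          table$feed_own_visits_d14)
  if (all(c("feed_partner_visits_d11", "feed_partner_visits_d14") %in% names(table)))
    table$feed_rate_partner <- mean_feed_rate(table$feed_partner_visits_d11,
                                              table$feed_partner_visits_d14)
  if (all(c("exploration_score_1", "exploration_score_2") %in% names(table)))
    table$exploration_mean <- rowMeans(
      table[, c("exploration_score_1", "exploration_score_2")], na.rm = TRUE)
  table
}
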
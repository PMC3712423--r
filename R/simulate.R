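#' Configure the pair-level synthetic data generator
#'
#' The generator draws standardized latent traits from a known recursive
#' structural model — exogenous variables jointly Gaussian with the configured
#' correlations, each endogenous variable a linear combination of its parents
#' plus a Gaussian residual whose variance completes unit total variance — so
#' the generating path coefficients are directly comparable to standardized
#' estimates. Optional layers add repeated measures with known intraclass
#' correlation and observation-scale realism (latency seconds with nest-stage
#' offsets, integer counts and dates).
#'
#' @param diagram a [path_diagram()] defining the structural DAG.
#' @param coefficients numeric vector of path coefficients named by edge label
#'   (every edge must be covered).
#' @param n_pairs number of breeding pairs (rows).
#' @param exog_correlations optional data.frame (`a`, `b`, `rho`) of
#'   correlations between exogenous variables, each rho in (-1, 1).
#' @param repeat_icc named numeric in `[0, 1]`: intraclass correlation of two
#'   repeated measures emitted for the named variables.
#' @param stage_effects named numeric: additive offsets on log approach
#'   latency per nest-stage label (used only with `observation_scale`).
#' @param missing_rates named numeric in `[0, 1]`: per-column rates passed to
#'   [apply_missingness()] by [generate_population()].
#' @param observation_scale logical: also emit observation-scale columns
#'   (latency seconds, count-valued assay scores and feeding visits, integer
#'   dates and brood sizes). Latent columns are always retained.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return A `generator_config` list.
#' @export
generator_config <- function(diagram, coefficients, n_pairs,
                             exog_correlations = NULL,
                             repeat_icc = numeric(0),
                             stage_effects = c(nest_building = 0,
                                               egg_laying = -0.3,
                                               incubation = -0.6),
                             missing_rates = numeric(0),
                             observation_scale = FALSE,
                             seed = NULL) {
  stopifnot(inherits(diagram, "path_diagram"),
            is.numeric(n_pairs), length(n_pairs) == 1, n_pairs >= 1)
  miss <- setdiff(diagram$edges$label, names(coefficients))
  if (length(miss) > 0)
    stop("coefficients missing for edges: ", paste(miss, collapse = ", "))
  if (length(repeat_icc) > 0) {
    if (any(repeat_icc < 0 | repeat_icc > 1)) stop("repeat_icc must lie in [0, 1]")
    bad <- setdiff(names(repeat_icc), diagram$variables)
    if (length(bad) > 0) stop("repeat_icc names unknown: ", paste(bad, collapse = ", "))
  }
  if (length(missing_rates) > 0 && any(missing_rates < 0 | missing_rates > 1))
    stop("missing rates must lie in [0, 1]")
  if (!is.null(exog_correlations)) {
    exog_correlations <- as.data.frame(exog_correlations)
    stopifnot(all(c("a", "b", "rho") %in% names(exog_correlations)))
    if (any(abs(exog_correlations$rho) >= 1))
      stop("exogenous correlations must lie in (-1, 1)")
    bad <- setdiff(unique(c(exog_correlations$a, exog_correlations$b)),
                   diagram$exogenous)
    if (length(bad) > 0)
      stop("exog_correlations may only involve exogenous variables; got: ",
           paste(bad, collapse = ", "))
  }
  cfg <- list(diagram = diagram, coefficients = coefficients,
              n_pairs = as.integer(n_pairs),
              exog_correlations = exog_correlations,
              repeat_icc = repeat_icc, stage_effects = stage_effects,
              missing_rates = missing_rates,
              observation_scale = isTRUE(observation_scale), seed = seed)
  cfg$truth <- structural_parameters(diagram, coefficients, exog_correlations)
  class(cfg) <- "generator_config"
  cfg
}

# Implied population correlation matrix and residual variances, built in
# topological order; errors when a variable's parents explain >= 100% of its
# variance or the exogenous correlation block is not positive definite.
structural_parameters <- function(diagram, coefficients, exog_correlations = NULL) {
  vars <- diagram$order
  p <- length(vars)
  R <- diag(p); dimnames(R) <- list(vars, vars)
  if (!is.null(exog_correlations) && nrow(exog_correlations) > 0) {
    R[cbind(exog_correlations$a, exog_correlations$b)] <- exog_correlations$rho
    R[cbind(exog_correlations$b, exog_correlations$a)] <- exog_correlations$rho
  }
  exo <- diagram$exogenous
  ok <- tryCatch({chol(R[exo, exo, drop = FALSE]); TRUE}, error = function(e) FALSE)
  if (!ok) stop("exogenous correlation block is not positive definite")

  psi <- stats::setNames(rep(1, p), vars)
  for (v in diagram$endogenous) {
    sel <- diagram$edges$target == v
    P <- diagram$edges$source[sel]
    b <- coefficients[diagram$edges$label[sel]]
    psi[v] <- 1 - drop(t(b) %*% R[P, P, drop = FALSE] %*% b)
    if (psi[v] <= 0)
      stop("invalid coefficients: implied residual variance of '", v,
           "' is ", signif(psi[v], 3), " (parents explain >= 100% of variance)")
    others <- setdiff(vars, v)
    R[v, others] <- R[others, v] <- drop(t(b) %*% R[P, others, drop = FALSE])
  }
  ord <- diagram$variables
  list(implied = R[ord, ord], psi = psi[ord],
       coefficients = coefficients[diagram$edges$label])
}

#' Generate a synthetic pair-level trait table with known ground truth
#'
#' Latent standardized traits are simulated in topological order from the
#' configured structural model; each latent column is named by its diagram
#' variable. Variables listed in `repeat_icc` additionally get two repeated
#' measures `<var>_rep1`/`<var>_rep2` (latent plus Gaussian measurement noise
#' calibrated to the requested intraclass correlation). With
#' `observation_scale = TRUE`, observation columns mimicking the field assays
#' are added (see Details), and configured missingness is applied to the
#' latent columns via [apply_missingness()].
#'
#' @details Observation-scale columns (emitted only for variables present in
#' the diagram): `nest_stage` and `latency_s` (approach latency in seconds,
#' `exp(stage_offset - 0.5 * aggression) * 60` — an arbitrary monotone map;
#' only monotonicity matters because preprocessing inverts it up to rank);
#' `exploration_score_1/2` (non-negative activity counts from the repeated
#' measures); `feed_own_visits_d11/_d14` and `feed_partner_visits_d11/_d14`
#' (visits per 90-min window on nestling days 11 and 14); `lay_date_obs`
#' (integer days since March 1); `brood_size_obs`, `fledgling_no_obs`
#' (integers, fledgling number clamped to brood size) and
#' `fledgling_mass_obs` (grams). Integerization attenuates correlations, so
#' recovery analyses should use the latent columns.
#'
#' @param config a [generator_config()].
#' @return list with `table` (data.frame, one row per pair, `pair_id` first)
#'   and `truth` (generating coefficients, residual variances `psi`, implied
#'   population correlation matrix, repeat-measure ICCs).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- config$diagram
  n <- config$n_pairs
  truth <- config$truth
  vars <- d$variables

  X <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  exo <- d$exogenous
  Rexo <- truth$implied[exo, exo, drop = FALSE]
  X[, exo] <- matrix(stats::rnorm(n * length(exo)), n) %*% chol(Rexo)
  for (v in intersect(d$order, d$endogenous)) {
    sel <- d$edges$target == v
    P <- d$edges$source[sel]
    b <- config$coefficients[d$edges$label[sel]]
    X[, v] <- X[, P, drop = FALSE] %*% b + stats::rnorm(n, sd = sqrt(truth$psi[v]))
  }
  tab <- data.frame(pair_id = seq_len(n), X)

  # repeated measures: obs = latent + e, Var(e) = (1 - icc)/icc => ICC = icc
  for (v in names(config$repeat_icc)) {
    icc <- config$repeat_icc[[v]]
    sd_w <- if (icc >= 1) 0 else if (icc <= 0) Inf else sqrt((1 - icc) / icc)
    if (!is.finite(sd_w)) {
      rep1 <- stats::rnorm(n); rep2 <- stats::rnorm(n)  # pure noise at icc = 0
    } else {
      rep1 <- X[, v] + stats::rnorm(n, sd = sd_w)
      rep2 <- X[, v] + stats::rnorm(n, sd = sd_w)
    }
    tab[[paste0(v, "_rep1")]] <- rep1
    tab[[paste0(v, "_rep2")]] <- rep2
  }

  if (config$observation_scale)
    tab <- add_observation_columns(tab, config)

  if (length(config$missing_rates) > 0) {
    ms <- if (is.null(config$seed)) NULL else config$seed + 1L
    tab <- apply_missingness(tab, config$missing_rates, seed = ms)
    # an unassayed pair has no raw measurement either: mirror each latent
    # variable's missingness onto its observation-scale columns
    obs_cols <- list(
      aggression = "latency_s",
      exploration = c("exploration_score_1", "exploration_score_2"),
      feed_own = c("feed_own_visits_d11", "feed_own_visits_d14"),
      feed_partner = c("feed_partner_visits_d11", "feed_partner_visits_d14"),
      lay_date = "lay_date_obs", brood_size = "brood_size_obs",
      fledgling_no = "fledgling_no_obs", fledgling_mass = "fledgling_mass_obs")
    for (v in intersect(names(config$missing_rates), names(obs_cols)))
      for (oc in intersect(obs_cols[[v]], names(tab)))
        tab[[oc]][is.na(tab[[v]])] <- NA
  }

  truth$repeat_icc <- config$repeat_icc
  list(table = tab, truth = truth)
}

add_observation_columns <- function(tab, config) {
  n <- nrow(tab)
  vars <- config$diagram$variables
  if ("aggression" %in% vars) {
    stages <- names(config$stage_effects)
    tab$nest_stage <- sample(stages, n, replace = TRUE)
    tab$latency_s <- exp(config$stage_effects[tab$nest_stage] -
                           0.5 * tab$aggression) * 60
  }
  if ("exploration" %in% vars) {
    r1 <- if (!is.null(tab$exploration_rep1)) tab$exploration_rep1 else tab$exploration
    r2 <- if (!is.null(tab$exploration_rep2)) tab$exploration_rep2 else tab$exploration
    tab$exploration_score_1 <- pmax(0, round(20 + 6 * r1))
    tab$exploration_score_2 <- pmax(0, round(20 + 6 * r2))
  }
  for (fv in intersect(c("feed_own", "feed_partner"), vars)) {
    r1 <- if (!is.null(tab[[paste0(fv, "_rep1")]])) tab[[paste0(fv, "_rep1")]] else tab[[fv]]
    r2 <- if (!is.null(tab[[paste0(fv, "_rep2")]])) tab[[paste0(fv, "_rep2")]] else tab[[fv]]
    tab[[paste0(fv, "_visits_d11")]] <- pmax(0, round(22 + 6 * r1))
    tab[[paste0(fv, "_visits_d14")]] <- pmax(0, round(22 + 6 * r2))
  }
  if ("lay_date" %in% vars)
    tab$lay_date_obs <- as.integer(round(30 + 8 * tab$lay_date))
  if ("brood_size" %in% vars)
    tab$brood_size_obs <- pmax(0L, as.integer(round(9 + 2 * tab$brood_size)))
  if ("fledgling_no" %in% vars) {
    fl <- pmax(0L, as.integer(round(7 + 2.2 * tab$fledgling_no)))
    if (!is.null(tab$brood_size_obs)) fl <- pmin(fl, tab$brood_size_obs)
    tab$fledgling_no_obs <- fl
  }
  if ("fledgling_mass" %in% vars)
    tab$fledgling_mass_obs <- pmax(0.1, 11 + 1.1 * tab$fledgling_mass)
  tab
}

#' Set cells missing completely at random
#'
#' Each cell of each named column is independently set to NA with its
#' configured rate; other columns are untouched. Emulates the pairwise-varying
#' sample sizes of field datasets where different assays cover different
#' subsets of pairs.
#'
#' @param table data.frame.
#' @param rates named numeric vector of per-column missingness rates in
#'   `[0, 1]`; names must be columns of `table`.
#' @param seed optional integer seed.
#' @return The table with NAs inserted.
#' @export
apply_missingness <- function(table, rates, seed = NULL) {
  if (length(rates) == 0) return(table)
  if (any(rates < 0 | rates > 1)) stop("missing rates must lie in [0, 1]")
  bad <- setdiff(names(rates), names(table))
  if (length(bad) > 0) stop("unknown variables: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  for (v in names(rates)) {
    hit <- stats::runif(nrow(table)) < rates[[v]]
    table[[v]][hit] <- NA
  }
  table
}

#' Study-scale generator configurations for the provisioning models
#'
#' Ready-made [generator_config()]s emulating the reference field study's
#' structure: generating coefficients fixed at the reference male/female path
#' estimates, repeated exploration scores at the combined-years repeatability
#' (0.66) and two daily feeding observations at the feeding-rate repeatability
#' (0.78), nest-stage offsets on log latency, and per-variable missingness
#' chosen so pairwise sample sizes land in the study's 33-73 range at the
#' default 75 pairs.
#'
#' @param n_pairs number of pairs (default 75).
#' @param observation_scale emit observation-scale columns (default TRUE for
#'   study-scale use; turn off for parameter-recovery runs).
#' @param missing_rates named rates on the latent columns; NULL for the
#'   study-scale defaults, `numeric(0)` for complete data.
#' @param seed integer seed.
#' @return A `generator_config`.
#' @export
male_model_config <- function(n_pairs = 75, observation_scale = TRUE,
                              missing_rates = NULL, seed = NULL) {
  ref <- reference_path_coefficients()
  ref <- ref[ref$sex == "male", ]
  if (is.null(missing_rates))
    missing_rates <- c(aggression = 0.42, exploration = 0.20,
                       feed_own = 0.36, feed_partner = 0.36,
                       lay_date = 0.08, brood_size = 0.05,
                       fledgling_no = 0.06, fledgling_mass = 0.10)
  generator_config(
    male_diagram(), stats::setNames(ref$coef, ref$label), n_pairs,
    repeat_icc = c(exploration = 0.66, feed_own = 0.78, feed_partner = 0.78),
    missing_rates = missing_rates,
    observation_scale = observation_scale, seed = seed)
}

#' @rdname male_model_config
#' @export
female_model_config <- function(n_pairs = 75, observation_scale = TRUE,
                                missing_rates = NULL, seed = NULL) {
  ref <- reference_path_coefficients()
  ref <- ref[ref$sex == "female", ]
  if (is.null(missing_rates))
    missing_rates <- c(exploration = 0.25, feed_own = 0.36, feed_partner = 0.36,
                       lay_date = 0.05, brood_size = 0.03,
                       fledgling_no = 0.03, fledgling_mass = 0.08)
  generator_config(
    female_diagram(), stats::setNames(ref$coef, ref$label), n_pairs,
    repeat_icc = c(exploration = 0.66, feed_own = 0.78, feed_partner = 0.78),
    missing_rates = missing_rates,
    observation_scale = observation_scale, seed = seed)
}

#' Read or write a trait table CSV
#'
#' UTF-8 CSV with a header row and "NA" for missing cells.
#'
#' @param table data.frame to write.
#' @param file path.
#' @return `read_trait_table` returns a data.frame.
#' @export
write_trait_table <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(file) {
  utils::read.csv(file, na.strings = "NA", fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE)
}

#' Serialize generator ground truth as JSON
#'
#' @param truth the `truth` element returned by [generate_population()].
#' @param file path.
#' @export
write_truth <- function(truth, file) {
  out <- list(coefficients = as.list(truth$coefficients),
              psi = as.list(truth$psi),
              repeat_icc = as.list(truth$repeat_icc),
              variables = colnames(truth$implied),
              implied_correlation = unname(apply(truth$implied, 1, as.list)))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
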
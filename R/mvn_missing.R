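#' Posterior draws of a covariance matrix under missing data
#'
#' Fits a multivariate Gaussian model to the analysis variables and returns
#' posterior draws of their variance-covariance matrix, to be carried forward
#' into per-draw path analyses so that estimation uncertainty propagates into
#' every path coefficient. Variables are standardized to observed mean 0 and
#' SD 1 before sampling (coefficients are then on the standardized scale).
#' Missing cells are handled by Gibbs data augmentation under ignorable (MAR)
#' missingness: the sampler alternates (missing cells | observed, mu, Sigma)
#' from the conditional Gaussians, (mu | data, Sigma) Gaussian, and
#' (Sigma | data, mu) inverse-Wishart.
#'
#' Priors: inverse-Wishart with `p + 1` degrees of freedom and identity scale
#' on the standardized scale (marginal correlations near-uniform); Gaussian
#' prior with variance 1e8 on each mean.
#'
#' @param table data.frame holding the analysis variables.
#' @param vars character vector of column names to model; defaults to every
#'   numeric column.
#' @param mcmc an [mcmc_settings()] (default: 13,000 iterations, 3,000
#'   burn-in, thin 10, i.e. 1,000 retained covariance draws).
#' @param seed optional integer seed.
#' @param fix_mean logical; fix the mean vector at 0 instead of sampling it
#'   (with complete data this makes the Sigma posterior the closed-form
#'   conjugate inverse-Wishart).
#' @param prior_df,mean_prior_var prior hyperparameters (see above).
#' @return list of class `covariance_draws`: `variables`, `draws` (p x p x K
#'   array of symmetric PD matrices), `means` (K x p), `n` (pairwise
#'   observed-count matrix), `settings`, `center`/`scale` used for
#'   standardization, `log` (character vector of recorded warnings).
#' @export
fit_mvn_missing <- function(table, vars = NULL, mcmc = mcmc_settings(),
                            seed = NULL, fix_mean = FALSE,
                            prior_df = NULL, mean_prior_var = 1e8) {
  table <- as.data.frame(table)
  if (is.null(vars))
    vars <- names(table)[vapply(table, is.numeric, logical(1))]
  miss <- setdiff(vars, names(table))
  if (length(miss) > 0) stop("unknown variables: ", paste(miss, collapse = ", "))
  if (length(vars) < 2) stop("need at least 2 variables")
  Y <- as.matrix(table[, vars])
  storage.mode(Y) <- "double"
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  nobs <- colSums(!is.na(Y))
  if (any(nobs < 3))
    stop("variables observed on fewer than 3 rows: ",
         paste(vars[nobs < 3], collapse = ", "))

  ctr <- colMeans(Y, na.rm = TRUE)
  scl <- apply(Y, 2, stats::sd, na.rm = TRUE)
  if (any(scl < 1e-12))
    stop("zero variance in: ", paste(vars[scl < 1e-12], collapse = ", "))
  Y <- sweep(sweep(Y, 2, ctr), 2, scl, "/")

  npair <- pairwise_counts(as.data.frame(Y))
  log_msgs <- character(0)
  if (min(npair) < 1) {
    log_msgs <- "some variable pair has no jointly observed rows; imputation borrows across variables"
    warning(log_msgs)
  }

  if (!is.null(seed)) set.seed(seed)
  if (is.null(prior_df)) prior_df <- p + 1
  S0 <- diag(p)

  # fixed missingness patterns, grouped once
  na_mat <- is.na(Y)
  pat_key <- apply(na_mat, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat_key)
  groups <- groups[vapply(groups, function(g) any(na_mat[g[1], ]), logical(1))]

  Yc <- Y
  Yc[na_mat] <- 0
  mu <- if (fix_mean) numeric(p) else colMeans(Yc)
  Sigma <- stats::cov(Yc) + diag(1e-6, p)

  K <- mcmc$n_draws
  draws <- array(NA_real_, c(p, p, K), dimnames = list(vars, vars, NULL))
  means <- matrix(NA_real_, K, p, dimnames = list(NULL, vars))
  k <- 0L
  for (it in seq_len(mcmc$n_iter)) {
    # missing cells | observed, mu, Sigma
    for (g in groups) {
      m <- na_mat[g[1], ]
      o <- !m
      if (!any(o)) {
        Yc[g, ] <- matrix(stats::rnorm(length(g) * p), ncol = p) %*% chol(Sigma) +
          rep(mu, each = length(g))
        next
      }
      Soo <- Sigma[o, o, drop = FALSE]
      C <- t(solve(Soo, Sigma[o, m, drop = FALSE]))      # Sigma_mo Sigma_oo^-1
      cond_cov <- Sigma[m, m, drop = FALSE] - C %*% Sigma[o, m, drop = FALSE]
      cond_cov <- (cond_cov + t(cond_cov)) / 2
      cm <- sweep(Yc[g, o, drop = FALSE], 2, mu[o]) %*% t(C)
      cm <- sweep(cm, 2, mu[m], "+")
      L <- chol(cond_cov + diag(1e-10, nrow(cond_cov)))
      Yc[g, m] <- cm + matrix(stats::rnorm(length(g) * sum(m)), ncol = sum(m)) %*% L
    }
    # mu | data, Sigma
    if (!fix_mean) {
      Sinv <- chol2inv(chol(Sigma))
      V <- chol2inv(chol(n * Sinv + diag(1 / mean_prior_var, p)))
      mhat <- V %*% (Sinv %*% colSums(Yc))
      mu <- drop(mhat + t(chol(V)) %*% stats::rnorm(p))
    }
    # Sigma | data, mu : inverse-Wishart
    S <- S0 + crossprod(sweep(Yc, 2, mu))
    W <- stats::rWishart(1, prior_df + n, chol2inv(chol(S)))[, , 1]
    Sigma <- chol2inv(chol(W))
    Sigma <- (Sigma + t(Sigma)) / 2

    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
      k <- k + 1L
      draws[, , k] <- Sigma
      means[k, ] <- mu
    }
  }
  structure(list(variables = vars, draws = draws, means = means, n = npair,
                 settings = mcmc, center = ctr, scale = scl, log = log_msgs),
            class = "covariance_draws")
}

#' @export
print.covariance_draws <- function(x, ...) {
  cat("Covariance posterior:", dim(x$draws)[3], "draws over",
      length(x$variables), "variables\n")
  cat("  ", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise observed-sample-size matrix
#'
#' Entry (i, j) counts the rows on which both variables are observed — the
#' per-path sample sizes of a dataset whose assays cover different subsets of
#' pairs. The diagonal holds per-variable observed counts.
#'
#' @param table data.frame.
#' @param vars columns to include (default: all numeric columns).
#' @return Symmetric integer matrix.
#' @export
pairwise_counts <- function(table, vars = NULL) {
  table <- as.data.frame(table)
  if (is.null(vars))
    vars <- names(table)[vapply(table, is.numeric, logical(1))]
  obs <- !is.na(as.matrix(table[, vars, drop = FALSE]))
  storage.mode(obs) <- "integer"
  out <- crossprod(obs)
  dimnames(out) <- list(vars, vars)
  out
}

#' Rescale covariance draws to correlation matrices
#'
#' Each draw is rescaled to unit diagonal (`cov2cor`); positive definiteness
#' is preserved by the rescaling.
#'
#' @param draws a `covariance_draws`.
#' @return A `covariance_draws` whose matrices are correlation matrices.
#' @export
to_correlation <- function(draws) {
  stopifnot(inherits(draws, "covariance_draws"))
  K <- dim(draws$draws)[3]
  for (k in seq_len(K)) {
    d <- diag(draws$draws[, , k])
    if (any(d <= 0)) stop("draw ", k, " has a non-positive diagonal entry")
    draws$draws[, , k] <- stats::cov2cor(draws$draws[, , k])
  }
  draws
}
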
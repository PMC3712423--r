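#' MCMC chain settings
#'
#' Defaults follow the convention used throughout the package: 13,000
#' iterations, 3,000 burn-in, thinning interval 10, leaving exactly 1,000
#' retained draws.
#'
#' @param n_iter total iterations.
#' @param burn_in iterations discarded before retention.
#' @param thin keep every `thin`-th iteration after burn-in.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 13000, burn_in = 3000, thin = 10) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 n_draws = (as.integer(n_iter) - as.integer(burn_in)) %/% as.integer(thin)),
            class = "mcmc_settings")
}

#' Gibbs sampler for a Gaussian random-intercept model
#'
#' Fits `y = X b + u[individual] + e` with `u_i ~ N(0, sigma2_ind)` and
#' `e ~ N(0, sigma2_res)` — the univariate mixed model used to quantify
#' repeatability of repeated behavioural assays (random intercepts for
#' individual identity; assay covariates such as sex or test sequence as
#' fixed effects). Priors are flat on the fixed effects and inverse-gamma
#' (shape 0.001, scale 0.001) on both variances. The sampler alternates the
#' full conditionals (fixed effects | rest), (intercepts | rest),
#' (sigma2_ind | intercepts), (sigma2_res | residuals).
#'
#' @param y numeric response vector.
#' @param individual individual identities (factor or vector), same length.
#' @param covariates optional data.frame or matrix of fixed-effect covariates
#'   (an intercept is always included).
#' @param mcmc an [mcmc_settings()].
#' @param seed optional integer seed.
#' @param prior_shape,prior_scale inverse-gamma hyperparameters for both
#'   variance priors.
#' @return list of class `vc_posterior`: `sigma2_ind`, `sigma2_res` (draw
#'   vectors), `beta` (draw matrix), `settings`, `ess` (effective sample sizes
#'   of the variance chains).
#' @export
fit_random_intercept <- function(y, individual, covariates = NULL,
                                 mcmc = mcmc_settings(), seed = NULL,
                                 prior_shape = 0.001, prior_scale = 0.001) {
  keep <- !is.na(y) & !is.na(individual)
  y <- y[keep]
  individual <- factor(individual[keep])
  n <- length(y)
  q <- nlevels(individual)
  if (q < 2) stop("need at least 2 individuals")
  counts <- tabulate(individual)
  if (sum(counts >= 2) < 2)
    stop("need at least 2 individuals with at least 2 measures each")

  if (is.null(covariates)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
    X <- stats::model.matrix(~ ., data = covariates)
  }
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design matrix")
  p <- ncol(X)

  if (!is.null(seed)) set.seed(seed)
  XtX <- crossprod(X)
  XtX_chol <- chol(XtX)
  idx <- as.integer(individual)

  s2_ind <- s2_res <- max(stats::var(y), 1e-6) / 2
  u <- numeric(q)
  beta <- backsolve(XtX_chol, forwardsolve(t(XtX_chol), crossprod(X, y)))

  n_keep <- mcmc$n_draws
  out_ind <- out_res <- numeric(n_keep)
  out_beta <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  k <- 0L
  for (it in seq_len(mcmc$n_iter)) {
    # fixed effects | rest : N((X'X)^-1 X'(y - Zu), s2_res (X'X)^-1)
    ytil <- y - u[idx]
    bhat <- backsolve(XtX_chol, forwardsolve(t(XtX_chol), crossprod(X, ytil)))
    beta <- bhat + backsolve(XtX_chol, stats::rnorm(p)) * sqrt(s2_res)
    # intercepts | rest : conditionally independent normals
    resid <- y - drop(X %*% beta)
    prec <- counts / s2_res + 1 / s2_ind
    mu_u <- (rowsum(resid, idx)[, 1] / s2_res) / prec
    u <- stats::rnorm(q, mu_u, sqrt(1 / prec))
    # variances | rest : conjugate inverse-gamma updates
    s2_ind <- rinvgamma(1L, prior_shape + q / 2, prior_scale + sum(u^2) / 2)
    e <- resid - u[idx]
    s2_res <- rinvgamma(1L, prior_shape + n / 2, prior_scale + sum(e^2) / 2)

    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
      k <- k + 1L
      out_ind[k] <- s2_ind
      out_res[k] <- s2_res
      out_beta[k, ] <- beta
    }
  }
  structure(list(sigma2_ind = out_ind, sigma2_res = out_res, beta = out_beta,
                 settings = mcmc,
                 ess = c(sigma2_ind = effective_size(out_ind),
                         sigma2_res = effective_size(out_res))),
            class = "vc_posterior")
}

# Initial-monotone-sequence style ESS from the autocorrelation function.
effective_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) < 1e-12) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  cut <- if (length(pos) > 0) pos[1] - 1 else length(rho)
  n / (1 + 2 * sum(rho[seq_len(cut)]))
}

#' Repeatability (intraclass correlation) from a variance-component posterior
#'
#' Per draw, repeatability is the between-individual variance divided by the
#' sum of between-individual and residual variance,
#' `R = sigma2_ind / (sigma2_ind + sigma2_res)` — the fraction of the variance
#' not explained by the fixed effects that is attributable to consistent
#' individual differences. The point estimate is the Gaussian-KDE mode of the
#' R draws (the "most likely" value); the posterior mean and the equal-tailed
#' 95% credible interval are reported alongside.
#'
#' @param post a `vc_posterior` from [fit_random_intercept()].
#' @return list of class `repeatability_estimate`: `point` (KDE mode), `mean`,
#'   `lower95`, `upper95`, `draws` (the per-draw R values).
#' @export
repeatability <- function(post) {
  if (length(post$sigma2_ind) == 0) stop("empty posterior")
  r <- post$sigma2_ind / (post$sigma2_ind + post$sigma2_res)
  ci <- unname(stats::quantile(r, c(0.025, 0.975)))
  structure(list(point = min(max(kde_mode(r), 0), 1), mean = mean(r),
                 lower95 = ci[1], upper95 = ci[2], draws = r),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("Repeatability R = %.2f (mean %.2f, 95%% CI %.2f-%.2f, %d draws)\n",
              x$point, x$mean, x$lower95, x$upper95, length(x$draws)))
  invisible(x)
}
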
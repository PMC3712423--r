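#' Mode of a Gaussian kernel density estimate
#'
#' The "most likely" value of a sample of posterior draws: the maximizer of a
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth, evaluated on a
#' 512-point grid. Used as the point estimate for path coefficients and
#' repeatabilities; the posterior mean is always reported alongside because
#' mode estimation is bandwidth-sensitive.
#'
#' @param x numeric vector of draws.
#' @return The grid point with maximal density; for (near-)constant input the
#'   common value.
#' @export
kde_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite values")
  if (stats::sd(x) < 1e-12) return(x[1])
  d <- stats::density(x, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

# Inverse-gamma draws: X = 1/G with G ~ Gamma(shape, rate = scale) so that
# E[X] = scale/(shape-1). Shared by both Gibbs samplers' variance updates.
rinvgamma <- function(n, shape, scale) 1 / stats::rgamma(n, shape = shape, rate = scale)

# Residual-variance conditional used by the variance-component sampler:
# sigma2 | residuals ~ InvGamma(shape0 + n/2, scale0 + SS/2).
draw_variance <- function(resid, shape0, scale0)
  rinvgamma(1L, shape0 + length(resid) / 2, scale0 + sum(resid^2) / 2)

# Eigenvalue-clipped PD repair for a nearly-indefinite correlation matrix:
# clip eigenvalues at `floor`, reconstruct, renormalize to unit diagonal.
# Well-conditioned matrices pass through (numerically) unchanged.
repair_correlation <- function(R, floor = 1e-8) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= floor) return(R)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(R)
  (out + t(out)) / 2
}

# Sample skewness (used in transform diagnostics/tests).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
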
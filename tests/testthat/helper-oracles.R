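# Independent oracles used across the suite. These deliberately avoid the
# package's own linear-algebra routes (no implied_matrix / fit_paths calls).

# Exhaustive tracing-rule oracle: total-effect matrix by explicit DFS
# enumeration of every directed path, then corr = T Psi T' with T including
# the identity (length-0 paths). Feasible for small diagrams only.
tracing_implied <- function(edges, psi, exog_corr = NULL, variables) {
  p <- length(variables)
  full_psi <- stats::setNames(rep(1, p), variables)  # exogenous: unit variance
  full_psi[names(psi)] <- psi
  psi <- full_psi
  coef_of <- function(s, t) {
    hit <- edges$source == s & edges$target == t
    if (any(hit)) edges$coef[hit] else 0
  }
  children <- function(v) edges$target[edges$source == v]
  # sum over all directed paths u -> ... -> w of the coefficient product
  total_effect <- function(u, w) {
    if (u == w) return(1)
    s <- 0
    for (ch in children(u))
      s <- s + coef_of(u, ch) * total_effect(ch, w)
    s
  }
  Tm <- matrix(0, p, p, dimnames = list(variables, variables))
  for (u in variables) for (w in variables)
    Tm[w, u] <- total_effect(u, w)     # effect of u on w
  Psi <- diag(psi[variables])
  dimnames(Psi) <- list(variables, variables)
  if (!is.null(exog_corr) && nrow(exog_corr) > 0) {
    Psi[cbind(exog_corr$a, exog_corr$b)] <- exog_corr$rho
    Psi[cbind(exog_corr$b, exog_corr$a)] <- exog_corr$rho
  }
  Tm %*% Psi %*% t(Tm)
}

# Random recursive model over `p` ordered variables; coefficients rescaled
# until every implied residual variance is positive. Returns edges (with
# coef), psi, and the diagram.
random_dag_model <- function(p, edge_prob = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vars <- paste0("v", seq_len(p))
  src <- tgt <- character(0)
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    if (stats::runif(1) < edge_prob) { src <- c(src, vars[i]); tgt <- c(tgt, vars[j]) }
  if (length(src) == 0) { src <- vars[1]; tgt <- vars[2] }
  edges <- data.frame(source = src, target = tgt,
                      label = as.character(seq_along(src)),
                      coef = stats::runif(length(src), -0.7, 0.7),
                      stringsAsFactors = FALSE)
  d <- path_diagram(edges[, c("source", "target", "label")], variables = vars)
  repeat {
    ok <- tryCatch({
      tr <- pathprop:::structural_parameters(
        d, stats::setNames(edges$coef, edges$label))
      TRUE
    }, error = function(e) FALSE)
    if (ok) break
    edges$coef <- edges$coef * 0.7
  }
  list(diagram = d, edges = edges,
       coefficients = stats::setNames(edges$coef, edges$label))
}

# Simulate raw data from a recursive model (independent of the package
# generator: plain sequential regression simulation).
simulate_raw <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- model$diagram
  X <- matrix(NA_real_, n, length(d$variables),
              dimnames = list(NULL, d$variables))
  for (v in d$order) {
    sel <- model$edges$target == v
    if (!any(sel)) { X[, v] <- stats::rnorm(n); next }
    P <- model$edges$source[sel]
    X[, v] <- X[, P, drop = FALSE] %*% model$edges$coef[sel] + stats::rnorm(n)
  }
  X
}

# Inverse-gamma CDF via the gamma tail (oracle for conjugate KS checks).
pinvgamma <- function(x, shape, scale)
  stats::pgamma(1 / x, shape = shape, rate = scale, lower.tail = FALSE)

# Builds a covariance_draws object from a list/array of matrices, for tests
# that feed constructed draws into propagate().
draws_from_matrices <- function(mats, variables) {
  arr <- if (is.list(mats)) simplify2array(mats) else mats
  dimnames(arr)[1:2] <- list(variables, variables)
  structure(list(variables = variables, draws = arr,
                 means = matrix(0, dim(arr)[3], length(variables)),
                 n = matrix(NA_integer_, length(variables), length(variables),
                            dimnames = list(variables, variables)),
                 settings = NULL, center = NULL, scale = NULL, log = character(0)),
            class = "covariance_draws")
}
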
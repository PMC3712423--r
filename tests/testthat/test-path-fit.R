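test_that("orthogonal parents recover their marginal correlations as coefficients", {
  d <- parse_diagram(c("1: x1 -> y", "2: x2 -> y"))
  R <- diag(3); dimnames(R) <- list(c("x1", "x2", "y"), c("x1", "x2", "y"))
  R["x1", "y"] <- R["y", "x1"] <- 0.3
  R["x2", "y"] <- R["y", "x2"] <- 0.3
  fit <- fit_paths(R, d)
  expect_equal(unname(fit$coefficients), c(0.3, 0.3))
  expect_equal(unname(fit$psi["y"]), 1 - 0.18, tolerance = 1e-12)
  expect_equal(unname(fit$r_squared["y"] + fit$psi["y"]), 1, tolerance = 1e-12)
})

test_that("a consistent chain yields its link coefficients and implied corr(X,Z) = ab", {
  d <- parse_diagram(c("1: X -> Y", "2: Y -> Z"))
  nm <- c("X", "Y", "Z")
  R <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3, dimnames = list(nm, nm))
  fit <- fit_paths(R, d)
  expect_equal(unname(fit$coefficients), c(0.5, 0.5))
  M <- implied_matrix(d, fit)
  expect_equal(M["X", "Z"], 0.25, tolerance = 1e-12)
  expect_equal(M, R, tolerance = 1e-12)
})

test_that("coefficients equal standardized least squares on raw data (matrix-exact)", {
  for (seed in 1:3) {
    model <- random_dag_model(5, seed = seed)
    X <- simulate_raw(model, n = 2000, seed = seed + 100)
    R <- stats::cor(X)
    fit <- fit_paths(R, model$diagram)
    Z <- scale(X)
    for (v in model$diagram$endogenous) {
      sel <- model$edges$target == v
      P <- model$edges$source[sel]
      ols <- stats::lm.fit(Z[, P, drop = FALSE], Z[, v])$coefficients
      expect_equal(unname(fit$coefficients[model$edges$label[sel]]),
                   unname(ols) * (1), tolerance = 1e-10)
    }
  }
})

test_that("implied matrix equals exhaustive tracing-rule enumeration", {
  for (seed in 4:6) {
    model <- random_dag_model(6, seed = seed)
    truth <- pathprop:::structural_parameters(model$diagram, model$coefficients)
    fit <- list(coefficients = model$coefficients, psi = truth$psi)
    M <- implied_matrix(model$diagram, fit)
    edges <- model$edges
    oracle <- tracing_implied(edges, truth$psi, variables = model$diagram$variables)
    expect_lt(max(abs(M - oracle)), 1e-10)
    expect_lt(max(abs(diag(M) - 1)), 1e-10)
  }
})

test_that("fit_paths on an implied matrix recovers the generating coefficients", {
  for (seed in 7:10) {
    model <- random_dag_model(6, seed = seed)
    truth <- pathprop:::structural_parameters(model$diagram, model$coefficients)
    fit0 <- list(coefficients = model$coefficients, psi = truth$psi)
    M <- implied_matrix(model$diagram, fit0)
    fit <- fit_paths(M, model$diagram)
    expect_lt(max(abs(fit$coefficients[names(model$coefficients)] -
                        model$coefficients)), 1e-10)
    expect_true(all(fit$psi >= 0 & fit$r_squared >= 0 & fit$r_squared <= 1))
  }
})

test_that("a saturated diagram reproduces any PD correlation matrix exactly", {
  set.seed(42)
  p <- 5
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) + diag(p)
  R <- stats::cov2cor(S)
  vars <- paste0("v", 1:p)
  dimnames(R) <- list(vars, vars)
  src <- tgt <- character(0)
  for (i in 1:(p - 1)) for (j in (i + 1):p) { src <- c(src, vars[i]); tgt <- c(tgt, vars[j]) }
  d <- path_diagram(data.frame(source = src, target = tgt), variables = vars)
  M <- implied_matrix(d, fit_paths(R, d))
  expect_lt(max(abs(M - R)), 1e-10)
})

test_that("an empty-coefficient model implies the identity matrix", {
  d <- parse_diagram("1: A -> B")
  fit <- list(coefficients = c("1" = 0), psi = c(B = 1))
  expect_equal(unname(implied_matrix(d, fit)), diag(2))
})

test_that("compound coefficients are chain-validated products", {
  d <- male_diagram()
  ref <- reference_path_coefficients()
  ref <- ref[ref$sex == "male", ]
  R <- pathprop:::structural_parameters(
    d, stats::setNames(ref$coef, ref$label))$implied
  fit <- fit_paths(R, d)
  expect_equal(compound_coefficient(fit, c("10", "13")),
               prod(fit$coefficients[c("10", "13")]))
  expect_equal(compound_coefficient(fit, "18"),
               unname(fit$coefficients["18"]))
  # the point-estimate product for the aggression -> feeds -> fledglings
  # chain (paths 2, 10, 13) at the reference values
  expect_equal(-0.49 * -0.59 * 0.43, 0.124313, tolerance = 1e-12)
  expect_equal(compound_coefficient(fit, c("2", "10", "13")), 0.124313,
               tolerance = 1e-9)
  # ... which is distinct from the posterior summary of per-draw products
  # reported for that compound (0.09); the two must not be conflated
  expect_gt(abs(0.124313 - 0.09), 0.03)
  # reversed-first-edge chain (syndrome link traversed backwards) is allowed
  expect_equal(compound_coefficient(fit, c("1", "2")),
               prod(fit$coefficients[c("1", "2")]))
  # genuinely disconnected labels error
  expect_error(compound_coefficient(fit, c("15", "13")), "broken compound chain")
  # forward edge followed by a reversed edge is inadmissible
  expect_error(compound_coefficient(fit, c("2", "16")), "inadmissible")
  expect_error(compound_coefficient(fit, c("10", "99")), "unknown edge label")
})

test_that("degenerate inputs error cleanly", {
  d <- parse_diagram(c("1: x1 -> y", "2: x2 -> y"))
  nm <- c("x1", "x2", "y")
  R <- matrix(c(1, 1, .3, 1, 1, .3, .3, .3, 1), 3, dimnames = list(nm, nm))
  expect_error(fit_paths(R, d), "singular parent block")
  R2 <- diag(3)
  expect_error(fit_paths(R2[1:2, 1:2], d), "dimension|missing")
  R3 <- diag(3); dimnames(R3) <- list(nm, nm); R3[1, 2] <- 0.5
  expect_error(fit_paths(R3, d), "symmetric")
})
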
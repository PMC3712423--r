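chain3 <- function() parse_diagram(c("1: X -> Y", "2: Y -> Z"))

chain_matrix <- function(a, b) {
  nm <- c("X", "Y", "Z")
  matrix(c(1, a, a * b, a, 1, b, a * b, b, 1), 3, dimnames = list(nm, nm))
}

test_that("identical draws propagate to constant coefficients equal to the single fit", {
  d <- chain3()
  R <- chain_matrix(0.5, 0.4)
  cd <- draws_from_matrices(replicate(150, R, simplify = FALSE), c("X", "Y", "Z"))
  pd <- propagate(cd, d, compounds = list(C = c("1", "2")))
  expect_equal(unname(apply(pd$draws, 2, sd)), rep(0, 3))
  single <- fit_paths(R, d)
  expect_equal(unname(pd$draws[1, c("1", "2")]), unname(single$coefficients))
  expect_equal(unname(pd$draws[1, "C"]), 0.2)
  rep_tab <- path_report(pd)
  expect_equal(rep_tab$upper95 - rep_tab$lower95, rep(0, 3))
  expect_equal(rep_tab$p, rep(1 / 150, 3))     # floored tail probability
  expect_equal(rep_tab$support, rep("strong", 3))
})

test_that("small jitter in the draws yields small coefficient dispersion", {
  set.seed(1)
  R <- chain_matrix(0.5, 0.4)
  jitter_draws <- function(sd_j, k = 300) {
    lapply(seq_len(k), function(i) {
      E <- matrix(rnorm(9, sd = sd_j), 3)
      E <- (E + t(E)) / 2; diag(E) <- 0
      S <- R + E
      dimnames(S) <- dimnames(R)
      S
    })
  }
  cd <- draws_from_matrices(jitter_draws(1e-3), c("X", "Y", "Z"))
  pd <- propagate(cd, chain3())
  expect_lt(max(apply(pd$draws, 2, sd)), 1e-2)
  # widening the dispersion never narrows any credible interval
  widths <- sapply(c(1e-3, 5e-3, 2e-2), function(sd_j) {
    set.seed(2)
    pd <- propagate(draws_from_matrices(jitter_draws(sd_j), c("X", "Y", "Z")), chain3())
    tab <- path_report(pd)
    tab$upper95 - tab$lower95
  })
  expect_true(all(diff(t(widths)) >= 0))
})

test_that("per-draw implied correlations equal the tracing-rule sum of compound products", {
  set.seed(3)
  model <- random_dag_model(5, seed = 33)
  truth <- pathprop:::structural_parameters(model$diagram, model$coefficients)
  mats <- lapply(1:120, function(i) {
    E <- matrix(rnorm(25, sd = 5e-3), 5); E <- (E + t(E)) / 2; diag(E) <- 0
    S <- truth$implied + E
    dimnames(S) <- dimnames(truth$implied)
    S
  })
  cd <- draws_from_matrices(mats, model$diagram$variables)
  pd <- propagate(cd, model$diagram)
  for (k in c(1, 60, 120)) {
    R <- pathprop:::repair_correlation(stats::cov2cor(mats[[k]]))
    fit <- fit_paths(R, model$diagram)
    M <- implied_matrix(model$diagram, fit)
    edges <- model$edges
    edges$coef <- unname(fit$coefficients[edges$label])
    oracle <- tracing_implied(edges, fit$psi, variables = model$diagram$variables)
    diag(oracle) <- diag(M)
    expect_lt(max(abs(M - oracle)), 1e-8)
  }
})

test_that("indefinite draws are repaired or rejected, with a 5% rejection ceiling", {
  nm <- c("X", "Y", "Z")
  good <- chain_matrix(0.5, 0.4)
  nearly <- matrix(c(1, .999, .999, .999, 1, .996, .999, .996, 1), 3,
                   dimnames = list(nm, nm))  # tiny negative eigenvalue
  expect_lt(min(eigen(nearly, only.values = TRUE)$values), 0)
  cd <- draws_from_matrices(c(replicate(199, good, simplify = FALSE), list(nearly)), nm)
  pd <- propagate(cd, chain3())
  expect_lte(pd$n_rejected, 1)
  expect_gte(nrow(pd$draws), 199)
  bad <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3, dimnames = list(nm, nm))
  cd_bad <- draws_from_matrices(c(replicate(5, good, simplify = FALSE),
                                  replicate(5, bad, simplify = FALSE)), nm)
  expect_error(propagate(cd_bad, chain3()), "rejected")
})

test_that("draw summaries give KDE modes, quantile intervals and floored tail probabilities", {
  expect_error(summarize_draws(numeric(0)), "empty")
  expect_error(summarize_draws(rnorm(50)), "at least 100")
  s <- summarize_draws(rep(0.43, 1000))
  expect_equal(s$point, 0.43)
  expect_equal(c(s$lower95, s$upper95), c(0.43, 0.43))
  expect_equal(s$p, 1 / 1000)
  s2 <- summarize_draws(c(rep(-1, 500), rep(1, 500)))
  expect_equal(s2$p, 1)
  set.seed(4)
  x <- rnorm(1e5, 0.3, 0.1)
  s3 <- summarize_draws(x)
  expect_lt(abs(s3$lower95 - (0.3 - 1.96 * 0.1)), 0.01)
  expect_lt(abs(s3$upper95 - (0.3 + 1.96 * 0.1)), 0.01)
  expect_lt(abs(s3$point - 0.3), 0.02)   # KDE mode is grid/bandwidth-limited
})

test_that("support classification reproduces the strong/some/none rule", {
  expect_equal(classify_support(0.12, 0.68, 0.002), "strong")
  expect_equal(classify_support(-0.62, 0.02, 0.04), "some")
  expect_equal(classify_support(-0.3, 0.3, 0.5), "none")
  expect_equal(classify_support(-0.68, -0.12, 0.002), "strong")
  expect_equal(classify_support(-0.02, 0.62, 0.04), "some")
  expect_equal(classify_support(-0.05, 0.55, 0.08), "none")
  # boundary: an interval touching zero counts as overlapping
  expect_equal(classify_support(0, 0.5, 0.01), "some")
})

test_that("compound summaries come from per-draw products, not products of summaries", {
  set.seed(5)
  k <- 400
  e <- rep(c(-0.2, 0.2), k / 2)
  a <- 0.3 + e
  b <- 0.3 + e                       # strongly dependent component paths
  mats <- lapply(seq_len(k), function(i) chain_matrix(a[i], b[i]))
  cd <- draws_from_matrices(mats, c("X", "Y", "Z"))
  pd <- propagate(cd, chain3(), compounds = list(C = c("1", "2")))
  tab <- path_report(pd)
  mean_of_products <- tab$mean[tab$label == "C"]
  product_of_means <- prod(tab$mean[tab$label %in% c("1", "2")])
  expect_equal(mean_of_products, mean(a * b), tolerance = 1e-10)
  expect_gt(abs(mean_of_products - product_of_means), 1e-3)
})

test_that("the report table has one row per path and compound with working output files", {
  set.seed(6)
  cfg <- male_model_config(n_pairs = 400, observation_scale = FALSE,
                           missing_rates = numeric(0), seed = 7)
  pop <- generate_population(cfg)
  cd <- fit_mvn_missing(pop$table, vars = cfg$diagram$variables,
                        mcmc = mcmc_settings(700, 200, 1), seed = 8)
  comps <- reference_compound_paths()$male
  pd <- propagate(cd, male_diagram(), compounds = comps)
  tab <- path_report(pd)
  expect_equal(nrow(tab), 19 + length(comps))
  expect_equal(sum(tab$type == "compound"), length(comps))
  expect_true(all(tab$n[tab$type == "path"] == 400))
  expect_true(all(is.na(tab$n[tab$type == "compound"])))
  expect_true(all(tab$p >= 1 / 500 & tab$p <= 1))
  # empty compound list: only the simple paths
  pd2 <- propagate(cd, male_diagram())
  expect_equal(nrow(path_report(pd2)), 19)
  csv <- tempfile(fileext = ".csv"); dotf <- tempfile(fileext = ".dot")
  path_report(pd, csv = csv, dot = dotf)
  expect_equal(nrow(utils::read.csv(csv)), nrow(tab))
  expect_match(readLines(dotf)[1], "digraph")
  unlink(c(csv, dotf))
})
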
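simple_diagram <- function() parse_diagram(c("1: a -> b", "2: b -> c"))

test_that("independent traits show near-zero sample correlations", {
  d <- simple_diagram()
  cfg <- generator_config(d, c("1" = 0, "2" = 0), n_pairs = 10000, seed = 1)
  tab <- generate_population(cfg)$table
  R <- stats::cor(tab[, c("a", "b", "c")])
  expect_lt(max(abs(R[upper.tri(R)])), 4 / sqrt(10000))
})

test_that("latent correlations converge to the implied matrix at large n", {
  cfg <- male_model_config(n_pairs = 1e5, observation_scale = FALSE,
                           missing_rates = numeric(0), seed = 2)
  pop <- generate_population(cfg)
  vars <- cfg$diagram$variables
  Rhat <- stats::cor(pop$table[, vars])
  expect_lt(max(abs(Rhat - pop$truth$implied[vars, vars])), 0.02)
  # own vs partner feeding-rate latent correlation matches the implied value
  expect_lt(abs(Rhat["feed_own", "feed_partner"] -
                  pop$truth$implied["feed_own", "feed_partner"]), 0.02)
  # and the implied matrix itself agrees with tracing-rule enumeration
  ref <- reference_path_coefficients(); ref <- ref[ref$sex == "male", ]
  edges <- data.frame(source = ref$source, target = ref$target,
                      label = ref$label, coef = ref$coef)
  oracle <- tracing_implied(edges, pop$truth$psi, variables = vars)
  expect_lt(max(abs(pop$truth$implied - oracle)), 1e-10)
})

test_that("over-explained variance raises an invalid-coefficient error", {
  d <- parse_diagram(c("1: p1 -> y", "2: p2 -> y"))
  expect_error(
    generator_config(d, c("1" = 0.9, "2" = 0.9), n_pairs = 10,
                     exog_correlations = data.frame(a = "p1", b = "p2", rho = 0.9)),
    "residual variance")
  # non-PD exogenous correlation block
  d2 <- parse_diagram(c("1: p1 -> y", "2: p2 -> y", "3: p3 -> y"))
  ex <- data.frame(a = c("p1", "p1", "p2"), b = c("p2", "p3", "p3"),
                   rho = c(0.95, 0.95, -0.95))
  expect_error(generator_config(d2, c("1" = .1, "2" = .1, "3" = .1), 10,
                                exog_correlations = ex),
               "positive definite")
})

test_that("exogenous correlation edges are honoured in the simulated data", {
  d <- parse_diagram(c("1: p1 -> y", "2: p2 -> y"))
  cfg <- generator_config(d, c("1" = 0.3, "2" = 0.3), n_pairs = 50000,
                          exog_correlations = data.frame(a = "p1", b = "p2", rho = 0.4),
                          seed = 5)
  tab <- generate_population(cfg)$table
  expect_equal(stats::cor(tab$p1, tab$p2), 0.4, tolerance = 0.02)
  expect_equal(cfg$truth$psi[["y"]], 1 - (0.09 + 0.09 + 2 * 0.3 * 0.3 * 0.4),
               tolerance = 1e-12)
})

test_that("repeated measures reproduce the configured intraclass correlation", {
  d <- simple_diagram()
  for (icc in c(0.3, 0.66, 0.78)) {
    cfg <- generator_config(d, c("1" = 0.2, "2" = 0.2), n_pairs = 10000,
                            repeat_icc = c(b = icc), seed = 7)
    tab <- generate_population(cfg)$table
    # ICC oracle: variance decomposition of the two repeats
    r1 <- tab$b_rep1; r2 <- tab$b_rep2
    icc_hat <- stats::cor(r1, r2)
    expect_lt(abs(icc_hat - icc), 0.03)
  }
})

test_that("regeneration with the same seed is bit-identical", {
  cfg <- male_model_config(n_pairs = 300, seed = 11)
  a <- generate_population(cfg)
  b <- generate_population(male_model_config(n_pairs = 300, seed = 11))
  expect_identical(a$table, b$table)
  expect_identical(a$truth$implied, b$truth$implied)
  c3 <- generate_population(male_model_config(n_pairs = 300, seed = 12))
  expect_false(identical(a$table, c3$table))
})

test_that("missingness is MCAR at the configured per-variable rates", {
  d <- simple_diagram()
  cfg <- generator_config(d, c("1" = 0.2, "2" = 0.2), n_pairs = 1000, seed = 3)
  tab <- generate_population(cfg)$table
  expect_identical(apply_missingness(tab, c(a = 0, b = 0, c = 0), seed = 1), tab)
  gone <- apply_missingness(tab, c(a = 1), seed = 1)
  expect_true(all(is.na(gone$a)))
  expect_identical(gone$b, tab$b)
  m <- apply_missingness(tab, c(b = 0.3), seed = 99)
  n_obs <- sum(!is.na(m$b))
  expect_lt(abs(n_obs - 700), 3 * sqrt(1000 * 0.3 * 0.7))
  expect_error(apply_missingness(tab, c(nope = 0.5)), "unknown variable")
  expect_error(apply_missingness(tab, c(b = 1.2)), "\\[0, 1\\]")
})

test_that("observation-scale tables respect field constraints", {
  cfg <- male_model_config(n_pairs = 500, observation_scale = TRUE,
                           missing_rates = numeric(0), seed = 13)
  tab <- generate_population(cfg)$table
  expect_true(all(tab$latency_s > 0))
  expect_true(all(tab$nest_stage %in% names(cfg$stage_effects)))
  ok <- !is.na(tab$fledgling_no_obs) & !is.na(tab$brood_size_obs)
  expect_true(all(tab$fledgling_no_obs[ok] <= tab$brood_size_obs[ok]))
  counts <- c(tab$feed_own_visits_d11, tab$feed_own_visits_d14,
              tab$exploration_score_1, tab$exploration_score_2)
  expect_true(all(counts >= 0 & counts == round(counts)))
  expect_true(is.integer(tab$lay_date_obs))
  expect_true(all(tab$fledgling_mass_obs > 0))
  # latent columns retained alongside
  expect_true(all(cfg$diagram$variables %in% names(tab)))
  # latency is monotone decreasing in the aggression latent within stage
  for (s in unique(tab$nest_stage)) {
    sel <- tab$nest_stage == s
    expect_equal(order(tab$latency_s[sel]), order(-tab$aggression[sel]))
  }
})

test_that("trait tables and ground truth round-trip through CSV/JSON", {
  cfg <- male_model_config(n_pairs = 40, seed = 21)
  pop <- generate_population(cfg)
  tmp <- tempfile(fileext = ".csv")
  write_trait_table(pop$table, tmp)
  back <- read_trait_table(tmp)
  expect_equal(back$aggression, pop$table$aggression, tolerance = 1e-12)
  expect_equal(sum(is.na(back)), sum(is.na(pop$table)))
  tj <- tempfile(fileext = ".json")
  write_truth(pop$truth, tj)
  parsed <- jsonlite::read_json(tj)
  expect_equal(unlist(parsed$coefficients[["10"]]), -0.59, ignore_attr = TRUE)
  unlink(c(tmp, tj))
})
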
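# midrank + product-moment transcription of the rank correlation
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

stack_from <- function(dfs, schema) {
  structure(list(datasets = lapply(dfs, survey_table, schema = schema),
                 m = length(dfs), schema = schema),
            class = "imputed_stack")
}

two_var_schema <- function() {
  survey_schema(
    variable_spec("year", "design", "continuous", imputable = FALSE),
    variable_spec("sex", "design", "binary", levels = c("male", "female"), imputable = FALSE),
    variable_spec("age", "design", "continuous", imputable = FALSE),
    variable_spec("y", "covariate", "continuous")
  )
}

test_that("rank correlations match hand values and the midrank oracle", {
  sch <- two_var_schema()
  df <- data.frame(year = 2000, sex = "male", age = c(1, 2, 3), y = c(3, 1, 2))
  st <- stack_from(list(df), sch)
  rep <- correlation_structure(st, c("age", "y"))
  expect_equal(rep$rho, -0.5)
  # strictly monotone pair
  df2 <- data.frame(year = 2000, sex = "male", age = c(5, 1, 9), y = c(50, 10, 90))
  expect_equal(correlation_structure(stack_from(list(df2), sch), c("age", "y"))$rho, 1)
  # random vectors with ties against the brute-force oracle
  set.seed(41)
  for (r in 1:25) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:4, 12, replace = TRUE) + 0.5 * x
    df3 <- data.frame(year = 2000, sex = "male", age = x, y = y)
    got <- correlation_structure(stack_from(list(df3), sch), c("age", "y"))$rho
    expect_equal(got, spearman_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("a constant variable yields NA with a warning; categorical is rejected", {
  sch <- two_var_schema()
  df <- data.frame(year = 2000, sex = "male", age = 30, y = 1:4)
  expect_warning(rep <- correlation_structure(stack_from(list(df), sch), c("age", "y")),
                 "constant")
  expect_true(is.na(rep$rho))
  full <- finrisk_schema()
  dfull <- data.frame(year = 2000, sex = "male", age = 30:33, area = "area1",
                      education = "low", marital = "0", obesity = "0",
                      smoking = "0", hypertension = "0")
  expect_error(correlation_structure(stack_from(list(dfull), full), c("age", "education")),
               "categorical")
})

test_that("simulated future waves preserve the generating correlation structure", {
  cfg <- generator_config(
    waves = data.frame(year = c(1997, 2002, 2007, 2012, 2017),
                       n_male = 400, n_female = 400),
    indicator_models = list(
      obesity = list(intercept = -1.4, men = 0.1, zage = 0.3, zyear = 0.2),
      hypertension = list(intercept = -0.8, men = 0.4, zage = 1.0, zyear = -0.1)),
    missingness_models = list(obesity = list(intercept = -1.2, men = 0.3),
                              hypertension = list(intercept = -1.2, men = 0.3)))
  sch <- survey_schema(
    variable_spec("year", "design", "continuous", imputable = FALSE),
    variable_spec("sex", "design", "binary", levels = c("male", "female"), imputable = FALSE),
    variable_spec("age", "design", "continuous", imputable = FALSE),
    variable_spec("obesity", "outcome-indicator", "binary", levels = c("0", "1")),
    variable_spec("hypertension", "outcome-indicator", "binary", levels = c("0", "1"))
  )
  pop <- generate_population(cfg, seed = 51, schema = sch)
  tab <- impose_missingness(pop$table, cfg, seed = 52)
  fc <- make_forecast(cfg, 2022)
  comb <- append_future(tab, build_pseudo_sample(2022, 800, fc, sch))
  stack <- fcs_impute(comb, m = 5, iterations = 3, seed = 53)
  rep <- correlation_structure(stack, c("age", "obesity", "hypertension"))
  # the strong age-hypertension association persists into the pseudo-wave
  # within the envelope of the observed waves
  for (pair in list(c("age", "hypertension"), c("age", "obesity"),
                    c("obesity", "hypertension"))) {
    rho_obs <- rep$rho[rep$year < 2022 & rep$var1 == pair[1] & rep$var2 == pair[2]]
    rho_fut <- rep$rho[rep$year == 2022 & rep$var1 == pair[1] & rep$var2 == pair[2]]
    expect_gte(rho_fut, min(rho_obs) - 0.1)
    expect_lte(rho_fut, max(rho_obs) + 0.1)
  }
  rho_ah <- rep$rho[rep$year == 2022 & rep$var1 == "age" & rep$var2 == "hypertension"]
  expect_gt(rho_ah, 0.2)
})

test_that("hold-out validation reports self-consistent intervals and flags", {
  cfg <- linear_trend_config(n_per_sex = 300)
  pop <- generate_population(cfg, seed = 61, schema = obesity_schema())
  tab <- impose_missingness(pop$table, cfg, seed = 62)
  rep <- holdout_validation(tab, 2017, m = 4, iterations = 2, seed = 63)
  expect_equal(nrow(rep), 2L)  # one row per sex
  expect_equal(rep$included,
               rep$observed >= rep$proj_low & rep$observed <= rep$proj_high)
  expect_true(all(rep$obs_low <= rep$observed & rep$observed <= rep$obs_high))
  expect_error(holdout_validation(tab, 1234, m = 4, iterations = 2), "not present")
  two_wave <- survey_table(as.data.frame(tab[tab$year %in% c(2012, 2017), ]),
                           attr(tab, "schema"))
  expect_error(holdout_validation(two_wave, 2017, m = 4, iterations = 2),
               "at least 2 remaining")
})

test_that("sensitivity comparison needs two variants and is seed-stable", {
  cfg <- linear_trend_config(n_per_sex = 200)
  pop <- generate_population(cfg, seed = 71, schema = obesity_schema())
  tab <- impose_missingness(pop$table, cfg, seed = 72)
  fc <- make_forecast(cfg, 2022)
  comb <- append_future(tab, build_pseudo_sample(2022, 300, fc, obesity_schema()))
  expect_error(sensitivity_compare(comb, "obesity", list(a = list(term_main("year")))),
               "at least 2")
  res <- sensitivity_compare(comb, "obesity",
                             list(a = list(term_main("year")),
                                  b = list(term_main("year"))),
                             m = 3, iterations = 2, seed = 5)
  # identical variants under a shared seed give identical projections
  a <- res[res$variant == "a", c("year", "sex", "estimate")]
  b <- res[res$variant == "b", c("year", "sex", "estimate")]
  expect_equal(a$estimate, b$estimate)
  expect_true(all(res$diff_vs_first[res$variant == "b"] == 0))
})
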
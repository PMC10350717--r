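test_that("indicator definitions use inclusive clinical cutoffs", {
  d <- derive_indicators(bmi = c(30, 29.9, 35), sbp = c(120, 139, 150),
                         dbp = c(70, 89, 70), bp_medication = c(FALSE, FALSE, FALSE))
  expect_equal(d$obesity, c(1L, 0L, 1L))
  expect_equal(d$hypertension, c(0L, 0L, 1L))
  # medication alone is enough for hypertension
  expect_equal(derive_indicators(25, 120, 70, TRUE)$hypertension, 1L)
  expect_equal(derive_indicators(25, 140, 70, FALSE)$hypertension, 1L)
  expect_equal(derive_indicators(25, 120, 90, FALSE)$hypertension, 1L)
})

test_that("the default configuration reproduces the five published wave sizes", {
  cfg <- finrisk_like_config()
  expect_equal(cfg$waves$year, c(1997, 2002, 2007, 2012, 2017))
  expect_equal(cfg$waves$n_male, c(5000, 4999, 4000, 4000, 1635))
  expect_equal(cfg$waves$n_female, c(5000, 5000, 4000, 4000, 1542))
  pop <- generate_population(
    generator_config(waves = data.frame(year = 2017, n_male = 1635, n_female = 1542)),
    seed = 1)
  expect_equal(sum(pop$table$sex == "male"), 1635L)
  expect_equal(sum(pop$table$sex == "female"), 1542L)
})

test_that("empirical prevalences track the enumerated truth at n = 5000", {
  cfg <- generator_config(waves = data.frame(year = 2007, n_male = 5000, n_female = 5000))
  pop <- generate_population(cfg, seed = 11)
  for (ind in c("obesity", "smoking", "hypertension")) {
    for (sx in c("male", "female")) {
      truth <- pop$truth$prevalence[pop$truth$indicator == ind & pop$truth$sex == sx]
      emp <- mean(pop$table[[ind]][pop$table$sex == sx] == "1")
      expect_lt(abs(emp - truth), 3 * sqrt(truth * (1 - truth) / 5000))
    }
  }
  expect_true(all(pop$truth$prevalence >= 0 & pop$truth$prevalence <= 1))
})

test_that("a probability-zero indicator yields all zeros and zero truth", {
  cfg <- generator_config(waves = data.frame(year = 2007, n_male = 200, n_female = 200),
                          indicator_models = list(obesity = list(intercept = -40)))
  pop <- generate_population(cfg, seed = 3, schema = obesity_schema())
  expect_true(all(pop$table$obesity == "0"))
  expect_lt(max(pop$truth$prevalence[pop$truth$indicator == "obesity"]), 1e-10)
})

test_that("masking calibration hits the published 1997 male obesity cell", {
  cfg <- generator_config(waves = data.frame(year = 1997, n_male = 5000, n_female = 5000))
  pop <- generate_population(cfg, seed = 21)
  tab <- impose_missingness(pop$table, cfg, seed = 22)
  frac <- mean(is.na(tab$obesity[tab$sex == "male"]))
  expect_lt(abs(frac - 0.321), 3 * sqrt(0.321 * 0.679 / 5000))
})

test_that("masking respects design variables and degenerate coefficients", {
  cfg <- generator_config(waves = data.frame(year = 2007, n_male = 300, n_female = 300),
                          missingness_models = list(obesity = list(intercept = -40)))
  pop <- generate_population(cfg, seed = 5)
  tab <- impose_missingness(pop$table, cfg, seed = 6)
  expect_equal(sum(is.na(tab$obesity)), 0L)
  expect_false(anyNA(tab$year) || anyNA(tab$sex) || anyNA(tab$age))
  # referencing an imputable variable breaks MAR and is refused at config time
  expect_error(
    generator_config(waves = data.frame(year = 2007, n_male = 10, n_female = 10),
                     missingness_models = list(obesity = list(intercept = 0, smoking = 1))),
    "only use design variables")
})

test_that("a positive year coefficient gives non-decreasing expected masking", {
  mm <- default_missingness_models()$obesity
  p <- plogis(mm$intercept + mm$men + mm$zyear * ((c(1997, 2002, 2007, 2012) - 2007) / 10))
  expect_true(all(diff(p) > 0))
  # and empirically across two waves far apart
  cfg <- generator_config(waves = data.frame(year = c(1997, 2012),
                                             n_male = 2000, n_female = 2000))
  tab <- impose_missingness(generate_population(cfg, seed = 7)$table, cfg, seed = 8)
  ms <- missingness_summary(tab, "obesity")
  expect_gt(ms$pct_missing[ms$year == 2012 & ms$sex == "male"],
            ms$pct_missing[ms$year == 1997 & ms$sex == "male"])
})

test_that("masking is MAR by construction: masked values carry no extra signal", {
  # regression of the mask on the true (pre-masking) value given the design
  # variables: coefficient consistent with zero across replicates
  coefs <- numeric(20)
  for (r in 1:20) {
    cfg <- linear_trend_config(n_per_sex = 400)
    pop <- generate_population(cfg, seed = 300 + r, schema = obesity_schema())
    tab <- impose_missingness(pop$table, cfg, seed = 600 + r)
    mask <- as.numeric(is.na(tab$obesity))
    truth <- as.numeric(pop$table$obesity == "1")
    fit <- glm(mask ~ truth + sex + age + year, family = binomial(),
               data = data.frame(mask, truth, sex = tab$sex, age = tab$age, year = tab$year))
    coefs[r] <- coef(fit)[["truth"]]
  }
  expect_lt(abs(mean(coefs)), 3 * sd(coefs) / sqrt(20))
})

test_that("the emulated forecast behaves like an aging population projection", {
  cfg <- linear_trend_config()
  fc <- make_forecast(cfg, c(2020, 2025))
  expect_s3_class(fc, "population_forecast")
  expect_true(all(fc$count > 0))
  expect_setequal(unique(fc$year), c(2020, 2025))
  # identity growth rule: future margins equal the baseline pyramid
  fid <- make_forecast(cfg, c(2020, 2025), growth_rule = function(y, s, a) 1)
  m20 <- fid$count[fid$year == 2020]
  m25 <- fid$count[fid$year == 2025]
  expect_equal(m20, m25)
  # a rule shifting mass toward older ages raises the allocated mean age
  fold <- make_forecast(cfg, 2025, growth_rule = function(y, s, a) 1 + 0.05 * (a - 25))
  a_id <- allocate_cells(fid, 2025, 5000)
  a_old <- allocate_cells(fold, 2025, 5000)
  expect_gt(weighted.mean(a_old$age, a_old$count), weighted.mean(a_id$age, a_id$count))
  expect_error(make_forecast(cfg, 2025, growth_rule = function(y, s, a) -1), "negative")
  expect_error(make_forecast(cfg, 2010), "after the last")
})

test_that("the continuous measurement layer feeds the derived indicators", {
  cfg <- generator_config(waves = data.frame(year = 2007, n_male = 500, n_female = 500),
                          continuous_layer = default_continuous_layer())
  pop <- generate_population(cfg, seed = 13)
  expect_false(anyNA(pop$table$obesity))
  p_ob <- mean(pop$table$obesity == "1")
  truth <- pop$truth$prevalence[pop$truth$indicator == "obesity"]
  expect_lt(abs(p_ob - mean(truth)), 0.05)
})
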
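mcar_table <- function(n = 400, miss = 0.3, seed = 1, p = 0.4) {
  set.seed(seed)
  df <- data.frame(year = sample(c(2000, 2005, 2010), n, replace = TRUE),
                   sex = sample(c("male", "female"), n, replace = TRUE),
                   age = sample(25:64, n, replace = TRUE),
                   smoking = as.character(rbinom(n, 1, p)))
  df$smoking[runif(n) < miss] <- NA
  survey_table(df, tiny_schema())
}

test_that("initialization fills from the observed support only", {
  tab <- tiny_table()
  expect_equal(as.data.frame(fcs_initialize(tab)), as.data.frame(tab))
  # binary variable observed only as 1: every fill is 1
  df <- data.frame(year = 2000, sex = "male", age = 30,
                   smoking = c("1", "1", NA, NA))
  tab2 <- survey_table(df, tiny_schema())
  filled <- fcs_initialize(tab2)
  expect_true(all(filled$smoking == "1"))
  # fully missing variable cannot be initialized
  df$smoking <- NA_character_
  expect_error(fcs_initialize(survey_table(df, tiny_schema())), "no observed values")
})

test_that("a complete input yields m identical copies and empty traces", {
  tab <- tiny_table(n = 40)
  stack <- fcs_impute(tab, m = 3, iterations = 2, seed = 1)
  for (i in 1:3) expect_equal(as.data.frame(complete_data(stack, i)), as.data.frame(tab))
  expect_equal(nrow(stack$traces), 0L)
  expect_message(trace_summary(stack), "empty")
})

test_that("originally observed cells are never altered and gaps are filled", {
  tab <- mcar_table(seed = 3)
  stack <- fcs_impute(tab, m = 3, iterations = 2, seed = 9)
  obs <- !is.na(tab$smoking)
  for (i in 1:3) {
    d <- complete_data(stack, i)
    expect_false(anyNA(d$smoking))
    expect_identical(as.character(d$smoking[obs]), as.character(tab$smoking[obs]))
    # identical across datasets and equal to the input wherever observed
    expect_identical(as.data.frame(d)[obs, setdiff(names(d), "smoking")],
                     as.data.frame(tab)[obs, setdiff(names(tab), "smoking")])
  }
})

test_that("the same master seed reproduces the stack exactly", {
  tab <- mcar_table(seed = 4)
  s1 <- fcs_impute(tab, m = 3, iterations = 2, seed = 123)
  s2 <- fcs_impute(tab, m = 3, iterations = 2, seed = 123)
  for (i in 1:3) {
    expect_identical(as.data.frame(complete_data(s1, i)), as.data.frame(complete_data(s2, i)))
  }
  expect_identical(s1$traces, s2$traces)
  s3 <- fcs_impute(tab, m = 3, iterations = 2, seed = 124)
  expect_false(identical(as.data.frame(complete_data(s1, 1)),
                         as.data.frame(complete_data(s3, 1))))
})

test_that("engine RNG does not disturb the caller's random stream", {
  tab <- mcar_table(seed = 5)
  set.seed(42); a <- runif(1)
  set.seed(42); invisible(fcs_impute(tab, m = 2, iterations = 1, seed = 7)); b <- runif(1)
  expect_identical(a, b)
})

test_that("traces have m x iterations rows per incomplete variable", {
  tab <- mcar_table(seed = 6)
  stack <- fcs_impute(tab, m = 2, iterations = 3, seed = 2)
  tr <- trace_summary(stack)
  expect_equal(nrow(tr), 6L)
  expect_setequal(tr$iteration, 1:3)
  # single missing cell: zero trace variance
  df <- data.frame(year = c(2000, 2000, 2005, 2005, 2010, 2010),
                   sex = rep(c("male", "female"), 3), age = 30:35,
                   smoking = c("1", "0", "1", NA, "0", "1"))
  st <- fcs_impute(survey_table(df, tiny_schema()), m = 2, iterations = 2, seed = 3)
  expect_true(all(st$traces$variance == 0))
})

test_that("paper-scale defaults are m = 50 datasets and 10 iterations", {
  expect_equal(eval(formals(fcs_impute)$m), 50L)
  expect_equal(eval(formals(fcs_impute)$iterations), 10L)
})

test_that("an incomplete variable without a model is refused", {
  tab <- mcar_table(seed = 8)
  expect_error(fcs_impute(tab, models = list(), m = 2, iterations = 1, seed = 1),
               "no imputation model")
})

test_that("pseudo-wave fitting sets contain only originally observed outcomes", {
  tab <- mcar_table(n = 300, seed = 9)
  fc <- population_forecast(expand.grid(year = 2015, sex = c("male", "female"),
                                        age = 25:64, count = 2))
  ps <- build_pseudo_sample(2015, 100, fc, tiny_schema())
  comb <- append_future(tab, ps)
  stack <- fcs_impute(comb, m = 2, iterations = 2, seed = 5)
  pseudo_rows <- comb$.source == "pseudo"
  # 100% of pseudo-wave cells needed imputation ...
  expect_true(all(stack$missing$smoking[pseudo_rows]))
  # ... and none of them is in the fitting mask (originally observed)
  expect_false(any(!stack$missing$smoking & pseudo_rows))
  for (i in 1:2) expect_false(anyNA(complete_data(stack, i)$smoking))
})

test_that("one-variable engine run matches a direct observed-data draw in law", {
  # with a single imputable variable and one iteration, the chained
  # equations collapse to: fit on observed, draw for missing
  set.seed(101)
  reps <- 200
  eng <- numeric(reps); direct <- numeric(reps)
  n_eng <- 0; n_dir <- 0
  for (r in 1:reps) {
    tab <- mcar_table(n = 150, miss = 0.4, seed = 1000 + r, p = 0.35)
    stack <- fcs_impute(tab, m = 2, iterations = 1, seed = 2000 + r)
    mis <- is.na(tab$smoking)
    eng[r] <- mean(complete_data(stack, 1)$smoking[mis] == "1")
    X <- build_design(as.data.frame(tab), lapply(c("year", "sex", "age"), term_main),
                      tiny_schema())$X
    fit <- fit_binary_logistic(X[!mis, ], as.numeric(tab$smoking[!mis] == "1"))
    direct[r] <- mean(draw_binary_imputation(fit, X[mis, , drop = FALSE]))
    n_eng <- n_eng + sum(mis); n_dir <- n_dir + sum(mis)
  }
  # two-sample comparison of imputed prevalences across replicates
  tt <- t.test(eng, direct)
  expect_gt(tt$p.value, 0.01)
})

test_that("chains show no first-half vs second-half drift when well specified", {
  tab <- mcar_table(n = 800, miss = 0.4, seed = 12)
  stack <- fcs_impute(tab, m = 5, iterations = 20, seed = 31)
  tr <- trace_summary(stack)
  rejections <- 0
  for (d in 1:5) {
    m1 <- tr$mean[tr$dataset == d & tr$iteration <= 10]
    m2 <- tr$mean[tr$dataset == d & tr$iteration > 10]
    if (t.test(m1, m2)$p.value < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 1)
})
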
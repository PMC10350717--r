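# Shared fixtures: all test data is generated in code.

# minimal schema: design variables + one binary indicator
tiny_schema <- function() {
  survey_schema(
    variable_spec("year", "design", "continuous", imputable = FALSE),
    variable_spec("sex", "design", "binary", levels = c("male", "female"), imputable = FALSE),
    variable_spec("age", "design", "continuous", imputable = FALSE),
    variable_spec("smoking", "outcome-indicator", "binary", levels = c("0", "1"))
  )
}

# design + covariates + a single indicator; used by the recovery and
# coverage simulations so only one variable needs imputation
obesity_schema <- function() {
  survey_schema(
    variable_spec("year", "design", "continuous", imputable = FALSE),
    variable_spec("sex", "design", "binary", levels = c("male", "female"), imputable = FALSE),
    variable_spec("age", "design", "continuous", imputable = FALSE),
    variable_spec("area", "covariate", "categorical", levels = paste0("area", 1:5)),
    variable_spec("education", "covariate", "categorical", levels = c("low", "middle", "high")),
    variable_spec("marital", "covariate", "binary", levels = c("0", "1")),
    variable_spec("obesity", "outcome-indicator", "binary", levels = c("0", "1"))
  )
}

# small complete survey table with a known seed
tiny_table <- function(n = 60, years = c(2000, 2005, 2010), seed = 42) {
  set.seed(seed)
  df <- data.frame(
    year = sample(years, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = sample(25:64, n, replace = TRUE),
    smoking = as.character(rbinom(n, 1, 0.3))
  )
  survey_table(df, tiny_schema())
}

# generator config with a linear logit year trend on a single indicator and
# MAR missingness through sex and age
linear_trend_config <- function(n_per_sex = 500,
                                years = c(1997, 2002, 2007, 2012, 2017),
                                b_year = 0.25, extra = list()) {
  ind <- utils::modifyList(
    list(intercept = -1.4, men = 0.2, zage = 0.3, zyear = b_year), extra)
  generator_config(
    waves = data.frame(year = years, n_male = n_per_sex, n_female = n_per_sex),
    indicator_models = list(obesity = ind),
    missingness_models = list(obesity = list(intercept = -1.0, men = 0.4, zage = 0.25))
  )
}

# main-effects model list for the obesity-only schema
obesity_models <- function(schema = obesity_schema()) default_models(schema)
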
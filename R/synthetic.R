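#' Synthetic repeated cross-sectional survey generator
#'
#' Configuration for generating survey data with the statistical structure
#' the projection method assumes: binary indicators generated on the logit
#' scale with known sex/age/calendar-time effects, discrete covariates with
#' optionally age/year-dependent distributions, and missing-at-random item
#' non-response driven by design variables only. The implied "true"
#' prevalences are available in closed form by enumeration, so recovery
#' and coverage of the whole pipeline can be tested without any external
#' data.
#'
#' Continuous age and calendar year enter all generating models through the
#' centered/scaled transforms `zage = (age - 45) / 10` and
#' `zyear = (year - 2007) / 10`, so coefficients are per decade of age or
#' calendar time; `men` is a 0/1 indicator of male sex.
#'
#' @param waves Data frame with columns `year`, `n_male`, `n_female`
#'   (invited individuals per sex and wave); wave years must be strictly
#'   increasing.
#' @param age_range Inclusive age bounds; ages are drawn uniformly on the
#'   integer grid.
#' @param covariate_model List with `area_probs` (length-5 probabilities),
#'   `education(zage, zyear)` returning a 3-column probability matrix
#'   (low/middle/high) and `marital(zage, zyear)` returning P(marital = 1).
#' @param indicator_models Named list (obesity, smoking, hypertension) of
#'   coefficient lists: `intercept`, `men`, `zage`, `zyear`, `zyear2`,
#'   `zage_zyear`, `men_zage`, optional named level-effect vectors
#'   `edu`, `area`, scalar `marital`, and an optional
#'   `shock = list(year =, delta =)` adding an abrupt logit-scale level
#'   shift in a single wave (for negative-control experiments).
#' @param missingness_models Named list per maskable variable of logit
#'   coefficients on `intercept`, `men`, `zage`, `zyear` only — referencing
#'   an imputable variable would break the missing-at-random construction
#'   and is rejected.
#' @param continuous_layer Optional list of generator functions
#'   `bmi(n, men, zage)`, `sbp(n, men, zage)`, `dbp(n, men, zage)`,
#'   `bp_medication(n, men, zage)`; when present, obesity and hypertension
#'   are derived from these via [derive_indicators()] instead of the logit
#'   models.
#' @return A `generator_config`.
#' @export
generator_config <- function(waves, age_range = c(25, 64),
                             covariate_model = default_covariate_model(),
                             indicator_models = default_indicator_models(),
                             missingness_models = default_missingness_models(),
                             continuous_layer = NULL) {
  stopifnot(all(c("year", "n_male", "n_female") %in% names(waves)))
  if (any(diff(waves$year) <= 0)) stop("wave years must be strictly increasing", call. = FALSE)
  if (abs(sum(covariate_model$area_probs) - 1) > 1e-8) {
    stop("area probabilities must sum to 1", call. = FALSE)
  }
  allowed <- c("intercept", "men", "zage", "zyear")
  for (v in names(missingness_models)) {
    bad <- setdiff(names(missingness_models[[v]]), allowed)
    if (length(bad)) {
      stop("missingness model for '", v, "' may only use design variables (",
           paste(allowed, collapse = ", "), "); found: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(waves = waves, age_range = age_range,
                 covariate_model = covariate_model,
                 indicator_models = indicator_models,
                 missingness_models = missingness_models,
                 continuous_layer = continuous_layer),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_covariate_model <- function() {
  list(
    area_probs = rep(0.2, 5),
    education = function(zage, zyear) {
      lp_mid <- 0.25 + 0.15 * zyear - 0.15 * zage
      lp_high <- 0.05 + 0.35 * zyear - 0.25 * zage
      denom <- 1 + exp(lp_mid) + exp(lp_high)
      cbind(low = 1 / denom, middle = exp(lp_mid) / denom, high = exp(lp_high) / denom)
    },
    marital = function(zage, zyear) stats::plogis(0.5 + 0.4 * zage - 0.1 * zyear)
  )
}

#' @rdname generator_config
#' @export
default_indicator_models <- function() {
  list(
    obesity = list(intercept = -1.45, men = 0.05, zage = 0.30, zyear = 0.25,
                   edu = c(low = 0, middle = -0.10, high = -0.30)),
    smoking = list(intercept = -1.30, men = 0.35, zage = -0.15, zyear = -0.30,
                   zyear2 = -0.12, edu = c(low = 0, middle = -0.20, high = -0.50),
                   marital = -0.10),
    hypertension = list(intercept = -0.75, men = 0.45, zage = 1.00, zyear = -0.15)
  )
}

#' @rdname generator_config
#' @export
default_missingness_models <- function() {
  # logit-scale coefficients solved from the published missingness table:
  # women-1997 cell fixes the intercept, the men-vs-women 1997 contrast the
  # male offset, and the men 1997 -> 2012 change the per-decade year slope
  list(
    obesity = list(intercept = -0.6497, men = 0.3602, zyear = 0.4590),
    smoking = list(intercept = -0.7774, men = 0.3607, zyear = 0.3102),
    hypertension = list(intercept = -0.6738, men = 0.3602, zyear = 0.4349),
    marital = list(intercept = -2.2, men = 0.2, zyear = 0.2),
    education = list(intercept = -2.2, men = 0.2, zyear = 0.2),
    area = list(intercept = -2.2, men = 0.2, zyear = 0.2)
  )
}

#' Default configuration emulating five Finnish survey waves
#'
#' Wave years 1997-2017 at five-year intervals with the published invited
#' sample sizes per sex, ages 25-64, five areas, three education levels,
#' and missingness calibrated to the published percentages.
#'
#' @return A `generator_config`.
#' @export
finrisk_like_config <- function() {
  generator_config(
    waves = data.frame(year = c(1997, 2002, 2007, 2012, 2017),
                       n_male = c(5000, 4999, 4000, 4000, 1635),
                       n_female = c(5000, 5000, 4000, 4000, 1542))
  )
}

zage_of <- function(age) (age - 45) / 10
zyear_of <- function(year) (year - 2007) / 10

indicator_lp <- function(coefs, men, zage, zyear, edu = NULL, marital = NULL, area = NULL) {
  g <- function(nm) if (is.null(coefs[[nm]])) 0 else coefs[[nm]]
  lp <- g("intercept") + g("men") * men + g("zage") * zage + g("zyear") * zyear +
    g("zyear2") * zyear^2 + g("zage_zyear") * zage * zyear + g("men_zage") * men * zage
  if (!is.null(coefs$edu) && !is.null(edu)) lp <- lp + unname(coefs$edu[edu])
  if (!is.null(coefs$marital) && !is.null(marital)) lp <- lp + coefs$marital * marital
  if (!is.null(coefs$area) && !is.null(area)) lp <- lp + unname(coefs$area[area])
  if (!is.null(coefs$shock)) {
    # abrupt level shift in one wave: the kind of unexpected change a
    # trend-following projection cannot anticipate
    lp <- lp + coefs$shock$delta * (abs(zyear - zyear_of(coefs$shock$year)) < 1e-9)
  }
  lp
}

#' Derive obesity and hypertension indicators from measurements
#'
#' Obesity is body mass index of at least 30; hypertension is systolic
#' blood pressure of at least 140 mmHg, or diastolic of at least 90 mmHg,
#' or current use of blood-pressure medication. Boundaries are inclusive.
#'
#' @param bmi Body mass index (kg/m^2).
#' @param sbp,dbp Systolic / diastolic blood pressure (mmHg).
#' @param bp_medication Logical or 0/1 medication use.
#' @return Data frame with integer columns `obesity`, `hypertension`.
#' @export
derive_indicators <- function(bmi, sbp, dbp, bp_medication) {
  data.frame(obesity = as.integer(bmi >= 30),
             hypertension = as.integer(sbp >= 140 | dbp >= 90 | as.logical(bp_medication)))
}

#' Generating-model prevalences by enumeration
#'
#' The "true" prevalence implied by a generator configuration for each
#' (indicator, year, sex), obtained by exact enumeration over the discrete
#' covariate space (integer ages uniform on the age range, education and
#' marital status at their model probabilities, areas at their fixed
#' probabilities). Years need not be wave years — the generating model
#' extends smoothly in calendar time, which is what projection recovery
#' tests rely on.
#'
#' @param config A `generator_config`.
#' @param years Calendar years to evaluate.
#' @param indicators Indicator names (default all configured).
#' @return Data frame `indicator`, `year`, `sex`, `prevalence`.
#' @export
config_truth <- function(config, years, indicators = names(config$indicator_models)) {
  if (!is.null(config$continuous_layer)) {
    return(mc_truth(config, years, indicators))
  }
  ages <- seq(config$age_range[1L], config$age_range[2L])
  cm <- config$covariate_model
  rows <- list()
  for (ind in indicators) {
    coefs <- config$indicator_models[[ind]]
    for (yr in years) for (sx in c("male", "female")) {
      men <- as.numeric(sx == "male")
      zy <- zyear_of(yr)
      za <- zage_of(ages)
      edu_p <- cm$education(za, zy)              # |ages| x 3
      mar_p <- cm$marital(za, zy)                # |ages|
      prev <- 0
      for (e in 1:3) for (mval in 0:1) for (a in 1:5) {
        lp <- indicator_lp(coefs, men, za, zy,
                           edu = rep(e, length(ages)), marital = mval,
                           area = rep(a, length(ages)))
        wcell <- (1 / length(ages)) * edu_p[, e] *
          ifelse(mval == 1, mar_p, 1 - mar_p) * cm$area_probs[a]
        prev <- prev + sum(wcell * stats::plogis(lp))
      }
      rows[[length(rows) + 1L]] <- data.frame(indicator = ind, year = yr, sex = sx,
                                              prevalence = prev)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Monte-Carlo marginalization (1e5 draws) for configs whose indicators come
# from the continuous measurement layer
mc_truth <- function(config, years, indicators, ndraw = 1e5) {
  rows <- list()
  for (yr in years) for (sx in c("male", "female")) {
    men <- as.numeric(sx == "male")
    ages <- sample(seq(config$age_range[1L], config$age_range[2L]), ndraw, replace = TRUE)
    za <- zage_of(ages)
    cl <- config$continuous_layer
    der <- derive_indicators(cl$bmi(ndraw, men, za), cl$sbp(ndraw, men, za),
                             cl$dbp(ndraw, men, za), cl$bp_medication(ndraw, men, za))
    for (ind in indicators) {
      prev <- if (ind %in% names(der)) mean(der[[ind]]) else {
        mean(stats::plogis(indicator_lp(config$indicator_models[[ind]], men, za, zyear_of(yr))))
      }
      rows[[length(rows) + 1L]] <- data.frame(indicator = ind, year = yr, sex = sx,
                                              prevalence = prev)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a fully observed synthetic survey population
#'
#' Draws, per wave and sex, the invited individuals: uniform integer ages,
#' covariates from the covariate model, then binary indicators from the
#' logit-scale indicator models (or from the continuous measurement layer
#' when configured). Returns the fully observed table plus the implied true
#' prevalences at the wave years.
#'
#' @param config A `generator_config`.
#' @param seed Integer seed.
#' @param schema Target schema (default [finrisk_schema()] with the
#'   config's age range).
#' @return List with `table` (a `survey_table` without missing values) and
#'   `truth` (see [config_truth()]).
#' @export
generate_population <- function(config, seed = NULL, schema = finrisk_schema(config$age_range)) {
  if (!is.null(seed)) set.seed(seed)
  cm <- config$covariate_model
  blocks <- list()
  for (i in seq_len(nrow(config$waves))) {
    yr <- config$waves$year[i]
    for (sx in c("male", "female")) {
      n <- if (sx == "male") config$waves$n_male[i] else config$waves$n_female[i]
      if (n == 0L) next
      age <- sample(seq(config$age_range[1L], config$age_range[2L]), n, replace = TRUE)
      men <- as.numeric(sx == "male")
      za <- zage_of(age)
      zy <- zyear_of(yr)
      edu_p <- cm$education(za, zy)
      edu <- vapply(seq_len(n), function(j) sample.int(3L, 1L, prob = edu_p[j, ]), integer(1))
      marital <- stats::rbinom(n, 1L, cm$marital(za, zy))
      area <- sample.int(5L, n, replace = TRUE, prob = cm$area_probs)
      df <- data.frame(year = yr, sex = sx, age = age,
                       area = paste0("area", area),
                       education = c("low", "middle", "high")[edu],
                       marital = as.character(marital))
      if (!is.null(config$continuous_layer)) {
        cl <- config$continuous_layer
        der <- derive_indicators(cl$bmi(n, men, za), cl$sbp(n, men, za),
                                 cl$dbp(n, men, za), cl$bp_medication(n, men, za))
        df$obesity <- as.character(der$obesity)
        df$hypertension <- as.character(der$hypertension)
        for (ind in setdiff(names(config$indicator_models), names(der))) {
          p <- stats::plogis(indicator_lp(config$indicator_models[[ind]], men, za, zy,
                                          edu = edu, marital = marital, area = area))
          df[[ind]] <- as.character(stats::rbinom(n, 1L, p))
        }
      } else {
        for (ind in names(config$indicator_models)) {
          p <- stats::plogis(indicator_lp(config$indicator_models[[ind]], men, za, zy,
                                          edu = edu, marital = marital, area = area))
          df[[ind]] <- as.character(stats::rbinom(n, 1L, p))
        }
      }
      blocks[[length(blocks) + 1L]] <- df
    }
  }
  tab <- do.call(rbind, blocks)
  for (v in schema_names(schema)) if (!v %in% names(tab)) tab[[v]] <- NA_character_
  tab <- tab[intersect(names(tab), schema_names(schema))]  # covariates the schema omits are marginalized out
  list(table = survey_table(tab, schema),
       truth = config_truth(config, config$waves$year))
}

#' Impose missing-at-random item non-response
#'
#' Masks each maskable cell independently with probability
#' `plogis(intercept + men * men + zage * zage + zyear * zyear)` from the
#' variable's missingness model. Because the models reference only design
#' variables (enforced at configuration), the masking is missing at random
#' by construction. Design variables are never masked.
#'
#' @param table A fully observed `survey_table`.
#' @param config A `generator_config`.
#' @param seed Integer seed.
#' @return The table with missing values.
#' @export
impose_missingness <- function(table, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  schema <- attr(table, "schema")
  men <- as.numeric(table$sex == "male")
  za <- zage_of(table$age)
  zy <- zyear_of(table$year)
  for (v in names(config$missingness_models)) {
    spec <- schema[[v]]
    if (is.null(spec) || !spec$imputable) next
    mm <- config$missingness_models[[v]]
    g <- function(nm) if (is.null(mm[[nm]])) 0 else mm[[nm]]
    p <- stats::plogis(g("intercept") + g("men") * men + g("zage") * za + g("zyear") * zy)
    mask <- stats::runif(nrow(table)) < p
    table[[v]][mask] <- NA
  }
  table
}

#' Emulated population forecast
#'
#' Builds a forecast table over (year, sex, single year of age) from a
#' smooth baseline age pyramid multiplied by a growth rule, emulating an
#' official national population projection without downloading one. The
#' default rule applies mild total growth plus a gradual shift of mass
#' toward older ages.
#'
#' @param config A `generator_config` (supplies the age range and the last
#'   wave year the rule is anchored to).
#' @param future_years Years to project (after the last wave).
#' @param growth_rule Function `(year, sex, age) -> multiplier` (>= 0).
#' @return A `population_forecast`.
#' @export
make_forecast <- function(config, future_years,
                          growth_rule = default_growth_rule(max(config$waves$year))) {
  if (any(future_years <= max(config$waves$year))) {
    stop("future_years must lie after the last observed wave", call. = FALSE)
  }
  ages <- seq(config$age_range[1L], config$age_range[2L])
  rows <- expand.grid(year = future_years, sex = c("male", "female"), age = ages,
                      stringsAsFactors = FALSE)
  baseline <- 60000 * exp(-((rows$age - 52)^2) / 2500) *
    ifelse(rows$sex == "male", 1.0, 0.98)
  mult <- mapply(growth_rule, rows$year, rows$sex, rows$age)
  if (any(mult < 0)) stop("growth rule produced a negative multiplier", call. = FALSE)
  population_forecast(data.frame(rows, count = baseline * mult))
}

#' @rdname make_forecast
#' @param anchor_year Year at which the rule's multiplier is 1.
#' @export
default_growth_rule <- function(anchor_year) {
  function(year, sex, age) {
    dt <- (year - anchor_year) / 10
    (1 + 0.02 * dt) * (1 + 0.015 * dt * (age - 45) / 10)
  }
}

#' A simple continuous measurement layer
#'
#' Optional generators for BMI and blood pressure used to exercise
#' [derive_indicators()]: log-normal BMI and normal blood pressures with
#' age and sex effects, medication probability rising with age.
#'
#' @return A list suitable for `generator_config(continuous_layer = ...)`.
#' @export
default_continuous_layer <- function() {
  list(
    bmi = function(n, men, zage) exp(stats::rnorm(n, log(26) + 0.02 * zage + 0.005 * men, 0.15)),
    sbp = function(n, men, zage) stats::rnorm(n, 128 + 6 * zage + 3 * men, 14),
    dbp = function(n, men, zage) stats::rnorm(n, 79 + 2.5 * zage + 2 * men, 10),
    bp_medication = function(n, men, zage) stats::rbinom(n, 1L, stats::plogis(-2.5 + 0.9 * zage))
  )
}
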
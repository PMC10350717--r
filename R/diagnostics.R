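#' Spearman correlation structure across waves
#'
#' Rank correlations between indicator/covariate pairs, per survey wave,
#' averaged over the m imputed datasets. Used to check that relationships
#' between variables in fully simulated future waves remain similar to
#' those in the observed waves (e.g. the age-hypertension correlation
#' should persist while unrelated indicators stay near zero). Ties are
#' handled by midranks. Binary variables are coded 0/1; categorical
#' variables with more than two levels must be dummy-selected by the
#' caller and are rejected here.
#'
#' @param stack An `imputed_stack`.
#' @param variables Numeric-codable variables (continuous or binary).
#' @return Data frame `year`, `var1`, `var2`, `rho` (averaged over
#'   datasets); a pair constant within a wave yields `NA` with a warning.
#' @export
correlation_structure <- function(stack, variables) {
  schema <- stack$schema
  for (v in variables) {
    spec <- schema[[v]]
    if (is.null(spec)) stop("unknown variable '", v, "'", call. = FALSE)
    if (spec$vtype == "categorical") {
      stop("'", v, "' is categorical; select a dummy or drop it", call. = FALSE)
    }
  }
  years <- sort(unique(stack$datasets[[1L]]$year))
  pairs <- utils::combn(variables, 2L)
  acc <- array(0, dim = c(length(years), ncol(pairs)))
  cnt <- array(0L, dim = dim(acc))
  any_na <- FALSE
  for (d in stack$datasets) {
    codes <- sapply(variables, function(v) numeric_code(d[[v]], schema[[v]]))
    for (yi in seq_along(years)) {
      sel <- d$year == years[yi]
      cm <- suppressWarnings(stats::cor(codes[sel, , drop = FALSE], method = "spearman"))
      for (pi in seq_len(ncol(pairs))) {
        r <- cm[pairs[1L, pi], pairs[2L, pi]]
        if (is.na(r)) any_na <- TRUE else {
          acc[yi, pi] <- acc[yi, pi] + r
          cnt[yi, pi] <- cnt[yi, pi] + 1L
        }
      }
    }
  }
  if (any_na) warning("a variable was constant in some wave; coefficients reported as NA")
  out <- do.call(rbind, lapply(seq_along(years), function(yi) {
    data.frame(year = years[yi], var1 = pairs[1L, ], var2 = pairs[2L, ],
               rho = ifelse(cnt[yi, ] > 0, acc[yi, ] / cnt[yi, ], NA_real_))
  }))
  rownames(out) <- NULL
  out
}

#' Hold-out validation against an observed wave
#'
#' Removes the hold-out wave from the data, builds a fully missing
#' pseudo-wave for that year with the observed wave's own size and
#' empirical age/sex margins, runs the imputation engine on the remaining
#' waves plus the pseudo-wave, and compares the pooled projected
#' prevalences with the observed ones. Observed prevalences are
#' complete-case proportions with Wald confidence intervals. The inclusion
#' flag records whether the observed point lies inside the projected
#' interval.
#'
#' @param table A `survey_table` of observed waves.
#' @param holdout_year Wave to withhold (must be present; at least two
#'   other waves must remain).
#' @param models Imputation models for the engine (default main effects).
#' @param indicators Binary indicators to validate (default all
#'   outcome-indicators).
#' @param m,iterations,seed Engine settings.
#' @param level Confidence level.
#' @return Data frame `indicator`, `sex`, `observed`, `obs_low`,
#'   `obs_high`, `projected`, `proj_low`, `proj_high`, `included`.
#' @export
holdout_validation <- function(table, holdout_year, models = NULL, indicators = NULL,
                               m = 10L, iterations = 5L, seed = NULL, level = 0.95) {
  schema <- attr(table, "schema")
  wave <- table[table$year == holdout_year & table$.source == "observed", , drop = FALSE]
  if (nrow(wave) == 0L) stop("hold-out year ", holdout_year, " not present", call. = FALSE)
  rest <- table[table$year != holdout_year, , drop = FALSE]
  if (length(unique(rest$year[rest$.source == "observed"])) < 2L) {
    stop("need at least 2 remaining observed waves", call. = FALSE)
  }
  rest <- survey_table(as.data.frame(rest), schema)
  if (is.null(indicators)) {
    indicators <- schema_names(schema)[vapply(schema, function(v) v$role == "outcome-indicator", logical(1))]
  }
  # pseudo-wave margins from the observed wave itself
  marg <- stats::aggregate(list(count = rep(1L, nrow(wave))),
                           by = list(sex = wave$sex, age = wave$age), FUN = sum)
  fc <- population_forecast(data.frame(year = holdout_year, marg),
                            sex_levels = levels(table$sex))
  pseudo <- build_pseudo_sample(holdout_year, nrow(wave), fc, schema,
                                age_range = range(wave$age))
  combined <- append_future(rest, pseudo)
  if (is.null(models)) models <- default_models(schema)
  stack <- fcs_impute(combined, models, m = m, iterations = iterations, seed = seed)
  z <- stats::qnorm((1 + level) / 2)
  rows <- list()
  for (ind in indicators) {
    proj <- project_prevalences(stack, ind, by = c("year", "sex"), level = level)
    proj <- proj[proj$year == holdout_year, ]
    for (sx in levels(table$sex)) {
      obs <- wave[[ind]][wave$sex == sx]
      obs <- obs[!is.na(obs)]
      q <- mean(binary01(obs, schema[[ind]]))
      se <- sqrt(q * (1 - q) / length(obs))
      pr <- proj[proj$sex == sx, ]
      rows[[length(rows) + 1L]] <- data.frame(
        indicator = ind, sex = sx,
        observed = q, obs_low = max(0, q - z * se), obs_high = min(1, q + z * se),
        projected = pr$estimate, proj_low = pr$ci_low, proj_high = pr$ci_high,
        included = q >= pr$ci_low & q <= pr$ci_high)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity of projections to the calendar-time term
#'
#' Runs the full imputation + pooling pipeline once per variant of the
#' outcome's calendar-year terms (e.g. linear year versus a restricted
#' cubic spline) with a shared seed, and reports the per-variant pooled
#' projections side by side with their differences from the first variant.
#' A curved observed trend extrapolated linearly versus through a spline's
#' linear tail can yield very different projections, which is why the
#' choice is worth this check.
#'
#' @param table A combined `survey_table` (observed plus pseudo-waves).
#' @param outcome Indicator whose year terms are varied.
#' @param variants Named list (>= 2) of term lists replacing the year
#'   terms of the outcome's model, e.g.
#'   `list(linear = list(term_main("year")), spline = list(term_spline("year", 2)))`.
#' @param models Base models (default main effects).
#' @param m,iterations,seed Engine settings (seed shared across variants).
#' @param level Confidence level.
#' @return Data frame of projections with columns `variant` and
#'   `diff_vs_first` (difference of `estimate` from the first variant in
#'   the same group).
#' @export
sensitivity_compare <- function(table, outcome, variants, models = NULL,
                                m = 10L, iterations = 5L, seed = 1L, level = 0.95) {
  if (length(variants) < 2L) stop("need at least 2 variants", call. = FALSE)
  schema <- attr(table, "schema")
  if (is.null(models)) models <- default_models(schema)
  if (is.null(names(variants))) names(variants) <- paste0("variant", seq_along(variants))
  res <- list()
  for (nm in names(variants)) {
    mod <- models[[outcome]]
    keep <- Filter(function(t) !identical(t$vars, "year") || t$kind == "interaction", mod$terms)
    models_v <- models
    models_v[[outcome]] <- imputation_model(outcome, c(keep, variants[[nm]]),
                                            family = mod$family, ridge = mod$ridge)
    stack <- fcs_impute(table, models_v, m = m, iterations = iterations, seed = seed)
    pr <- project_prevalences(stack, outcome, by = c("year", "sex"), level = level)
    pr$variant <- nm
    res[[nm]] <- pr
  }
  first <- res[[1L]]
  out <- do.call(rbind, res)
  key <- function(d) paste(d$year, d$sex)
  out$diff_vs_first <- out$estimate - first$estimate[match(key(out), key(first))]
  rownames(out) <- NULL
  out
}
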
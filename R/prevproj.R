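#' Project risk-factor prevalences by multiple imputation
#'
#' The main fitting function. Future survey waves are treated as missing
#' data: for each projection year a pseudo-sample with the forecast's
#' age/sex composition and all other variables missing is appended to the
#' observed waves; chained-equations multiple imputation fills in all
#' missing values (past item non-response and whole future waves alike);
#' and per-imputation prevalences are pooled with Rubin's rules into
#' projections with confidence intervals.
#'
#' @param data A `survey_table` of observed waves (see [read_survey()] or
#'   [generate_population()]).
#' @param forecast A `population_forecast` covering `years`.
#' @param years Projection years.
#' @param size Pseudo-sample size per projection year (scalar or one per
#'   year); 10,000 by default.
#' @param indicators Binary indicators to project (default: all
#'   outcome-indicator variables).
#' @param models Named list of [imputation_model()]s; default main effects
#'   of all other variables for every imputable variable.
#' @param select If `TRUE`, run BIC forward selection ([select_model()])
#'   for each indicator before imputing.
#' @param candidates Candidate terms for selection (default: a df-2
#'   restricted cubic spline on year, a year x age interaction, and a
#'   sex x age interaction).
#' @param m Number of imputed datasets (default 50).
#' @param iterations Chained-equation cycles (default 10).
#' @param seed Master seed.
#' @param level Confidence level for the pooled intervals.
#' @param keep_stack Keep the imputed stack in the returned object
#'   (needed for [correlation_structure()] and [plot.imputed_stack()]).
#' @return An object of class `"prevproj"` with the pooled projection
#'   table, the selected models and (optionally) the imputed stack.
#' @examples
#' cfg <- generator_config(waves = data.frame(year = c(2000, 2005, 2010),
#'                                            n_male = 300, n_female = 300))
#' dat <- impose_missingness(generate_population(cfg, seed = 1)$table, cfg, seed = 2)
#' fc <- make_forecast(cfg, 2015)
#' fit <- prevproj(dat, fc, years = 2015, size = 500, indicators = "obesity",
#'                 m = 3, iterations = 2, seed = 3)
#' fit
#' @export
prevproj <- function(data, forecast, years, size = 10000L, indicators = NULL,
                     models = NULL, select = FALSE, candidates = NULL,
                     m = 50L, iterations = 10L, seed = NULL, level = 0.95,
                     keep_stack = TRUE) {
  schema <- attr(data, "schema")
  if (is.null(indicators)) {
    indicators <- schema_names(schema)[vapply(schema, function(v) v$role == "outcome-indicator", logical(1))]
  }
  size <- rep_len(size, length(years))
  pseudo <- Map(function(yr, sz) build_pseudo_sample(yr, sz, forecast, schema), years, size)
  combined <- append_future(data, pseudo)
  if (is.null(models)) models <- default_models(schema)
  if (select) {
    if (is.null(candidates)) {
      candidates <- list(term_spline("year", 2L), term_interaction(c("year", "age")),
                         term_interaction(c("sex", "age")))
    }
    for (ind in indicators) {
      base <- models[[ind]]$terms
      models[[ind]] <- select_model(data, ind, base, candidates, schema = schema,
                                    ridge = models[[ind]]$ridge)
    }
  }
  stack <- fcs_impute(combined, models, m = m, iterations = iterations, seed = seed)
  proj <- do.call(rbind, lapply(indicators, function(ind) {
    cbind(indicator = ind, project_prevalences(stack, ind, level = level))
  }))
  rownames(proj) <- NULL
  structure(list(projections = proj, models = models, years = years,
                 indicators = indicators, m = m, iterations = iterations,
                 seed = stack$seed, level = level,
                 stack = if (keep_stack) stack),
            class = "prevproj")
}

#' @export
print.prevproj <- function(x, digits = 3, ...) {
  cat("Prevalence projections by multiple imputation\n")
  cat("  m =", x$m, "imputations,", x$iterations, "iterations, seed", x$seed, "\n")
  cat("  projection years:", paste(x$years, collapse = ", "), "\n\n")
  fut <- x$projections[x$projections$source == "pseudo", ]
  fut$estimate <- round(fut$estimate, digits)
  fut$ci_low <- round(fut$ci_low, digits)
  fut$ci_high <- round(fut$ci_high, digits)
  print(fut[c("indicator", "year", "sex", "estimate", "ci_low", "ci_high")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.prevproj <- function(object, ...) {
  cat("Pooled prevalences (observed waves and projections):\n")
  print(object$projections, row.names = FALSE, digits = 4)
  invisible(object$projections)
}

#' @export
as.data.frame.prevproj <- function(x, ...) x$projections

#' @export
coef.prevproj <- function(object, ...) {
  est <- object$projections$estimate
  names(est) <- paste(object$projections$indicator, object$projections$year,
                      object$projections$sex, sep = ".")
  est
}

#' Plot pooled prevalence trends with projections
#'
#' One panel per indicator: pooled prevalence against survey year, one
#' line per sex, vertical segments for the confidence intervals; pseudo
#' (projected) waves are drawn with open symbols.
#'
#' @param x A `prevproj` object.
#' @param ... Unused.
#' @export
plot.prevproj <- function(x, ...) {
  pr <- x$projections
  inds <- unique(pr$indicator)
  old <- graphics::par(mfrow = c(length(inds), 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ind in inds) {
    sub <- pr[pr$indicator == ind, ]
    graphics::plot(range(sub$year), range(c(sub$ci_low, sub$ci_high)), type = "n",
                   xlab = "survey year", ylab = "prevalence", main = ind)
    for (sx in unique(sub$sex)) {
      s <- sub[sub$sex == sx, ]
      s <- s[order(s$year), ]
      lt <- if (sx == unique(sub$sex)[1L]) 1 else 2
      graphics::lines(s$year, s$estimate, lty = lt)
      graphics::points(s$year, s$estimate, pch = ifelse(s$source == "pseudo", 1, 16))
      graphics::segments(s$year, s$ci_low, s$year, s$ci_high)
    }
    graphics::legend("topleft", legend = unique(sub$sex), lty = c(1, 2), bty = "n")
  }
  invisible(NULL)
}
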
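#' Initialize a table for chained-equations imputation
#'
#' Fills every missing cell with a uniform draw from that variable's
#' observed values, the conventional starting point of a fully conditional
#' specification run. Filled values therefore always lie in the observed
#' support.
#'
#' @param table A `survey_table`.
#' @return A completed copy of `table`.
#' @export
fcs_initialize <- function(table) {
  schema <- attr(table, "schema")
  out <- table
  for (v in schema) {
    mis <- is.na(out[[v$name]])
    if (!any(mis)) next
    obs <- out[[v$name]][!mis]
    if (length(obs) == 0L) {
      stop("variable '", v$name, "' has no observed values to initialize from", call. = FALSE)
    }
    out[[v$name]][mis] <- sample(obs, sum(mis), replace = TRUE)
  }
  out
}

#' Multiple imputation by chained equations
#'
#' Runs fully conditional specification over a survey table (typically
#' observed waves plus appended pseudo-waves, see [append_future()]):
#' for each of `m` datasets, missing cells are initialized from observed
#' values, then for `iterations` cycles each incomplete variable is
#' revisited — its conditional model is refit on the records where it was
#' *originally observed* (using the current completed values of all
#' predictors) and every originally missing cell is redrawn from the
#' fitted model with parameter uncertainty. Originally observed cells are
#' never altered.
#'
#' Spline bases in the models are frozen from the originally observed
#' records before the first cycle, so pseudo-wave years are extrapolated
#' linearly beyond the last observed survey year.
#'
#' Each dataset runs on its own L'Ecuyer-CMRG random substream spawned
#' from `seed`, so runs are reproducible and datasets are statistically
#' independent.
#'
#' @param table A `survey_table`; every imputable variable with missing
#'   values needs a model.
#' @param models Named list of [imputation_model()]s (default: main
#'   effects of all other variables for every imputable variable).
#' @param m Number of imputed datasets (default 50).
#' @param iterations Cycles of the chained equations per dataset
#'   (default 10).
#' @param seed Master seed (integer).
#' @param visit_order Variable visit order; default ascending count of
#'   missing values with ties in schema order.
#' @return An `imputed_stack`: `m` completed tables, chain traces
#'   (mean/variance of the imputed values per variable, dataset and
#'   iteration), and the run configuration.
#' @export
fcs_impute <- function(table, models = default_models(attr(table, "schema")),
                       m = 50L, iterations = 10L, seed = NULL, visit_order = NULL) {
  schema <- attr(table, "schema")
  if (m < 2L) stop("m must be >= 2", call. = FALSE)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)

  mis <- lapply(schema_names(schema), function(v) is.na(table[[v]]))
  names(mis) <- schema_names(schema)
  incomplete <- names(mis)[vapply(mis, any, logical(1))]
  no_model <- setdiff(incomplete, names(models))
  if (length(no_model)) {
    stop("no imputation model for incomplete variable(s): ",
         paste(no_model, collapse = ", "), call. = FALSE)
  }
  for (v in incomplete) {
    bad <- setdiff(unlist(lapply(models[[v]]$terms, `[[`, "vars")), schema_names(schema))
    if (length(bad)) stop("model for '", v, "' references unknown variable(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(visit_order)) {
    counts <- vapply(mis[incomplete], sum, integer(1))
    visit_order <- incomplete[order(counts, match(incomplete, schema_names(schema)))]
  }

  # freeze spline knots at the originally observed records
  obs_rows_tab <- table$.source == "observed"
  bases <- list()
  for (v in incomplete) {
    for (term in models[[v]]$terms) {
      if (term$kind == "spline") {
        lab <- term_label(term)
        if (is.null(bases[[lab]])) {
          bases[[lab]] <- rcs_basis(table[[term$vars]][obs_rows_tab], term$df)
        }
      }
    }
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(seed)
  streams <- vector("list", m)
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(m)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }

  datasets <- vector("list", m)
  traces <- list()
  for (i in seq_len(m)) {
    assign(".Random.seed", streams[[i]], envir = globalenv())
    data_i <- fcs_initialize(table)
    for (it in seq_len(iterations)) {
      for (v in visit_order) {
        model <- models[[v]]
        spec <- schema[[v]]
        obs <- !mis[[v]]
        d <- build_design(data_i, model$terms, schema, bases)
        X <- d$X
        imp <- tryCatch({
          if (model$family == "binary-logistic") {
            fit <- fit_binary_logistic(X[obs, , drop = FALSE],
                                       binary01(data_i[[v]][obs], spec),
                                       ridge = model$ridge)
            draws <- draw_binary_imputation(fit, X[!obs, , drop = FALSE])
            factor(spec$levels[draws + 1L], levels = spec$levels)
          } else {
            draws <- draw_polytomous_imputation(data_i[[v]][obs],
                                                X[obs, , drop = FALSE],
                                                X[!obs, , drop = FALSE])
            factor(draws, levels = spec$levels)
          }
        }, error = function(e) {
          stop("imputation failed for variable '", v, "' (dataset ", i,
               ", iteration ", it, "): ", conditionMessage(e), call. = FALSE)
        })
        data_i[[v]][!obs] <- imp
        code <- numeric_code(imp, spec)
        traces[[length(traces) + 1L]] <- data.frame(
          variable = v, dataset = i, iteration = it,
          mean = mean(code),
          variance = if (length(code) > 1L) stats::var(code) else 0,
          stringsAsFactors = FALSE)
      }
    }
    datasets[[i]] <- data_i
  }
  traces <- if (length(traces)) do.call(rbind, traces) else
    data.frame(variable = character(), dataset = integer(), iteration = integer(),
               mean = numeric(), variance = numeric())
  structure(list(datasets = datasets, traces = traces, models = models,
                 schema = schema, m = m, iterations = iterations, seed = seed,
                 visit_order = visit_order, missing = mis, original = table,
                 bases = bases),
            class = "imputed_stack")
}

#' Extract a completed dataset from an imputed stack
#'
#' @param stack An `imputed_stack`.
#' @param i Dataset index in `1:m`.
#' @return The i-th completed `survey_table`.
#' @export
complete_data <- function(stack, i = 1L) {
  stopifnot(inherits(stack, "imputed_stack"), i >= 1L, i <= stack$m)
  stack$datasets[[i]]
}

#' Chain trace summary
#'
#' Long-format means and variances of the imputed values per variable,
#' dataset and iteration, the raw material of convergence plots.
#'
#' @param stack An `imputed_stack`.
#' @return Data frame `variable`, `dataset`, `iteration`, `mean`,
#'   `variance`.
#' @export
trace_summary <- function(stack) {
  tr <- stack$traces
  if (nrow(tr) == 0L) message("no incomplete variables: traces are empty")
  tr
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("Chained-equations imputation: m =", x$m, "datasets,",
      x$iterations, "iterations, seed", x$seed, "\n")
  cat("  visit order:", paste(x$visit_order, collapse = " -> "), "\n")
  cat("  records:", nrow(x$original),
      sprintf("(%d pseudo)", sum(x$original$.source == "pseudo")), "\n")
  invisible(x)
}

#' @export
summary.imputed_stack <- function(object, ...) {
  mis <- vapply(object$missing, sum, integer(1))
  out <- data.frame(variable = names(mis), n_missing = as.integer(mis))
  out <- out[out$n_missing > 0, ]
  rownames(out) <- NULL
  print(object)
  cat("\nImputed cells per variable:\n")
  print(out)
  invisible(out)
}

#' Convergence trace plot
#'
#' One panel per incomplete variable: mean of the imputed values against
#' iteration, one line per imputed dataset. Well-mixed chains show no
#' systematic drift and spread comparable across datasets.
#'
#' @param x An `imputed_stack`.
#' @param ... Unused.
#' @export
plot.imputed_stack <- function(x, ...) {
  tr <- x$traces
  if (nrow(tr) == 0L) {
    message("nothing to plot: traces are empty")
    return(invisible(NULL))
  }
  vars <- unique(tr$variable)
  old <- graphics::par(mfrow = c(length(vars), 1L), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in vars) {
    sub <- tr[tr$variable == v, ]
    wide <- stats::reshape(sub[c("dataset", "iteration", "mean")],
                           idvar = "iteration", timevar = "dataset", direction = "wide")
    wide <- wide[order(wide$iteration), ]
    graphics::matplot(wide$iteration, wide[, -1L, drop = FALSE], type = "l", lty = 1,
                      xlab = "iteration", ylab = "mean of imputed values", main = v)
  }
  invisible(NULL)
}
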
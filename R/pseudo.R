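#' Population forecast table
#'
#' A population forecast maps (calendar year, sex, single year of age) to a
#' projected population count. It fixes the demographic composition of the
#' pseudo-samples that stand in for future survey waves.
#'
#' @param data Data frame with columns `year`, `sex`, `age`, `count`.
#' @param sex_levels Level order for sex (used when integerizing cells).
#' @return A `population_forecast` data frame.
#' @export
population_forecast <- function(data, sex_levels = c("male", "female")) {
  need <- c("year", "sex", "age", "count")
  if (!all(need %in% names(data))) {
    stop("forecast needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(year = as.numeric(data$year),
                    sex = factor(as.character(data$sex), levels = sex_levels),
                    age = as.integer(data$age),
                    count = as.numeric(data$count))
  if (anyNA(out$sex)) stop("forecast sex values outside ", paste(sex_levels, collapse = "/"), call. = FALSE)
  if (any(out$count < 0)) stop("forecast counts must be non-negative", call. = FALSE)
  if (anyDuplicated(out[c("year", "sex", "age")])) {
    stop("duplicate (year, sex, age) cells in forecast", call. = FALSE)
  }
  class(out) <- c("population_forecast", "data.frame")
  out
}

#' @rdname population_forecast
#' @param path Delimited text file with header `year,sex,age,count`.
#' @param sep Field separator.
#' @export
read_forecast <- function(path, sep = ",", sex_levels = c("male", "female")) {
  population_forecast(utils::read.table(path, header = TRUE, sep = sep),
                      sex_levels = sex_levels)
}

#' @rdname population_forecast
#' @param forecast A `population_forecast`.
#' @export
write_forecast <- function(forecast, path, sep = ",") {
  utils::write.table(forecast, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Allocate a pseudo-sample over forecast cells
#'
#' Distributes `size` pseudo-individuals over the (sex, age) cells of a
#' forecast year proportionally to the projected population counts, using
#' largest-remainder (Hamilton) integerization so the cell counts sum
#' exactly to `size`. Cells are ordered by (sex level order, age); remainder
#' ties go to the lowest-index cell. Exact margins are used rather than
#' multinomial sampling so projections are not perturbed by extra
#' demographic noise.
#'
#' @param forecast A `population_forecast`.
#' @param target_year Forecast year to match.
#' @param size Number of pseudo-individuals (>= 1).
#' @param age_range Inclusive age bounds restricting the forecast cells.
#' @return Data frame `sex`, `age`, `count` with `sum(count) == size`.
#' @export
allocate_cells <- function(forecast, target_year, size, age_range = c(25, 64)) {
  stopifnot(size >= 1)
  cells <- forecast[forecast$year == target_year &
                      forecast$age >= age_range[1L] & forecast$age <= age_range[2L], ]
  if (nrow(cells) == 0L || sum(cells$count) <= 0) {
    stop("forecast has no positive counts for year ", target_year,
         " in age range [", age_range[1L], ", ", age_range[2L], "]", call. = FALSE)
  }
  cells <- cells[order(as.integer(cells$sex), cells$age), ]
  share <- cells$count / sum(cells$count)
  exact <- share * size
  n <- floor(exact)
  seats <- size - sum(n)
  if (seats > 0) {
    rem <- exact - n
    # order(): ties broken by position, i.e. lowest cell index
    top <- order(rem, decreasing = TRUE)[seq_len(seats)]
    n[top] <- n[top] + 1
  }
  data.frame(sex = cells$sex, age = cells$age, count = as.integer(n))
}

#' Build a fully missing pseudo-sample for a future wave
#'
#' Creates a survey table of `size` records for `target_year` with year, sex
#' and age fixed by [allocate_cells()] and every other schema variable
#' missing. Appended to observed data, these records are the "future wave as
#' missing data" that the imputation engine fills in.
#'
#' @inheritParams allocate_cells
#' @param schema A `survey_schema`.
#' @return A `survey_table` with `.source == "pseudo"` everywhere.
#' @export
build_pseudo_sample <- function(target_year, size, forecast, schema,
                                age_range = attr(schema, "age_range") %||% c(25, 64)) {
  alloc <- allocate_cells(forecast, target_year, size, age_range)
  alloc <- alloc[alloc$count > 0, ]
  n <- sum(alloc$count)
  df <- data.frame(year = rep(target_year, n),
                   sex = rep(as.character(alloc$sex), alloc$count),
                   age = rep(alloc$age, alloc$count))
  for (v in schema) {
    if (!v$name %in% names(df)) df[[v$name]] <- NA_character_
  }
  survey_table(df, schema, source = "pseudo")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Append pseudo-waves to observed data
#'
#' @param observed A `survey_table` of observed waves.
#' @param pseudo A `survey_table` or list of them (future waves).
#' @return Combined `survey_table`; `.source` keeps per-record provenance.
#' @export
append_future <- function(observed, pseudo) {
  if (inherits(pseudo, "survey_table")) pseudo <- list(pseudo)
  schema <- attr(observed, "schema")
  out <- observed
  for (p in pseudo) {
    if (!identical(schema_names(attr(p, "schema")), schema_names(schema))) {
      stop("schema mismatch between observed and pseudo tables", call. = FALSE)
    }
    out <- rbind(as.data.frame(out), as.data.frame(p))
  }
  out <- survey_table(out, schema)
  out
}

#' Fix a variable in a pseudo-wave for scenario projections
#'
#' A scenario projection asks how prevalences would develop if a background
#' variable were fixed to a level of interest (or drawn from a stated
#' distribution) in the future population. The variable is set non-missing
#' in every pseudo-record, so the engine subsequently treats it as observed.
#'
#' @param pseudo A `survey_table` consisting of pseudo-records only.
#' @param variable An imputable variable name.
#' @param value Either a single level (constant scenario) or a named numeric
#'   vector of probabilities over levels (distributional scenario).
#' @return The modified `survey_table`.
#' @export
apply_scenario <- function(pseudo, variable, value) {
  schema <- attr(pseudo, "schema")
  if (!all(pseudo$.source == "pseudo")) {
    stop("apply_scenario expects pseudo-records only", call. = FALSE)
  }
  spec <- schema[[variable]]
  if (is.null(spec)) stop("unknown variable '", variable, "'", call. = FALSE)
  if (!spec$imputable) {
    stop("'", variable, "' is a design variable and cannot be set by a scenario", call. = FALSE)
  }
  n <- nrow(pseudo)
  if (length(value) == 1L && is.null(names(value))) {
    vals <- rep(as.character(value), n)
  } else {
    probs <- value
    if (is.null(names(probs)) || abs(sum(probs) - 1) > 1e-8) {
      stop("distributional scenario needs named probabilities summing to 1", call. = FALSE)
    }
    vals <- sample(names(probs), n, replace = TRUE, prob = probs)
  }
  if (!is.null(spec$levels) && !all(vals %in% spec$levels)) {
    stop("scenario values outside declared levels of '", variable, "'", call. = FALSE)
  }
  pseudo[[variable]] <- if (is.null(spec$levels)) as.numeric(vals) else factor(vals, levels = spec$levels)
  pseudo
}
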
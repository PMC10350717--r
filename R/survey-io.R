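#' Read a survey table from delimited text
#'
#' Reads a delimited text file (one header row, UTF-8) into a validated
#' [survey_table()]. Cells equal to one of the `na` tokens become missing.
#' Columns not in the schema are dropped with a warning; a `.source` column,
#' if present, is used as record provenance.
#'
#' @param path Path to the file.
#' @param schema A `survey_schema`.
#' @param sep Field separator (`","` default, `"\t"` for TSV).
#' @param na Tokens read as missing.
#' @return A `survey_table`.
#' @export
read_survey <- function(path, schema, sep = ",", na = c("", "NA")) {
  raw <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  survey_table(raw, schema)
}

#' Write a survey table to delimited text
#'
#' Columns are written in schema order followed by `.source`; missing cells
#' are written as the empty string. `read_survey()` of the result recovers
#' the table exactly.
#'
#' @param table A `survey_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @param na Token written for missing cells.
#' @export
write_survey <- function(table, path, sep = ",", na = "") {
  validate_survey(table)
  utils::write.table(table, path, sep = sep, na = na, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# round half-up to `digits` decimals (sprintf/round use banker's rounding)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Missingness summary by variable, wave and sex
#'
#' Counts and percentages of missing values among all invited individuals,
#' per variable, survey year and sex — the layout used to describe
#' participation in repeated health examination surveys. Percentages are
#' rounded half-up to one decimal.
#'
#' @param table A `survey_table`.
#' @param variables Variables to summarise; defaults to all imputable ones.
#' @return A data frame with columns `variable`, `year`, `sex`, `n_invited`,
#'   `n_missing`, `pct_missing`.
#' @export
missingness_summary <- function(table, variables = NULL) {
  schema <- attr(table, "schema")
  if (is.null(variables)) variables <- imputable_vars(schema)
  unknown <- setdiff(variables, schema_names(schema))
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  years <- sort(unique(table$year))
  sexes <- levels(table$sex)
  grid <- expand.grid(sex = sexes, year = years, variable = variables,
                      stringsAsFactors = FALSE)[, 3:1]
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- table$year == grid$year[i] & table$sex == grid$sex[i]
    n <- sum(sel)
    miss <- sum(is.na(table[[grid$variable[i]]][sel]))
    data.frame(variable = grid$variable[i], year = grid$year[i], sex = grid$sex[i],
               n_invited = n, n_missing = miss,
               pct_missing = if (n > 0) round_half_up(100 * miss / n, 1L) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
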
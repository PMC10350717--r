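#' Declare a survey variable
#'
#' A variable specification describes one column of a repeated
#' cross-sectional survey table: its role in the projection pipeline, its
#' measurement type and, for categorical variables, the permitted levels.
#'
#' Design variables (survey year, sex, age) are structural: they are fixed
#' when a pseudo-sample for a future wave is built and are never imputed.
#' Outcome indicators are the binary risk factors whose prevalences are
#' projected; covariates are everything else that enters imputation models.
#'
#' @param name Variable name (a syntactic identifier).
#' @param role One of `"design"`, `"outcome-indicator"`, `"covariate"`.
#' @param vtype One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param levels Ordered character vector of permitted levels. Required for
#'   binary (exactly 2) and categorical (at least 2) variables. The second
#'   level of a binary variable is the "positive" one used for prevalences.
#' @param imputable Logical; may the variable be imputed? Design variables
#'   must not be imputable.
#' @return An object of class `"variable_spec"`.
#' @seealso [survey_schema()], [finrisk_schema()]
#' @export
variable_spec <- function(name, role, vtype, levels = NULL, imputable = !identical(role, "design")) {
  role <- match.arg(role, c("design", "outcome-indicator", "covariate"))
  vtype <- match.arg(vtype, c("continuous", "binary", "categorical"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a single non-empty string", call. = FALSE)
  }
  if (vtype == "binary") {
    if (is.null(levels) || length(levels) != 2L) {
      stop("binary variable '", name, "' needs exactly 2 levels", call. = FALSE)
    }
  } else if (vtype == "categorical") {
    if (is.null(levels) || length(levels) < 2L) {
      stop("categorical variable '", name, "' needs at least 2 levels", call. = FALSE)
    }
  } else if (!is.null(levels)) {
    stop("continuous variable '", name, "' must not declare levels", call. = FALSE)
  }
  if (!is.null(levels) && anyDuplicated(levels)) {
    stop("levels of '", name, "' must be unique", call. = FALSE)
  }
  if (role == "design" && imputable) {
    stop("design variable '", name, "' cannot be imputable", call. = FALSE)
  }
  structure(
    list(name = name, role = role, vtype = vtype,
         levels = if (!is.null(levels)) as.character(levels), imputable = isTRUE(imputable)),
    class = "variable_spec"
  )
}

#' Assemble a survey schema
#'
#' @param ... `variable_spec` objects. Must include the three design
#'   variables `year`, `sex` and `age`.
#' @return An object of class `"survey_schema"`: a named list of
#'   `variable_spec`s in declaration order.
#' @export
survey_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1L]]) && !inherits(specs[[1L]], "variable_spec")) {
    specs <- specs[[1L]]
  }
  ok <- vapply(specs, inherits, logical(1), "variable_spec")
  if (!all(ok)) stop("all arguments must be variable_spec objects", call. = FALSE)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate variable names in schema", call. = FALSE)
  names(specs) <- nms
  for (v in c("year", "sex", "age")) {
    if (!v %in% nms) stop("schema must declare design variable '", v, "'", call. = FALSE)
    if (specs[[v]]$role != "design") stop("'", v, "' must have role 'design'", call. = FALSE)
  }
  structure(specs, class = "survey_schema")
}

#' @export
print.survey_schema <- function(x, ...) {
  cat("Survey schema with", length(x), "variables:\n")
  for (v in x) {
    lv <- if (is.null(v$levels)) "" else paste0(" {", paste(v$levels, collapse = ", "), "}")
    cat(sprintf("  %-14s %-17s %-12s%s%s\n", v$name, v$role, v$vtype,
                if (v$imputable) "imputable" else "fixed", lv))
  }
  invisible(x)
}

#' Default schema mirroring five Finnish health examination surveys
#'
#' Survey year, sex and age as design variables; area (5 regions),
#' educational level (3 categories) and marital status as covariates;
#' obesity, current smoking and hypertension as binary outcome indicators
#' coded `"0"`/`"1"` with `"1"` the positive level.
#'
#' @param age_range Inclusive age bounds enforced on validation.
#' @return A `survey_schema`.
#' @export
finrisk_schema <- function(age_range = c(25, 64)) {
  sch <- survey_schema(
    variable_spec("year", "design", "continuous", imputable = FALSE),
    variable_spec("sex", "design", "binary", levels = c("male", "female"), imputable = FALSE),
    variable_spec("age", "design", "continuous", imputable = FALSE),
    variable_spec("area", "covariate", "categorical",
                  levels = paste0("area", 1:5)),
    variable_spec("education", "covariate", "categorical",
                  levels = c("low", "middle", "high")),
    variable_spec("marital", "covariate", "binary", levels = c("0", "1")),
    variable_spec("obesity", "outcome-indicator", "binary", levels = c("0", "1")),
    variable_spec("smoking", "outcome-indicator", "binary", levels = c("0", "1")),
    variable_spec("hypertension", "outcome-indicator", "binary", levels = c("0", "1"))
  )
  attr(sch, "age_range") <- age_range
  sch
}

schema_names <- function(schema) vapply(schema, `[[`, character(1), "name")

imputable_vars <- function(schema) {
  schema_names(schema)[vapply(schema, `[[`, logical(1), "imputable")]
}

#' Construct / validate a survey table
#'
#' A survey table is a data frame carrying its schema as an attribute and a
#' `.source` column flagging each record as `"observed"` or `"pseudo"`.
#' Validation enforces the schema invariants: design variables non-missing
#' everywhere, categorical values within their declared level sets, and age
#' within the schema's age range if one is attached.
#'
#' @param data A data frame with one column per schema variable.
#' @param schema A `survey_schema`.
#' @param source Provenance for records lacking a `.source` column.
#' @return A validated `survey_table` (a data frame subclass).
#' @export
survey_table <- function(data, schema, source = "observed") {
  stopifnot(inherits(schema, "survey_schema"))
  nms <- schema_names(schema)
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(data), c(nms, ".source"))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  out <- data[nms]
  for (v in schema) {
    col <- out[[v$name]]
    if (v$vtype == "continuous") {
      out[[v$name]] <- as.numeric(col)
    } else {
      chr <- as.character(col)
      bad <- !is.na(chr) & !(chr %in% v$levels)
      if (any(bad)) {
        i <- which(bad)[1L]
        stop("validation error: row ", i, ": value '", chr[i], "' of '", v$name,
             "' not in declared levels", call. = FALSE)
      }
      out[[v$name]] <- factor(chr, levels = v$levels)
    }
  }
  out$.source <- if (".source" %in% names(data)) {
    factor(as.character(data$.source), levels = c("observed", "pseudo"))
  } else {
    factor(rep(source, nrow(out)), levels = c("observed", "pseudo"))
  }
  class(out) <- c("survey_table", "data.frame")
  attr(out, "schema") <- schema
  validate_survey(out)
  out
}

#' @rdname survey_table
#' @param table A `survey_table`.
#' @export
validate_survey <- function(table) {
  schema <- attr(table, "schema")
  for (v in c("year", "sex", "age")) {
    if (anyNA(table[[v]])) {
      stop("validation error: design variable '", v, "' has missing values", call. = FALSE)
    }
  }
  rng <- attr(schema, "age_range")
  if (!is.null(rng) && nrow(table) &&
      (min(table$age) < rng[1L] || max(table$age) > rng[2L])) {
    stop("validation error: age outside [", rng[1L], ", ", rng[2L], "]", call. = FALSE)
  }
  invisible(table)
}

#' @export
print.survey_table <- function(x, ...) {
  yrs <- sort(unique(x$year))
  cat("Survey table:", nrow(x), "records,", length(yrs), "wave(s):",
      paste(yrs, collapse = ", "), "\n")
  src <- table(x$.source)
  cat("  observed:", src[["observed"]], " pseudo:", src[["pseudo"]], "\n")
  nmis <- colSums(is.na(x[setdiff(names(x), ".source")]))
  nmis <- nmis[nmis > 0]
  if (length(nmis)) {
    cat("  missing cells:", paste(names(nmis), nmis, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# 0/1 numeric code for a binary variable (positive = second declared level)
binary01 <- function(x, spec) {
  if (is.numeric(x)) return(x)
  as.numeric(as.character(x) == spec$levels[2L])
}

# numeric coding used for traces and rank correlations
numeric_code <- function(x, spec) {
  if (spec$vtype == "continuous") as.numeric(x)
  else if (spec$vtype == "binary") binary01(x, spec)
  else as.numeric(factor(as.character(x), levels = spec$levels))
}
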
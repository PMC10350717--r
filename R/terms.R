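#' Model terms for imputation models
#'
#' Imputation models are declared as lists of terms: main effects,
#' interactions (products of the coded columns of two or more variables)
#' and restricted cubic spline expansions of a continuous variable.
#' Categorical variables enter through reference-level dummy coding (first
#' declared level is the reference); binary variables as 0/1 indicators of
#' their second level.
#'
#' @param var,vars Variable name(s).
#' @param df Spline degrees of freedom (>= 2).
#' @return A `model_term` object.
#' @name model_term
NULL

#' @rdname model_term
#' @export
term_main <- function(var) {
  structure(list(kind = "main", vars = var), class = "model_term")
}

#' @rdname model_term
#' @export
term_interaction <- function(vars) {
  if (length(vars) < 2L) stop("interaction needs at least 2 variables", call. = FALSE)
  structure(list(kind = "interaction", vars = vars), class = "model_term")
}

#' @rdname model_term
#' @export
term_spline <- function(var, df = 2L) {
  if (df < 2L) stop("spline df must be >= 2", call. = FALSE)
  structure(list(kind = "spline", vars = var, df = as.integer(df)), class = "model_term")
}

term_label <- function(term) {
  switch(term$kind,
         main = term$vars,
         interaction = paste(term$vars, collapse = ":"),
         spline = paste0("rcs(", term$vars, ",", term$df, ")"))
}

# coded columns of one variable: continuous -> 1 col, binary -> 0/1,
# categorical -> K-1 dummies
var_columns <- function(data, var, schema) {
  spec <- schema[[var]]
  if (is.null(spec)) stop("unknown model variable '", var, "'", call. = FALSE)
  x <- data[[var]]
  if (spec$vtype == "continuous") {
    m <- matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, var))
  } else if (spec$vtype == "binary") {
    m <- matrix(binary01(x, spec), ncol = 1L, dimnames = list(NULL, var))
  } else {
    lv <- spec$levels
    m <- sapply(lv[-1L], function(l) as.numeric(as.character(x) == l))
    if (!is.matrix(m)) m <- matrix(m, nrow = length(x))
    colnames(m) <- paste0(var, lv[-1L])
  }
  m
}

#' Build the design matrix for a term list
#'
#' Returns the n x p design matrix (with intercept) for a set of model
#' terms, plus the spline bases used. Spline bases are computed from the
#' supplied data on first use and can be passed back in (`bases`) to freeze
#' the knots — the engine freezes year-spline knots at the observed survey
#' years so future waves are extrapolated linearly.
#'
#' @param data A data frame (typically a completed `survey_table`).
#' @param terms List of `model_term`s.
#' @param schema A `survey_schema`.
#' @param bases Named list of frozen `rcs_basis` objects keyed by term label.
#' @return List with elements `X` (matrix) and `bases`.
#' @export
build_design <- function(data, terms, schema, bases = list()) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  for (term in terms) {
    lab <- term_label(term)
    m <- switch(term$kind,
      main = var_columns(data, term$vars, schema),
      spline = {
        if (is.null(bases[[lab]])) {
          bases[[lab]] <- rcs_basis(data[[term$vars]], term$df)
        }
        b <- rcs_transform(bases[[lab]], as.numeric(data[[term$vars]]))
        colnames(b) <- c(term$vars, paste0(term$vars, "'", strrep("'", seq_len(ncol(b) - 1L) - 1L)))
        b
      },
      interaction = {
        parts <- lapply(term$vars, function(v) var_columns(data, v, schema))
        out <- parts[[1L]]
        for (p in parts[-1L]) {
          new <- matrix(0, n, ncol(out) * ncol(p))
          nm <- character(ncol(out) * ncol(p))
          k <- 0L
          for (i in seq_len(ncol(out))) for (j in seq_len(ncol(p))) {
            k <- k + 1L
            new[, k] <- out[, i] * p[, j]
            nm[k] <- paste(colnames(out)[i], colnames(p)[j], sep = ":")
          }
          colnames(new) <- nm
          out <- new
        }
        out
      })
    cols[[lab]] <- m
  }
  X <- do.call(cbind, cols)
  colnames(X) <- unlist(lapply(cols, colnames), use.names = FALSE)
  list(X = X, bases = bases)
}

#' Declare one variable's conditional imputation model
#'
#' @param outcome Variable to impute.
#' @param terms List of `model_term` predictors (must not include the
#'   outcome).
#' @param family `"binary-logistic"` for binary outcomes (posterior-draw
#'   logistic imputer) or `"polytomous-logistic"` for categorical ones
#'   (bootstrap multinomial imputer). Inferred from the schema if omitted
#'   at engine time.
#' @param ridge Ridge penalty used in the logistic fit; a small default
#'   guards against separation in small waves.
#' @return An `imputation_model`.
#' @export
imputation_model <- function(outcome, terms, family = c("binary-logistic", "polytomous-logistic"),
                             ridge = 1e-5) {
  family <- match.arg(family)
  used <- unlist(lapply(terms, `[[`, "vars"))
  if (outcome %in% used) stop("outcome '", outcome, "' may not appear among its predictors", call. = FALSE)
  structure(list(outcome = outcome, terms = terms, family = family, ridge = ridge),
            class = "imputation_model")
}

#' @export
print.imputation_model <- function(x, ...) {
  cat(x$outcome, "~", paste(vapply(x$terms, term_label, character(1)), collapse = " + "),
      sprintf("  [%s, ridge=%g]\n", x$family, x$ridge))
  invisible(x)
}

#' Main-effects imputation models for every imputable variable
#'
#' The default model set: each imputable variable is imputed from the main
#' effects of all other schema variables (year entering linearly), the
#' starting point for BIC-based forward selection.
#'
#' @param schema A `survey_schema`.
#' @param ridge Ridge penalty passed to each model.
#' @return Named list of `imputation_model`s.
#' @export
default_models <- function(schema, ridge = 1e-5) {
  vars <- imputable_vars(schema)
  models <- lapply(vars, function(v) {
    preds <- setdiff(schema_names(schema), v)
    fam <- if (schema[[v]]$vtype == "binary") "binary-logistic" else "polytomous-logistic"
    imputation_model(v, lapply(preds, term_main), family = fam, ridge = ridge)
  })
  names(models) <- vars
  models
}
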
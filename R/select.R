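#' BIC-based forward selection of an imputation model
#'
#' Starting from the base terms, repeatedly adds the candidate term that
#' lowers the BIC most, stopping when no candidate lowers it. A spline
#' candidate on a variable whose linear main effect is already in the model
#' replaces that main effect, so linear-versus-spline calendar-time trends
#' compete directly; conversely a linear main effect is never added on top
#' of its own spline. The fitting set is the available-case set: records
#' with the outcome observed and every base or candidate predictor
#' complete (selection precedes imputation, so completed values are not
#' yet available).
#'
#' @param table A `survey_table` (or completed data frame).
#' @param outcome Variable whose imputation model is selected.
#' @param base_terms Terms always kept (list of `model_term`).
#' @param candidate_terms Terms considered for inclusion.
#' @param schema Schema; defaults to the table's.
#' @param ridge Ridge penalty for the logistic fits.
#' @return The selected `imputation_model`.
#' @export
select_model <- function(table, outcome, base_terms, candidate_terms,
                         schema = attr(table, "schema"), ridge = 1e-5) {
  spec <- schema[[outcome]]
  if (is.null(spec)) stop("unknown outcome '", outcome, "'", call. = FALSE)
  family <- if (spec$vtype == "binary") "binary-logistic" else "polytomous-logistic"

  all_vars <- unique(unlist(lapply(c(base_terms, candidate_terms), `[[`, "vars")))
  keep <- !is.na(table[[outcome]])
  for (v in all_vars) keep <- keep & !is.na(table[[v]])
  data <- as.data.frame(table)[keep, , drop = FALSE]
  if (nrow(data) == 0L) stop("empty fitting set for '", outcome, "'", call. = FALSE)

  fit_terms <- function(terms) {
    X <- build_design(data, terms, schema)$X
    if (family == "binary-logistic") {
      fit_binary_logistic(X, binary01(data[[outcome]], spec), ridge = ridge)
    } else {
      fit_polytomous(X, data[[outcome]])
    }
  }
  spline_of <- function(t) if (t$kind == "spline") t$vars else NA_character_

  current <- base_terms
  current_bic <- bic(fit_terms(current))
  remaining <- candidate_terms
  while (length(remaining)) {
    trial <- lapply(remaining, function(cand) {
      terms <- current
      if (cand$kind == "spline") {
        # spline replaces the linear main effect of the same variable
        terms <- Filter(function(t) !(t$kind == "main" && t$vars == cand$vars), terms)
      } else if (cand$kind == "main" &&
                 cand$vars %in% stats::na.omit(vapply(current, spline_of, character(1)))) {
        return(NULL)  # linear term subsumed by an existing spline
      }
      c(terms, list(cand))
    })
    bics <- vapply(trial, function(t) if (is.null(t)) Inf else bic(fit_terms(t)), numeric(1))
    best <- which.min(bics)
    if (!length(best) || bics[best] >= current_bic) break
    current <- trial[[best]]
    current_bic <- bics[best]
    remaining <- remaining[-best]
  }
  imputation_model(outcome, current, family = family, ridge = ridge)
}
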
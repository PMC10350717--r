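#' Prevalence of a binary indicator in one cell of one completed dataset
#'
#' @param data A completed `survey_table`.
#' @param indicator Binary variable name.
#' @param cell Named list of selection values, e.g.
#'   `list(year = 2025, sex = "male")`; empty list selects everything.
#' @return List with `q` (proportion), `w` (Wald within-imputation
#'   variance `q(1-q)/n`) and `n_cell`.
#' @export
cell_prevalence <- function(data, indicator, cell = list()) {
  schema <- attr(data, "schema")
  spec <- schema[[indicator]]
  if (is.null(spec) || spec$vtype != "binary") {
    stop("'", indicator, "' is not a binary schema variable", call. = FALSE)
  }
  sel <- rep(TRUE, nrow(data))
  for (v in names(cell)) sel <- sel & (as.character(data[[v]]) == as.character(cell[[v]]))
  n <- sum(sel)
  if (n == 0L) {
    stop("empty cell: ", paste(names(cell), unlist(cell), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  y <- binary01(data[[indicator]][sel], spec)
  if (anyNA(y)) stop("indicator has missing values in the cell; pool completed data", call. = FALSE)
  q <- mean(y)
  list(q = q, w = q * (1 - q) / n, n_cell = n)
}

#' Pool per-imputation estimates with Rubin's rules
#'
#' Combines m per-dataset estimates q_i with within-imputation variances
#' w_i: pooled estimate `Qbar = mean(q)`, within variance `Wbar = mean(w)`,
#' between variance `B = var(q)`, total variance `T = Wbar + (1 + 1/m) B`,
#' degrees of freedom `nu = (m - 1) (1 + Wbar / ((1 + 1/m) B))^2` and a
#' t-based confidence interval truncated to \[0, 1\]. With `B = 0` the
#' normal quantile is used (`nu = Inf`). The classical large-sample df is
#' used rather than the Barnard-Rubin small-sample adjustment, appropriate
#' because completed pseudo-samples are large.
#'
#' @param q Numeric vector of per-dataset estimates (length m >= 2).
#' @param w Numeric vector of within-imputation variances.
#' @param level Confidence level (default 0.95).
#' @return A `pooled_estimate` list: `Qbar`, `Wbar`, `B`, `T`, `df`, `m`,
#'   `se`, `ci` (length-2), `level`.
#' @export
rubin_pool <- function(q, w, level = 0.95) {
  m <- length(q)
  if (m < 2L) stop("Rubin's rules need m >= 2 estimates", call. = FALSE)
  if (length(w) != m) stop("q and w must have equal length", call. = FALSE)
  Qbar <- mean(q)
  Wbar <- mean(w)
  B <- sum((q - Qbar)^2) / (m - 1)
  Tv <- Wbar + (1 + 1 / m) * B
  if (B > 0) {
    df <- (m - 1) * (1 + Wbar / ((1 + 1 / m) * B))^2
    quant <- stats::qt((1 + level) / 2, df)
  } else {
    df <- Inf
    quant <- stats::qnorm((1 + level) / 2)
  }
  se <- sqrt(Tv)
  ci <- c(max(0, Qbar - quant * se), min(1, Qbar + quant * se))
  structure(list(Qbar = Qbar, Wbar = Wbar, B = B, T = Tv, df = df, m = m,
                 se = se, ci = ci, level = level),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled prevalence %.4f (%.0f%% CI %.4f, %.4f), se %.4f, m = %d, df = %.1f\n",
              x$Qbar, 100 * x$level, x$ci[1L], x$ci[2L], x$se, x$m, x$df))
  invisible(x)
}

#' Pooled prevalence projections by group
#'
#' For each group (by default every year x sex combination present in the
#' stack, covering both observed waves and pseudo-waves) computes the
#' per-dataset prevalence of the indicator and pools across imputations
#' with [rubin_pool()].
#'
#' @param stack An `imputed_stack`.
#' @param indicator Binary variable to summarise.
#' @param by Grouping variables (default `c("year", "sex")`).
#' @param level Confidence level.
#' @return Data frame with the group columns plus `source`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `m`, `df`, `n`.
#' @export
project_prevalences <- function(stack, indicator, by = c("year", "sex"), level = 0.95) {
  d1 <- stack$datasets[[1L]]
  if (length(by) == 0L) {
    groups <- data.frame(row.names = 1L)  # one group covering everything
  } else {
    groups <- unique(as.data.frame(d1)[by])
    groups <- groups[do.call(order, groups), , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    cell <- as.list(groups[g, , drop = FALSE])
    ests <- lapply(stack$datasets, cell_prevalence, indicator = indicator, cell = cell)
    pooled <- rubin_pool(vapply(ests, `[[`, numeric(1), "q"),
                         vapply(ests, `[[`, numeric(1), "w"), level = level)
    sel <- rep(TRUE, nrow(d1))
    for (v in names(cell)) sel <- sel & (as.character(d1[[v]]) == as.character(cell[[v]]))
    src <- if (all(d1$.source[sel] == "pseudo")) "pseudo" else "observed"
    cbind(groups[g, , drop = FALSE],
          data.frame(source = src, estimate = pooled$Qbar, se = pooled$se,
                     ci_low = pooled$ci[1L], ci_high = pooled$ci[2L],
                     m = pooled$m, df = pooled$df, n = ests[[1L]]$n_cell))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
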
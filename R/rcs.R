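#' Restricted cubic spline basis
#'
#' Knot locations for a restricted (natural) cubic spline with `df` degrees
#' of freedom, i.e. `df + 1` knots, placed at Harrell's default quantiles of
#' the distinct observed values. For 3 knots these are the 0.10, 0.50 and
#' 0.90 quantiles. The restricted basis is linear beyond the boundary knots,
#' which is what makes extrapolation of a calendar-time trend to future
#' waves well behaved: knots are computed once from the observed survey
#' years and frozen, so projection years lie in the linear tail.
#'
#' @param values Sample of a continuous variable.
#' @param df Degrees of freedom (>= 2); the basis has `df` columns
#'   (1 linear + `df - 1` nonlinear).
#' @return An object of class `"rcs_basis"` holding the knot vector.
#' @references Harrell FE. Regression Modeling Strategies. Springer.
#' @export
rcs_basis <- function(values, df = 2L) {
  if (df < 2L) stop("spline df must be >= 2", call. = FALSE)
  k <- df + 1L
  ux <- sort(unique(values[!is.na(values)]))
  if (length(ux) < k) {
    stop("need at least ", k, " distinct values for ", k, " knots", call. = FALSE)
  }
  probs <- switch(as.character(k),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
    "7" = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975),
    seq(0.05, 0.95, length.out = k)
  )
  knots <- as.numeric(stats::quantile(ux, probs, type = 7, names = FALSE))
  if (any(diff(knots) <= 0)) {
    # fall back to evenly spaced distinct values when quantiles collide
    knots <- ux[round(seq(1, length(ux), length.out = k))]
    if (any(diff(knots) <= 0)) stop("cannot place strictly increasing knots", call. = FALSE)
  }
  structure(list(knots = knots), class = "rcs_basis")
}

#' Evaluate the restricted cubic spline basis
#'
#' For knots t1 < ... < tk the basis consists of the linear term x and
#' k - 2 restricted truncated-power terms
#' \deqn{s_j(x) = [(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2,}
#' for j = 1, ..., k - 2. Each s_j is zero below t1, twice continuously
#' differentiable everywhere, and exactly linear above tk.
#'
#' @param basis An `rcs_basis`.
#' @param x Numeric vector.
#' @return Matrix with columns `x1` (linear) and `x2`, ..., `x(k-1)`
#'   (nonlinear terms).
#' @export
rcs_transform <- function(basis, x) {
  t <- basis$knots
  k <- length(t)
  norm <- (t[k] - t[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    out[, j + 1L] <- (pos3(x - t[j]) -
                        pos3(x - t[k - 1L]) * (t[k] - t[j]) / (t[k] - t[k - 1L]) +
                        pos3(x - t[k]) * (t[k - 1L] - t[j]) / (t[k] - t[k - 1L])) / norm
  }
  colnames(out) <- paste0("x", seq_len(k - 1L))
  out
}
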
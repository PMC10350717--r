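#' Ridge-penalized logistic regression fit
#'
#' Maximum penalized likelihood for a binary outcome by Newton / iteratively
#' reweighted least squares. The penalty is `ridge * sum(beta_j^2)` over all
#' non-intercept coefficients, applied on an internally standardized scale:
#' non-intercept design columns are centered and scaled by their
#' fitting-sample mean and standard deviation (which also stabilizes the
#' optimization for variables such as calendar year), and coefficients and
#' covariance are reported back on the original scale. The covariance is
#' the inverse penalized observed information, which is what the proper
#' imputation step ([draw_binary_imputation()]) draws from. Rows with a
#' missing outcome or missing predictors must be excluded before calling.
#'
#' @param X Design matrix including an intercept column named
#'   `"(Intercept)"` (see [build_design()]).
#' @param y Binary 0/1 outcome vector (both levels must occur).
#' @param ridge Non-negative penalty; the default `1e-5` guards against
#'   separation in small waves while leaving estimates essentially
#'   unpenalized.
#' @param max_iter,tol Newton iteration controls.
#' @return A `binlogit_fit`: coefficients, covariance, unpenalized
#'   log-likelihood at the estimate, `n_fit`, `k_par`.
#' @export
fit_binary_logistic <- function(X, y, ridge = 1e-5, max_iter = 50L, tol = 1e-9) {
  y <- as.numeric(y)
  if (anyNA(y) || anyNA(X)) stop("fitting rows must be complete", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: only one observed level", call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  icol <- match("(Intercept)", colnames(X))
  if (is.na(icol)) stop("design must contain an '(Intercept)' column", call. = FALSE)
  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  mu[icol] <- 0; s[icol] <- 1
  s[s == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, s, "/")
  pen <- rep(2 * ridge, p); pen[icol] <- 0

  beta <- numeric(p)
  beta[icol] <- stats::qlogis(mean(y) * 0.998 + 0.001)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xs %*% beta)
    prob <- stats::plogis(eta)
    w <- prob * (1 - prob)
    g <- drop(crossprod(Xs, y - prob)) - pen * beta
    H <- crossprod(Xs * w, Xs)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, g), error = function(e) {
      stop("singular information matrix in logistic fit (ridge = ", ridge, ")", call. = FALSE)
    })
    # step-halving for stability far from the optimum
    obj0 <- sum(y * eta - log1p(exp(eta))) - sum(pen * beta^2) / 2
    lam <- 1
    repeat {
      bnew <- beta + lam * step
      etan <- drop(Xs %*% bnew)
      objn <- sum(y * etan - log1p(exp(etan))) - sum(pen * bnew^2) / 2
      if (is.finite(objn) && objn >= obj0 - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    beta <- bnew
    if (max(abs(lam * step)) < tol || max(abs(g)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    g <- drop(crossprod(Xs, y - stats::plogis(drop(Xs %*% beta)))) - pen * beta
    if (max(abs(g)) > 1e-4) {
      stop("logistic fit did not converge after ", max_iter,
           " iterations (max |gradient| = ", signif(max(abs(g)), 3),
           ", n = ", n, ", p = ", p, ")", call. = FALSE)
    }
  }
  eta <- drop(Xs %*% beta)
  prob <- stats::plogis(eta)
  w <- prob * (1 - prob)
  H <- crossprod(Xs * w, Xs)
  diag(H) <- diag(H) + pen
  Vs <- solve(H)
  # map standardized-scale estimates back to the original scale
  A <- diag(1 / s, p, p)
  A[icol, ] <- -mu / s
  A[icol, icol] <- 1
  coef <- drop(A %*% beta)
  V <- A %*% Vs %*% t(A)
  names(coef) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = coef, vcov = V,
                 loglik = sum(y * eta - log1p(exp(eta))),
                 n_fit = n, k_par = p, ridge = ridge),
            class = "binlogit_fit")
}

#' @export
coef.binlogit_fit <- function(object, ...) object$coefficients

#' @export
vcov.binlogit_fit <- function(object, ...) object$vcov

#' @export
logLik.binlogit_fit <- function(object, ...) {
  structure(object$loglik, df = object$k_par, nobs = object$n_fit, class = "logLik")
}

#' Bayesian information criterion of a fitted imputation model
#'
#' `BIC = k * ln(n) - 2 * loglik`, with the unpenalized log-likelihood
#' evaluated at the (lightly penalized) estimate; at the default ridge of
#' `1e-5` the discrepancy from the unpenalized optimum is negligible.
#' Lower is better.
#'
#' @param fit A `binlogit_fit` (or any object with `loglik`, `k_par`,
#'   `n_fit`).
#' @return Scalar BIC.
#' @export
bic <- function(fit) {
  if (is.null(fit$n_fit) || fit$n_fit == 0) stop("BIC undefined for an empty fit", call. = FALSE)
  fit$k_par * log(fit$n_fit) - 2 * fit$loglik
}

# MVN draw via eigendecomposition; tolerates a PSD covariance with
# zero eigenvalues (e.g. V = 0)
mvn_draw <- function(mean, V, tol = 1e-10) {
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  scale <- max(abs(e$values), 1)
  if (any(e$values < -tol * scale)) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  lam <- pmax(e$values, 0)
  drop(mean + e$vectors %*% (sqrt(lam) * stats::rnorm(length(mean))))
}

#' Proper imputation draw for a binary variable
#'
#' The "logreg" imputer: draws parameters `beta* ~ MVN(beta_hat, V_hat)`
#' from the asymptotic posterior approximation of the logistic fit, forms
#' predicted probabilities `plogis(X %*% beta*)` for the rows to impute,
#' and returns independent Bernoulli draws. Drawing the parameters (rather
#' than using the point estimate) is what makes the imputation proper, so
#' that between-imputation variance reflects model uncertainty.
#'
#' @param fit A `binlogit_fit`.
#' @param X_mis Design matrix for the rows to impute (same columns as the
#'   fitting design).
#' @return Integer 0/1 vector of length `nrow(X_mis)`.
#' @export
draw_binary_imputation <- function(fit, X_mis) {
  beta <- mvn_draw(fit$coefficients, fit$vcov)
  p <- stats::plogis(drop(X_mis %*% beta))
  stats::rbinom(length(p), 1L, p)
}
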
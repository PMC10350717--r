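# data frame with syntactic names for nnet::multinom (design matrix
# columns such as "year:age" are not valid formula variables)
design_frame <- function(X) {
  df <- as.data.frame(X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE])
  names(df) <- paste0("x", seq_along(df))
  df
}

#' Bootstrap imputation draw for a categorical variable
#'
#' The "polyreg" imputer: resamples the fitting records with replacement,
#' fits a multinomial logistic regression on the resample (via
#' [nnet::multinom()]), and draws each missing value from the fitted
#' category probabilities. The bootstrap refit plays the role of a
#' parameter draw, making the imputation proper. A resample missing one of
#' the observed outcome levels is retried (at most `max_retry` times).
#'
#' @param y_obs Factor of observed outcome values (>= 2 observed levels;
#'   typically >= 3, binary outcomes use [draw_binary_imputation()]).
#' @param X_obs Design matrix of the fitting rows (with intercept column).
#' @param X_mis Design matrix of the rows to impute.
#' @param max_retry Maximum bootstrap retries when a level is lost.
#' @return Character vector of drawn levels, length `nrow(X_mis)`.
#' @export
draw_polytomous_imputation <- function(y_obs, X_obs, X_mis, max_retry = 10L) {
  y_obs <- droplevels(as.factor(y_obs))
  lv <- levels(y_obs)
  if (length(lv) < 2L) {
    stop("degenerate outcome: fewer than 2 observed levels", call. = FALSE)
  }
  n <- length(y_obs)
  for (try in seq_len(max_retry)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (all(lv %in% y_obs[idx])) break
    if (try == max_retry) {
      stop("bootstrap resample lost an outcome level ", max_retry, " times", call. = FALSE)
    }
  }
  df <- design_frame(X_obs)[idx, , drop = FALSE]
  df$.y <- y_obs[idx]
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300,
                        MaxNWts = 5000)
  probs <- stats::predict(fit, newdata = design_frame(X_mis), type = "probs")
  if (is.null(dim(probs))) {  # K == 2: multinom returns P(level 2)
    probs <- cbind(1 - probs, probs)
  }
  colnames(probs) <- lv
  vapply(seq_len(nrow(probs)), function(i) {
    sample(lv, 1L, prob = probs[i, ])
  }, character(1))
}

# multinomial fit summary used only for BIC-based selection of
# categorical-outcome models
fit_polytomous <- function(X, y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("degenerate outcome: only one observed level", call. = FALSE)
  df <- design_frame(X)
  df$.y <- y
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300, MaxNWts = 5000)
  structure(list(loglik = -fit$deviance / 2,
                 n_fit = nrow(X),
                 k_par = (nlevels(y) - 1L) * ncol(X)),
            class = "polylogit_fit")
}
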
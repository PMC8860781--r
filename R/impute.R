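#' Fill missing outcome values from a fallback column
#'
#' Carry-forward preprocessing for longitudinal designs: where \code{target}
#' is missing and \code{fallback} (e.g. a baseline-wave measurement) is
#' observed, the fallback value is carried into the target column.
#'
#' @param table data.frame.
#' @param target,fallback column names.
#' @return the table with the target column filled where possible.
#' @export
fill_from_fallback <- function(table, target, fallback) {
  miss <- setdiff(c(target, fallback), names(table))
  if (length(miss))
    stop(errorCondition(paste0("column not found: ", paste(miss, collapse = ", ")),
                        class = c("smokesub_schema_error", "error")))
  idx <- is.na(table[[target]]) & !is.na(table[[fallback]])
  table[[target]][idx] <- table[[fallback]][idx]
  table
}

#' Stochastic-regression multiple imputation
#'
#' For each target column with missing values, a linear model on the complete
#' predictor columns is fitted to the observed rows; each of the \code{m}
#' completed datasets imputes with coefficients drawn from their asymptotic
#' normal distribution, a scaled-inverse-chi-square residual variance draw,
#' and added residual noise (proper imputation, valid under
#' missing-at-random). With no missingness all datasets equal the input.
#'
#' @param table data.frame.
#' @param predictors complete columns used in the imputation model (include
#'   the analysis outcome for congenial inference).
#' @param target columns to impute (default: every column of
#'   \code{predictors}' complement that has missing values among numeric
#'   columns named in \code{target}). Must be numeric.
#' @param m number of imputed datasets, at least 2 (default 25).
#' @param seed integer seed; draws are independent across datasets.
#' @return list of \code{m} completed data.frames.
#' @export
impute_missing <- function(table, predictors, target = NULL, m = 25, seed = 1) {
  m <- check_count(m, "m", min = 2L)
  if (is.null(target)) {
    target <- names(table)[vapply(table, function(x) is.numeric(x) && anyNA(x), logical(1))]
    target <- setdiff(target, predictors)
  }
  miss <- setdiff(c(predictors, target), names(table))
  if (length(miss))
    stop(errorCondition(paste0("column not found: ", paste(miss, collapse = ", ")),
                        class = c("smokesub_schema_error", "error")))
  if (any(vapply(table[predictors], anyNA, logical(1))))
    stop_param("imputation predictors must be complete")
  set.seed(seed)
  out <- replicate(m, table, simplify = FALSE)
  P <- cbind(1, as.matrix(table[, predictors, drop = FALSE]))
  for (tc in target) {
    yv <- table[[tc]]
    obs <- !is.na(yv)
    if (!any(obs))
      stop(errorCondition(paste0("no observed rows to impute '", tc, "' from"),
                          class = c("smokesub_imputation_error", "error")))
    if (!any(!obs)) next
    Xo <- P[obs, , drop = FALSE]
    fit <- stats::lm.fit(Xo, yv[obs])
    df <- sum(obs) - fit$rank
    if (df < 1) stop_param("too few observed rows for the imputation model")
    sigma2_hat <- sum(fit$residuals^2) / df
    R <- qr.R(fit$qr)
    XtX_inv <- chol2inv(R)
    piv <- fit$qr$pivot
    XtX_inv <- XtX_inv[order(piv), order(piv), drop = FALSE]
    L <- chol(XtX_inv)
    Xm <- P[!obs, , drop = FALSE]
    for (k in seq_len(m)) {
      sigma2_star <- sigma2_hat * df / stats::rchisq(1, df)
      beta_star <- fit$coefficients +
        sqrt(sigma2_star) * drop(crossprod(L, stats::rnorm(ncol(P))))
      out[[k]][[tc]][!obs] <- drop(Xm %*% beta_star) +
        stats::rnorm(nrow(Xm), 0, sqrt(sigma2_star))
    }
  }
  out
}

#' Pool fits over multiply imputed datasets by Rubin's rules
#'
#' Pooled estimate = mean over the \code{m} fits; total variance
#' \eqn{T = W + (1 + 1/m) B} with within-variance \eqn{W} (mean squared SE)
#' and between-variance \eqn{B}; p-values use a t reference with Rubin's
#' degrees of freedom \eqn{(m - 1)(1 + W / ((1 + 1/m) B))^2}.
#'
#' @param fits list of \code{fit_result}s over identical term sets, m >= 2.
#' @return object of class \code{pooled_fit}: data.frame with term, b, se,
#'   W, B, T, df, p (and or for logistic fits).
#' @export
pool_rubin <- function(fits) {
  m <- length(fits)
  if (m < 2L) stop_param("Rubin pooling needs at least 2 fits")
  terms <- fits[[1]]$coefficients$term
  for (f in fits)
    if (!identical(f$coefficients$term, terms))
      stop(errorCondition("fits have mismatched term sets",
                          class = c("smokesub_schema_error", "error")))
  bmat <- vapply(fits, function(f) f$coefficients$b, numeric(length(terms)))
  semat <- vapply(fits, function(f) f$coefficients$se, numeric(length(terms)))
  bmat <- matrix(bmat, nrow = length(terms))
  semat <- matrix(semat, nrow = length(terms))
  b <- rowMeans(bmat)
  W <- rowMeans(semat^2)
  B <- apply(bmat, 1, stats::var)
  Tv <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  tstat <- b / sqrt(Tv)
  p <- ifelse(is.finite(df), 2 * stats::pt(-abs(tstat), df),
              2 * stats::pnorm(-abs(tstat)))
  res <- data.frame(term = terms, b = b, se = sqrt(Tv), W = W, B = B, T = Tv,
                    df = df, p = pmax(p, .Machine$double.xmin),
                    stringsAsFactors = FALSE)
  if (fits[[1]]$family == "binomial") res$or <- exp(b)
  structure(list(coefficients = res, m = m, family = fits[[1]]$family),
            class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<pooled_fit> %d imputations, %s family\n", x$m, x$family))
  print(format(x$coefficients, digits = digits), ...)
  invisible(x)
}
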
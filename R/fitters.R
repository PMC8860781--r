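new_fit_result <- function(terms, b, se, p, family, r2 = NA_real_,
                           delta_r2 = NA_real_, n_used = NA_integer_,
                           converged = TRUE, extra = list()) {
  res <- data.frame(term = terms, b = b, se = se,
                    or = if (family == "binomial") exp(b) else NA_real_,
                    p = p, stringsAsFactors = FALSE)
  structure(c(list(coefficients = res, family = family, r2 = r2,
                   delta_r2 = delta_r2, n_used = n_used, converged = converged),
              extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 3, ...) {
  cat(sprintf("<fit_result> %s fit, n = %d, R2 = %s, delta R2 = %s\n",
              x$family, x$n_used,
              ifelse(is.na(x$r2), "NA", sprintf("%.1f%%", 100 * x$r2)),
              ifelse(is.na(x$delta_r2), "NA", sprintf("%.1f%%", 100 * x$delta_r2))))
  print(format(x$coefficients, digits = digits), ...)
  invisible(x)
}

# Nagelkerke pseudo-R2 relative to the intercept-only model
.nagelkerke <- function(deviance, null_deviance, n) {
  r2_cs <- 1 - exp((deviance - null_deviance) / n)
  denom <- 1 - exp(-null_deviance / n)
  if (denom <= 0) return(0)
  max(r2_cs / denom, 0)
}

#' Maximum-likelihood logistic regression
#'
#' IRLS logistic fit (via \code{glm.fit}) with Wald standard errors and
#' Nagelkerke pseudo-R2 against the intercept-only model. Diverging
#' coefficients (separation) raise a non-convergence error with diagnostics.
#'
#' @param design a \code{\link{build_design}} list or a design matrix
#'   including an intercept column.
#' @param outcome binary 0/1 vector (taken from \code{design} when omitted).
#' @return a \code{fit_result}.
#' @export
fit_logistic <- function(design, outcome = NULL) {
  X <- if (is.list(design)) design$X else as.matrix(design)
  y <- outcome %||% design$y
  if (length(unique(y[!is.na(y)])) != 2L)
    stop_param("logistic outcome needs both classes present")
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  if (!fit$converged || any(abs(fit$coefficients) > 20, na.rm = TRUE))
    stop(errorCondition(
      paste0("logistic fit did not converge (possible separation); max |b| = ",
             format(max(abs(fit$coefficients)), digits = 3)),
      class = c("smokesub_nonconvergence", "error")))
  W <- fit$weights
  vc <- solve(crossprod(X, X * W))
  se <- sqrt(diag(vc))
  b <- fit$coefficients
  z <- b / se
  r2 <- .nagelkerke(fit$deviance, fit$null.deviance, length(y))
  new_fit_result(colnames(X), b, se, two_sided_p(z), "binomial",
                 r2 = r2, n_used = length(y),
                 extra = list(vcov = vc, deviance = fit$deviance,
                              null_deviance = fit$null.deviance))
}

#' Ordinary least squares with the same result container
#'
#' @inheritParams fit_logistic
#' @return a \code{fit_result} with ordinary R2.
#' @export
fit_linear <- function(design, outcome = NULL) {
  X <- if (is.list(design)) design$X else as.matrix(design)
  y <- outcome %||% design$y
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- length(y) - fit$rank
  sigma2 <- rss / df
  R <- qr.R(fit$qr)
  vc <- chol2inv(R) * sigma2
  piv <- fit$qr$pivot
  vc <- vc[order(piv), order(piv), drop = FALSE]
  se <- sqrt(diag(vc))
  b <- fit$coefficients
  tstat <- b / se
  p <- 2 * stats::pt(-abs(tstat), df)
  r2 <- 1 - rss / sum((y - mean(y))^2)
  new_fit_result(colnames(X), b, se, p, "gaussian", r2 = r2,
                 n_used = length(y), extra = list(vcov = vc, sigma2 = sigma2))
}

#' Generalized estimating equations with exchangeable working correlation
#'
#' Marginal logistic or linear regression for clustered (family) data:
#' Fisher-scoring updates under a common within-cluster correlation alpha
#' (moment-estimated from Pearson residuals, or fixed via \code{alpha}), with
#' robust sandwich standard errors. With every cluster of size 1 the estimates
#' and robust SEs reduce to the independence fit. R2 is not defined for GEE
#' and is left NA here; \code{\link{run_model_ladder}} reports it from a
#' non-clustered refit.
#'
#' @param design a \code{\link{build_design}} list or design matrix.
#' @param outcome outcome vector (taken from \code{design} when omitted).
#' @param cluster_ids cluster membership vector (taken from \code{design}).
#' @param family \code{"binomial"} or \code{"gaussian"}.
#' @param alpha optional fixed working correlation (NULL = moment estimate).
#' @param max_iter,tol scoring iteration controls.
#' @return a \code{fit_result} with elements \code{alpha} and \code{vcov}
#'   (robust).
#' @export
fit_gee_exchangeable <- function(design, outcome = NULL, cluster_ids = NULL,
                                 family = c("binomial", "gaussian"),
                                 alpha = NULL, max_iter = 50, tol = 1e-8) {
  X <- if (is.list(design)) design$X else as.matrix(design)
  y <- outcome %||% design$y
  cl <- cluster_ids %||% (if (is.list(design)) design$cluster else NULL)
  if (is.null(cl)) stop_param("cluster_ids required for GEE")
  family <- match.arg(family)
  cl <- as.character(cl)
  groups <- split(seq_along(y), cl)
  if (length(groups) < 2L)
    stop(errorCondition("GEE needs at least 2 clusters",
                        class = c("smokesub_degenerate_clustering", "error")))
  p <- ncol(X)
  binom <- family == "binomial"
  beta <- if (binom) suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))$coefficients
          else stats::lm.fit(X, y)$coefficients
  beta[!is.finite(beta)] <- 0
  alpha_hat <- 0
  n_pairs <- sum(vapply(groups, function(g) length(g) * (length(g) - 1) / 2, numeric(1)))

  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- if (binom) stats::plogis(eta) else eta
    v <- if (binom) pmax(mu * (1 - mu), 1e-10) else rep(1, length(y))
    e <- (y - mu) / sqrt(v)
    phi <- sum(e^2) / (length(y) - p)
    if (is.null(alpha)) {
      alpha_hat <- if (n_pairs > p) {
        s <- sum(vapply(groups, function(g) {
          eg <- e[g]; (sum(eg)^2 - sum(eg^2)) / 2
        }, numeric(1)))
        min(max(s / (phi * (n_pairs - p)), 0), 0.99)
      } else 0
    } else alpha_hat <- alpha

    M <- matrix(0, p, p); U <- numeric(p)
    for (g in groups) {
      ni <- length(g)
      # canonical links: dmu/deta = v, so D' V^{-1} = (A^{1/2}X)' R^{-1} A^{-1/2} / phi
      Ag <- sqrt(v[g])
      rg <- (y[g] - mu[g]) / Ag
      Xs <- X[g, , drop = FALSE] * (v[g] / Ag)   # A^{-1/2} D
      if (ni == 1L || alpha_hat == 0) {
        Rinv_r <- rg
        Rinv_X <- Xs
      } else {
        c1 <- 1 / (1 - alpha_hat)
        c2 <- alpha_hat / ((1 - alpha_hat) * (1 + (ni - 1) * alpha_hat))
        Rinv_r <- c1 * rg - c2 * sum(rg)
        Rinv_X <- c1 * Xs - matrix(c2 * colSums(Xs), ni, p, byrow = TRUE)
      }
      U <- U + crossprod(Xs, Rinv_r) / phi
      M <- M + crossprod(Xs, Rinv_X) / phi
    }
    delta <- solve(M, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  converged <- max(abs(delta)) < tol

  # robust sandwich covariance at the final beta
  eta <- drop(X %*% beta)
  mu <- if (binom) stats::plogis(eta) else eta
  v <- if (binom) pmax(mu * (1 - mu), 1e-10) else rep(1, length(y))
  phi <- sum(((y - mu) / sqrt(v))^2) / (length(y) - p)
  M <- matrix(0, p, p); B <- matrix(0, p, p)
  for (g in groups) {
    ni <- length(g)
    Ag <- sqrt(v[g])
    rg <- (y[g] - mu[g]) / Ag
    Xs <- X[g, , drop = FALSE] * (v[g] / Ag)
    if (ni == 1L || alpha_hat == 0) {
      Rinv_r <- rg; Rinv_X <- Xs
    } else {
      c1 <- 1 / (1 - alpha_hat)
      c2 <- alpha_hat / ((1 - alpha_hat) * (1 + (ni - 1) * alpha_hat))
      Rinv_r <- c1 * rg - c2 * sum(rg)
      Rinv_X <- c1 * Xs - matrix(c2 * colSums(Xs), ni, p, byrow = TRUE)
    }
    ug <- crossprod(Xs, Rinv_r) / phi
    M <- M + crossprod(Xs, Rinv_X) / phi
    B <- B + tcrossprod(ug)
  }
  Minv <- solve(M)
  vc <- Minv %*% B %*% Minv
  se <- sqrt(diag(vc))
  z <- beta / se
  new_fit_result(colnames(X), beta, se, two_sided_p(z), family,
                 n_used = length(y), converged = converged,
                 extra = list(vcov = vc, alpha = alpha_hat, phi = phi,
                              n_clusters = length(groups)))
}
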
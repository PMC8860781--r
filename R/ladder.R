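#' Bonferroni-corrected significance threshold
#'
#' Exact division \code{alpha / n_tests}; rounding happens only in the
#' display attribute (3 decimal places), so 0.05/8 is carried as 0.00625 and
#' displayed as 0.006.
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of independent tests, at least 1.
#' @return the exact threshold with attribute \code{display}.
#' @examples
#' bonferroni_threshold(0.05, 8)   # 0.00625, displayed 0.006
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 1) {
  check_scalar(alpha, "alpha", 1e-300, 1)
  n_tests <- check_count(n_tests, "n_tests", min = 1L)
  thr <- alpha / n_tests
  structure(thr, display = format(round(thr, 3), scientific = FALSE))
}

.ladder_spec <- function(base, pgs, env = NULL, keller = FALSE) {
  s <- base
  s$pgs <- pgs; s$env <- env; s$keller <- keller
  s
}

#' The model ladder: PGS and environment effects on an outcome
#'
#' Fits the seven-model comparison on one analysis table: model 0 is
#' covariates only; 1a adds the all-smoking PGS and 1b the EA +
#' smoking-without-EA PGS pair; 2a/2b add the environment main effect; 3a/3b
#' add PGS x environment interactions flanked by the full Keller covariate
#' set (PC x E and PC x PGS products). With a cluster column the fits use
#' exchangeable GEE with robust SEs, and R2 (Nagelkerke for binary outcomes,
#' ordinary otherwise) comes from a non-clustered refit of the same design;
#' delta R2 is taken against model 0. PGS and environment terms are flagged
#' significant at the displayed multiple-testing threshold p < 0.006
#' (0.05 over 8 tests).
#'
#' @param table analysis data.frame containing outcome, PGS columns,
#'   environment, covariates, PCs (and optionally batch/cluster columns).
#' @param pgs_set named character vector with entries \code{allsmok},
#'   \code{ea}, \code{smok_noea} giving the PGS column names.
#' @param env_name environment column name.
#' @param outcome outcome column name (binary 0/1 or continuous).
#' @param cluster optional cluster id column name (enables GEE).
#' @param covariates,pcs,batch covariate configuration (see
#'   \code{\link{model_spec}}).
#' @return named list of \code{fit_result}s (\code{m0}, \code{m1a}, ...,
#'   \code{m3b}), class \code{model_ladder}, each with \code{r2},
#'   \code{delta_r2} and a \code{significant} flag column.
#' @export
run_model_ladder <- function(table, pgs_set, env_name, outcome,
                             cluster = NULL, covariates = c("age", "sex"),
                             pcs = grep("^pc[0-9]+$", names(table), value = TRUE),
                             batch = NULL) {
  need <- c("allsmok", "ea", "smok_noea")
  if (!all(need %in% names(pgs_set)))
    stop_param("pgs_set must name columns allsmok, ea, smok_noea")
  yvals <- unique(stats::na.omit(table[[outcome]]))
  binary <- length(yvals) == 2L && all(yvals %in% c(0, 1))
  family <- if (binary) "binomial" else "gaussian"
  base <- model_spec(outcome, covariates = covariates, pcs = pcs, batch = batch,
                     family = family, cluster_var = cluster)

  specs <- list(
    m0  = .ladder_spec(base, character()),
    m1a = .ladder_spec(base, pgs_set[["allsmok"]]),
    m1b = .ladder_spec(base, unname(pgs_set[c("ea", "smok_noea")])),
    m2a = .ladder_spec(base, pgs_set[["allsmok"]], env_name),
    m2b = .ladder_spec(base, unname(pgs_set[c("ea", "smok_noea")]), env_name),
    m3a = .ladder_spec(base, pgs_set[["allsmok"]], env_name, keller = TRUE),
    m3b = .ladder_spec(base, unname(pgs_set[c("ea", "smok_noea")]), env_name, keller = TRUE))

  thr <- bonferroni_threshold(0.05, 8)
  thr_disp <- as.numeric(attr(thr, "display"))
  r2_of <- function(d) {
    f <- if (binary) fit_logistic(d) else fit_linear(d)
    f$r2
  }
  r2_null <- NULL
  fits <- lapply(specs, function(sp) {
    d <- build_design(table, sp)
    fit <- if (!is.null(cluster)) fit_gee_exchangeable(d, family = family)
           else if (binary) fit_logistic(d) else fit_linear(d)
    fit$r2 <- r2_of(d)  # from non-clustered refit when GEE
    fit$coefficients$significant <- fit$coefficients$p < thr_disp
    fit
  })
  r2_null <- fits$m0$r2
  for (nm in names(fits)) fits[[nm]]$delta_r2 <- fits[[nm]]$r2 - r2_null
  structure(fits, class = "model_ladder", threshold = thr)
}

#' @export
print.model_ladder <- function(x, ...) {
  cat("<model_ladder>\n")
  for (nm in names(x))
    cat(sprintf("  %-4s R2 = %5.1f%% (delta = %5.1f%%)\n", nm,
                100 * x[[nm]]$r2, 100 * x[[nm]]$delta_r2))
  invisible(x)
}

#' Gene-environment correlation check
#'
#' Linear regression of a (possibly ordinal-as-continuous) outcome such as EA
#' or the neighborhood measure on a single PGS plus covariates. The reported
#' R2 excludes age and sex: it comes from a reduced refit on the PGS and
#' genetic covariates (PCs and batch) only.
#'
#' @param table analysis data.frame.
#' @param pgs_name PGS column name.
#' @param outcome outcome column name (continuous).
#' @inheritParams run_model_ladder
#' @return a \code{fit_result}; \code{r2} is the reduced-model value.
#' @export
rge_check <- function(table, pgs_name, outcome, covariates = c("age", "sex"),
                      pcs = grep("^pc[0-9]+$", names(table), value = TRUE),
                      batch = NULL) {
  full <- build_design(table, model_spec(outcome, pgs = pgs_name,
                                         covariates = covariates, pcs = pcs,
                                         batch = batch, family = "gaussian"))
  fit <- fit_linear(full)
  reduced <- build_design(table, model_spec(outcome, pgs = pgs_name,
                                            covariates = character(), pcs = pcs,
                                            batch = batch, family = "gaussian"))
  fit$r2 <- fit_linear(reduced)$r2
  fit
}
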
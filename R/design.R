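#' Model specification for the PGS regression ladder
#'
#' Declares outcome, polygenic-score predictors, an optional environment term,
#' covariates, and whether Keller interaction covariates (every PGS x E,
#' PC x E and PC x PGS product) accompany the tested G x E terms.
#'
#' @param outcome column name of the outcome.
#' @param pgs character vector of PGS column names.
#' @param env optional environment column name.
#' @param covariates non-PC covariate columns (default age and sex).
#' @param pcs principal-component column names.
#' @param batch optional categorical batch column (dummy-coded).
#' @param keller add the full interaction covariate set (requires \code{env}
#'   and at least one PGS).
#' @param family \code{"binomial"} or \code{"gaussian"}.
#' @param cluster_var optional cluster id column for GEE fitting.
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(outcome, pgs = character(), env = NULL,
                       covariates = c("age", "sex"), pcs = character(),
                       batch = NULL, keller = FALSE,
                       family = c("binomial", "gaussian"), cluster_var = NULL) {
  family <- match.arg(family)
  if (keller && (is.null(env) || !length(pgs)))
    stop_param("keller = TRUE requires an environment term and at least one PGS")
  structure(list(outcome = outcome, pgs = pgs, env = env,
                 covariates = covariates, pcs = pcs, batch = batch,
                 keller = isTRUE(keller), family = family,
                 cluster_var = cluster_var),
            class = "model_spec")
}

#' Build a design matrix from a phenotype table and model spec
#'
#' Continuous predictors (PGS, environment, age, PCs) are standardized in the
#' analysis sample before any products are formed; sex stays on its 1/2
#' numeric coding and batch is dummy-coded against its first level. With
#' Keller covariates on, the design gains one PGS x E column per PGS, one
#' PC x E column per PC and one PC x PGS column per pair beyond the main
#' effects. Rows with missing values in any used column are dropped.
#'
#' @param table data.frame (e.g. \code{\link{simulate_phenotypes}} output with
#'   PGS columns merged in).
#' @param spec a \code{\link{model_spec}}.
#' @return list with \code{X} (matrix incl. intercept), \code{y},
#'   \code{cluster} (or NULL), \code{spec}, \code{n_interactions}.
#' @export
build_design <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  used <- c(spec$outcome, spec$pgs, spec$env, spec$covariates, spec$pcs,
            spec$batch, spec$cluster_var)
  miss <- setdiff(used, names(table))
  if (length(miss))
    stop(errorCondition(paste0("column not found: ", paste(miss, collapse = ", ")),
                        class = c("smokesub_schema_error", "error")))
  tab <- table[stats::complete.cases(table[, used, drop = FALSE]), , drop = FALSE]
  y <- tab[[spec$outcome]]

  cont <- c(spec$pgs, spec$env, intersect(spec$covariates, c("age")), spec$pcs)
  Xc <- list(`(Intercept)` = rep(1, nrow(tab)))
  grab <- function(nm) if (nm %in% cont) std(tab[[nm]]) else as.numeric(tab[[nm]])
  for (nm in c(spec$covariates, spec$pcs)) Xc[[nm]] <- grab(nm)
  if (!is.null(spec$batch)) {
    f <- factor(tab[[spec$batch]])
    if (nlevels(f) > 1) {
      d <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(d) <- paste0(spec$batch, levels(f)[-1])
      for (k in seq_len(ncol(d))) Xc[[colnames(d)[k]]] <- d[, k]
    }
  }
  for (nm in spec$pgs) Xc[[nm]] <- grab(nm)
  if (!is.null(spec$env)) Xc[[spec$env]] <- grab(spec$env)

  n_int <- 0L
  if (spec$keller) {
    E <- Xc[[spec$env]]
    for (g in spec$pgs) { Xc[[paste0(g, ":", spec$env)]] <- Xc[[g]] * E; n_int <- n_int + 1L }
    for (pc in spec$pcs) { Xc[[paste0(pc, ":", spec$env)]] <- Xc[[pc]] * E; n_int <- n_int + 1L }
    for (pc in spec$pcs) for (g in spec$pgs) {
      Xc[[paste0(pc, ":", g)]] <- Xc[[pc]] * Xc[[g]]; n_int <- n_int + 1L
    }
  }
  X <- do.call(cbind, Xc)
  list(X = X, y = y,
       cluster = if (!is.null(spec$cluster_var)) tab[[spec$cluster_var]] else NULL,
       spec = spec, n_interactions = n_int)
}
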
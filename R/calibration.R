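# Reproducibility studies: each function reruns a pipeline stage end-to-end
# on freshly simulated cohorts and returns the per-replicate measurements.
# These back the package's calibration claims (mediation-path recovery, LDSC
# unbiasedness, SBLUP/ridge equivalence, GxE type-I error, MI coverage).

#' Synthetic 10-SNP QC demonstration panel
#'
#' A deterministic panel constructed so the standard QC filter has a known
#' outcome: 2 SNPs below 1% MAF, 1 SNP in extreme Hardy-Weinberg
#' disequilibrium (complete heterozygote deficit), 1 SNP with 89.5% call
#' rate, and 6 clean SNPs, giving n_pass = 6 with per-rule attribution.
#'
#' @param n samples (default 200; at least 100).
#' @return a \code{\link{genotype_panel}}.
#' @export
demo_qc_panel <- function(n = 200) {
  n <- check_count(n, "n", min = 100L)
  n <- 2L * (n %/% 2L)  # even split needed for the heterozygote-deficit SNP
  hwe_col <- function(p) { # HWE-proportioned deterministic genotype column
    counts <- round(n * c(p^2, 2 * p * (1 - p)))
    rep(c(2, 1, 0), c(counts[1], counts[2], n - sum(counts)))
  }
  cols <- list()
  for (k in 1:2) cols[[k]] <- c(rep(1, 2), rep(0, n - 2))        # MAF 2/(2n) < 1%
  cols[[3]] <- rep(c(2, 0), each = n / 2)                        # HWE chi2 = n
  c4 <- hwe_col(0.3); c4[seq_len(ceiling(0.105 * n))] <- NA      # call rate 89.5%
  cols[[4]] <- c4
  for (k in 5:10) cols[[k]] <- hwe_col(0.2 + 0.05 * k)
  X <- do.call(cbind, cols)
  meta <- data.frame(id = sprintf("qc%02d", 1:10), chrom = 1L,
                     pos_bp = 1000000L * (1:10), a1 = "A", a2 = "G",
                     block_id = 1:10, stringsAsFactors = FALSE)
  genotype_panel(X, meta)
}

# one subtraction-study replicate; returns the measured quantities
.subtraction_rep <- function(n, m, h2_ea, h2_direct, b_med, seed) {
  panel <- simulate_genotypes(n, m, block_size = 10, rho = 0.95, seed = seed)
  eff <- make_true_effects(m, h2_ea = h2_ea, h2_direct = h2_direct,
                           b_med = b_med, gamma_rge = 0, delta_gxe = 0,
                           seed = seed + 1)
  pheno <- simulate_phenotypes(panel, eff, n_pcs = 0, seed = seed + 2,
                               exposure_missing_rate = 0)
  ss_ea <- run_gwas(panel, pheno$ea_years, trait_label = "EA")
  # mediation paths are defined on the liability scale; analyze the liability
  ss_smok <- run_gwas(panel, pheno$smoking_liability, trait_label = "smoking")
  ld <- compute_ld_scores(panel)
  h2_ea_fit <- estimate_h2(ss_ea, ld)
  rg_fit <- estimate_rg(ss_ea, ss_smok, ld)
  med <- estimate_mediation_path(rg_fit, h2_ea_fit)
  ss_sub <- subtract_ea(ss_smok, ss_ea, med)
  rg_sub_ea <- estimate_rg(ss_sub, ss_ea, ld)
  rg_sub_smok <- estimate_rg(ss_sub, ss_smok, ld)
  c(b_hat = med$b_med_hat, b_se = med$se,
    rg_sub_ea = rg_sub_ea$rg, rg_sub_ea_se = rg_sub_ea$se_rg,
    rg_sub_smok = rg_sub_smok$rg,
    h2_sub = estimate_h2(ss_sub, ld)$h2, h2_smok = estimate_h2(ss_smok, ld)$h2)
}

#' Subtraction-recovery study
#'
#' Replicated full-pipeline recovery of a known EA-to-smoking mediation path
#' under full mediation of the EA-smoking genetic overlap (independent direct
#' effects): per replicate, simulate a cohort, run both GWAS, estimate the
#' path from LDSC covariances, subtract, and measure the genetic correlations
#' of the subtracted trait with EA and with the original smoking trait.
#'
#' @param n_reps replicates; \code{n}, \code{m} cohort size.
#' @param b_med generative path (default 0.4).
#' @param h2_ea,h2_direct generative heritabilities.
#' @param seed integer seed.
#' @return data.frame, one row per replicate.
#' @export
study_subtraction <- function(n_reps = 20, n = 8000, m = 2000, b_med = 0.4,
                              h2_ea = 0.5, h2_direct = 0.5, seed = 1) {
  rows <- lapply(seq_len(n_reps), function(r)
    .subtraction_rep(n, m, h2_ea, h2_direct, b_med, seed + 1000L * r))
  as.data.frame(do.call(rbind, rows))
}

#' LDSC heritability calibration study
#'
#' Replicated recovery of a generative SNP-heritability by LD score
#' regression: simulate a cohort with the given \code{h2} on a continuous
#' trait, run the GWAS, and estimate h2 and the intercept.
#'
#' @inheritParams study_subtraction
#' @param h2 generative heritability (0 gives the null calibration).
#' @return data.frame with h2_hat and intercept per replicate.
#' @export
study_ldsc_h2 <- function(n_reps = 20, n = 4000, m = 2000, h2 = 0.5, seed = 1) {
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- seed + 1000L * r
    panel <- simulate_genotypes(n, m, block_size = 10, rho = 0.95, seed = s)
    eff <- make_true_effects(m, h2_ea = h2, h2_direct = 0, b_med = 0,
                             gamma_rge = 0, seed = s + 1)
    pheno <- simulate_phenotypes(panel, eff, n_pcs = 0, seed = s + 2,
                                 exposure_missing_rate = 0)
    fit <- estimate_h2(run_gwas(panel, pheno$ea_years), compute_ld_scores(panel))
    c(h2_hat = fit$h2, h2_se = fit$se, intercept = fit$intercept)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Sample-overlap rg calibration study
#'
#' Two traits with independently drawn per-SNP effects (true rg = 0) but
#' residuals sharing a common component and measured on the same individuals
#' (phenotypic correlation 0.25); checks that the free cross-trait LDSC
#' intercept absorbs the overlap so the estimated genetic correlation stays
#' unbiased at zero.
#'
#' @inheritParams study_subtraction
#' @return data.frame with rg_hat and cross_intercept per replicate.
#' @export
study_overlap_rg <- function(n_reps = 20, n = 4000, m = 2000, seed = 1) {
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- seed + 1000L * r
    panel <- simulate_genotypes(n, m, block_size = 10, rho = 0.95, seed = s)
    set.seed(s + 1)
    Z <- scale(panel$dosages)
    u1 <- stats::rnorm(m)
    u2 <- stats::rnorm(m)
    g1 <- drop(Z %*% u1); g1 <- g1 * sqrt(0.5) / stats::sd(g1)
    g2 <- drop(Z %*% u2); g2 <- g2 * sqrt(0.5) / stats::sd(g2)
    e_shared <- stats::rnorm(n)
    y1 <- g1 + sqrt(0.25) * e_shared + sqrt(0.25) * stats::rnorm(n)
    y2 <- g2 + sqrt(0.25) * e_shared + sqrt(0.25) * stats::rnorm(n)
    ld <- compute_ld_scores(panel)
    rg <- estimate_rg(run_gwas(panel, y1, trait_label = "t1"),
                      run_gwas(panel, y2, trait_label = "t2"), ld)
    c(rg_hat = rg$rg_raw, cross_intercept = rg$cross_intercept)
  })
  as.data.frame(do.call(rbind, rows))
}

#' SBLUP versus individual-level ridge oracle
#'
#' On a single-block panel, compares summary-statistic SBLUP weights with the
#' individual-level ridge solution \eqn{(X'X + \lambda I)^{-1} X'y} computed
#' by a dense solve on the raw (centered) data, and evaluates the exact
#' lambda limits.
#'
#' @param n,m panel size (default 500 x 50, one LD block).
#' @param h2 trait heritability used for the shrinkage lambda.
#' @param seed integer seed.
#' @return list with \code{cor_ridge} (correlation of the two weight
#'   vectors), \code{w_sblup}, \code{w_ridge}, \code{lambda}.
#' @export
study_sblup_oracle <- function(n = 500, m = 50, h2 = 0.5, seed = 1) {
  panel <- simulate_genotypes(n, m, block_size = m, rho = 0.8, seed = seed)
  eff <- make_true_effects(m, h2_ea = h2, h2_direct = 0, b_med = 0,
                           gamma_rge = 0, seed = seed + 1)
  pheno <- simulate_phenotypes(panel, eff, n_pcs = 0, seed = seed + 2,
                               exposure_missing_rate = 0)
  y <- pheno$ea_years
  ss <- run_gwas(panel, y)
  w <- sblup_weights(ss, ld_block_cor(panel), h2 = h2, m = m)
  lambda <- attr(w, "lambda")
  # oracle: ridge on centered/standardized raw data, matching the summary view
  Xc <- scale(panel$dosages)
  w_ridge <- solve(crossprod(Xc) + diag(lambda, m), crossprod(Xc, y - mean(y)))
  # put SBLUP weights on the standardized-genotype scale for comparison
  sdx <- apply(panel$dosages, 2, stats::sd)
  list(cor_ridge = stats::cor(w$weight * sdx, drop(w_ridge)),
       w_sblup = w$weight, w_ridge = drop(w_ridge), lambda = lambda)
}

# shared machinery for the GxE studies: one cohort, PGS from true direct
# effects, Keller-covariate logistic model, returns the PGS x E row
.gxe_fit_rep <- function(n, m, delta_gxe, seed, n_pcs = 10) {
  panel <- simulate_genotypes(n, m, block_size = 5, rho = 0.5, seed = seed)
  eff <- make_true_effects(m, h2_ea = 0.1, h2_direct = 0.2, b_med = 0,
                           gamma_rge = 0, delta_gxe = delta_gxe, seed = seed + 1)
  pheno <- simulate_phenotypes(panel, eff, n_pcs = n_pcs, seed = seed + 2,
                               exposure_missing_rate = 0)
  w <- data.frame(id = panel$snp_meta$id, a1 = panel$snp_meta$a1,
                  a2 = panel$snp_meta$a2, weight = eff$beta_direct)
  tab <- as.data.frame(pheno)
  tab$pgs_direct <- as.numeric(score_individuals(panel, w))
  d <- build_design(tab, model_spec("smoker", pgs = "pgs_direct",
                                    env = "exposure", keller = TRUE,
                                    pcs = paste0("pc", seq_len(n_pcs))))
  fit <- fit_logistic(d)
  fit$coefficients[fit$coefficients$term == "pgs_direct:exposure", ]
}

#' Type-I error of the PGS x environment Wald test
#'
#' Null cohorts (no generative interaction) fitted with the full Keller
#' covariate set; returns the per-fit Wald p-values of the PGS x E term, whose
#' rejection rate at 0.05 should sit inside the binomial band.
#'
#' @param n_fits number of null fits; \code{n}, \code{m} cohort size.
#' @param seed integer seed.
#' @return numeric vector of p-values.
#' @export
study_gxe_type1 <- function(n_fits = 500, n = 2000, m = 200, seed = 1) {
  vapply(seq_len(n_fits), function(r)
    .gxe_fit_rep(n, m, delta_gxe = 0, seed = seed + 1000L * r)$p, numeric(1))
}

#' Sign recovery of a generative PGS x environment interaction
#'
#' Cohorts with a positive liability-scale interaction; returns the fitted
#' PGS x E coefficients, whose sign should match in nearly all replicates.
#'
#' @param n_reps replicates; \code{delta_gxe} generative coefficient.
#' @inheritParams study_gxe_type1
#' @return numeric vector of fitted interaction coefficients.
#' @export
study_gxe_sign <- function(n_reps = 50, n = 10000, m = 500, delta_gxe = 0.15,
                           seed = 1) {
  vapply(seq_len(n_reps), function(r)
    .gxe_fit_rep(n, m, delta_gxe = delta_gxe, seed = seed + 1000L * r)$b,
    numeric(1))
}

#' Multiple-imputation confidence-interval coverage
#'
#' Linear generative model with 10% MCAR missingness in the exposure;
#' each replicate imputes, fits the outcome model per dataset, pools by
#' Rubin's rules, and records whether the pooled 95% CI covers the true
#' slope.
#'
#' @param n_reps replicates; \code{n} sample size; \code{slope} true effect;
#'   \code{miss_rate} MCAR missingness; \code{m_imp} imputations.
#' @param seed integer seed.
#' @return data.frame with pooled slope, se, and covered flag per replicate.
#' @export
study_mi_coverage <- function(n_reps = 50, n = 1000, slope = 0.3,
                              miss_rate = 0.1, m_imp = 10, seed = 1) {
  rows <- lapply(seq_len(n_reps), function(r) {
    set.seed(seed + 1000L * r)
    z <- stats::rnorm(n)
    e <- 0.6 * z + stats::rnorm(n, 0, 0.8)
    y <- slope * e + stats::rnorm(n)
    tab <- data.frame(z = z, e = e, y = y)
    tab$e[sample.int(n, round(miss_rate * n))] <- NA
    imp <- impute_missing(tab, predictors = c("z", "y"), target = "e",
                          m = m_imp, seed = seed + 1000L * r + 1L)
    fits <- lapply(imp, function(d)
      fit_linear(list(X = cbind(`(Intercept)` = 1, e = d$e), y = d$y)))
    pooled <- pool_rubin(fits)
    row <- pooled$coefficients[pooled$coefficients$term == "e", ]
    crit <- stats::qt(0.975, max(row$df, 1))
    c(b = row$b, se = row$se,
      covered = as.numeric(abs(row$b - slope) <= crit * row$se))
  })
  as.data.frame(do.call(rbind, rows))
}
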
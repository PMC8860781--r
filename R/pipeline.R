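#' Run the full subtraction pipeline on a synthetic cohort
#'
#' End-to-end flow: simulate a cohort, QC-filter, GWAS for EA and smoking,
#' LD scores, heritabilities, EA-smoking genetic covariance, mediation path,
#' per-SNP subtraction, clumping, SBLUP weights and scores for the three
#' traits (all-smoking, EA, smoking-without-EA), the model ladder on the
#' binary smoking outcome, rGE checks, and multiply-imputed / pooled
#' environment models. Every output table is written under \code{out_dir}
#' when given; the run is fully reproducible from \code{cfg$seed}.
#'
#' @param cfg a \code{\link{default_config}} list.
#' @param out_dir optional output directory for TSV artifacts and a manifest.
#' @param eff optional \code{\link{make_true_effects}} override.
#' @param quiet suppress per-stage log messages (logged to stderr).
#' @return invisible list with every intermediate object.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = NULL, eff = NULL,
                         quiet = FALSE) {
  log <- function(...) if (!quiet) message("[smokesub] ", sprintf(...))
  seed <- cfg$seed
  eff <- eff %||% make_true_effects(cfg$m, seed = seed + 1)

  log("simulate: n = %d, m = %d", cfg$n, cfg$m)
  panel <- simulate_genotypes(cfg$n, cfg$m, cfg$block_size, cfg$rho,
                              c(cfg$maf_lo, cfg$maf_hi), seed = seed)
  pheno <- simulate_phenotypes(panel, eff, n_pcs = cfg$n_pcs, seed = seed + 2,
                               exposure_missing_rate = cfg$exposure_missing_rate)

  qc <- qc_filter(panel, cfg$qc_maf_min, cfg$qc_hwe_p_min, cfg$qc_callrate_min)
  log("qc: %d of %d SNPs pass", qc$report$n_pass, qc$report$n_input)

  covar <- as.matrix(cbind(age = std(pheno$age), sex = pheno$sex,
                           pheno[, grep("^pc[0-9]+$", names(pheno)), drop = FALSE]))
  ss_ea <- run_gwas(qc$panel, pheno$ea_years, covar, trait_label = "EA")
  ss_smok <- run_gwas(qc$panel, pheno$smoker, covar, binary = TRUE,
                      trait_label = "smoking")
  log("gwas: EA and smoking scans done (%d SNPs)", nrow(ss_ea))

  ld <- compute_ld_scores(qc$panel)
  h2_ea <- estimate_h2(ss_ea, ld)
  h2_smok <- estimate_h2(ss_smok, ld)
  # at desk scale an estimated h2 can be non-positive; the genetic covariance
  # (all the mediation path needs) is still defined, so degrade gracefully
  rg <- tryCatch(estimate_rg(ss_ea, ss_smok, ld),
                 smokesub_undefined_rg = function(e) {
                   log("ldsc: rg undefined (non-positive h2); keeping gcov")
                   structure(list(rg = NA_real_, rg_raw = NA_real_,
                                  gcov = e$gcov, gcov_loo = e$gcov_loo,
                                  cross_intercept = e$cross_intercept,
                                  se_rg = NA_real_, se_gcov = e$se_gcov,
                                  h2_1 = e$h2_1, h2_2 = e$h2_2,
                                  n_blocks = e$n_blocks, m = attr(ld, "m_ref"),
                                  traits = c("EA", "smoking")),
                             class = "rg_estimate")
                 })
  log("ldsc: h2_EA = %.3f, h2_smok = %.3f, rg = %.3f", h2_ea$h2, h2_smok$h2, rg$rg)

  med <- estimate_mediation_path(rg, h2_ea)
  ss_sub <- subtract_ea(ss_smok, ss_ea, med)
  h2_sub <- estimate_h2(ss_sub, ld)
  log("subtract: b = %.3f (SE %.3f), h2_subtracted = %.3f", med$b_med_hat, med$se, h2_sub$h2)

  loci <- clump_loci(ss_sub, qc$panel, cfg$clump_p, cfg$clump_r2, cfg$clump_dist_bp)
  log("clump: %d independent loci", length(loci))

  blocks <- ld_block_cor(qc$panel)
  w_all <- sblup_weights(ss_smok, blocks, max(h2_smok$h2, 0.01))
  w_ea <- sblup_weights(ss_ea, blocks, max(h2_ea$h2, 0.01))
  w_sub <- sblup_weights(ss_sub, blocks, max(h2_sub$h2, 0.01))
  tab <- as.data.frame(pheno)
  tab$pgs_allsmok <- as.numeric(score_individuals(panel, w_all))
  tab$pgs_ea <- as.numeric(score_individuals(panel, w_ea))
  tab$pgs_smok_noea <- as.numeric(score_individuals(panel, w_sub))
  log("pgs: three SBLUP scores computed")

  pgs_set <- c(allsmok = "pgs_allsmok", ea = "pgs_ea", smok_noea = "pgs_smok_noea")
  complete_tab <- tab[!is.na(tab$exposure), ]
  ladder <- run_model_ladder(complete_tab, pgs_set, "exposure", "smoker",
                             cluster = if (any(duplicated(tab$cluster_id))) "cluster_id")
  rge <- lapply(stats::setNames(nm = unname(pgs_set)), function(g)
    rge_check(tab, g, "exposure"))
  imp <- impute_missing(tab, predictors = c("age", "sex", "ea_years", "smoker"),
                        target = "exposure", m = cfg$m_imputations,
                        seed = seed + 3)
  pooled <- pool_rubin(lapply(imp, function(d) {
    fit_logistic(build_design(d, model_spec("smoker", pgs = unname(pgs_set),
                                            env = "exposure",
                                            pcs = grep("^pc[0-9]+$", names(d), value = TRUE))))
  }))
  log("gxe: ladder, rGE checks and %d-imputation pooling done", cfg$m_imputations)

  res <- list(config = cfg, effects = eff, panel = panel, phenotypes = pheno,
              qc = qc, ss_ea = ss_ea, ss_smok = ss_smok, ld = ld,
              h2_ea = h2_ea, h2_smok = h2_smok, h2_sub = h2_sub, rg = rg,
              mediation = med, ss_sub = ss_sub, loci = loci,
              analysis_table = tab, ladder = ladder, rge = rge, pooled = pooled)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  invisible(res)
}

.ladder_table <- function(ladder) {
  do.call(rbind, lapply(names(ladder), function(nm) {
    co <- ladder[[nm]]$coefficients
    data.frame(model = nm, term = co$term, b = co$b, se = co$se, or = co$or,
               p = co$p, R2 = ladder[[nm]]$r2, delta_R2 = ladder[[nm]]$delta_r2,
               stringsAsFactors = FALSE)
  }))
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write_panel(res$panel, fp("panel"))
  write_phenotypes(res$phenotypes, fp("phenotypes.tsv"))
  write_sumstats(res$ss_ea, fp("sumstats_ea.tsv"))
  write_sumstats(res$ss_smok, fp("sumstats_smoking.tsv"))
  write_sumstats(res$ss_sub, fp("sumstats_smoking_without_ea.tsv"))
  loci_df <- if (length(res$loci))
    do.call(rbind, lapply(res$loci, function(l)
      data.frame(lead_snp = l$lead_snp, chrom = l$chrom, pos_bp = l$pos_bp,
                 lead_p = l$lead_p,
                 member_snps = paste(l$member_snps, collapse = ","),
                 stringsAsFactors = FALSE)))
    else data.frame(lead_snp = character(), chrom = integer(), pos_bp = integer(),
                    lead_p = numeric(), member_snps = character())
  .write_table(loci_df, fp("loci.tsv"))
  .write_table(.ladder_table(res$ladder), fp("table1_models.tsv"))
  rge_df <- do.call(rbind, lapply(names(res$rge), function(g) {
    co <- res$rge[[g]]$coefficients
    row <- co[co$term == g, ]
    data.frame(pgs = g, b = row$b, se = row$se, p = row$p, R2 = res$rge[[g]]$r2,
               stringsAsFactors = FALSE)
  }))
  .write_table(rge_df, fp("table2_rge.tsv"))
  .write_table(res$pooled$coefficients, fp("pooled_models.tsv"))
  summ <- data.frame(
    key = c("seed", "n", "m", "qc_n_pass", "h2_ea", "h2_smoking",
            "h2_smoking_without_ea", "rg_ea_smoking", "b_med", "se_b_med",
            "n_loci_subtracted"),
    value = c(res$config$seed, res$config$n, res$config$m, res$qc$report$n_pass,
              res$h2_ea$h2, res$h2_smok$h2, res$h2_sub$h2, res$rg$rg,
              res$mediation$b_med_hat, res$mediation$se, length(res$loci)))
  .write_table(summ, fp("manifest.tsv"))
  invisible(out_dir)
}
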
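#' Per-SNP association scan
#'
#' Ordinary least squares of the outcome on each SNP's dosage plus shared
#' covariates, computed for all SNPs at once through the Frisch-Waugh
#' decomposition (outcome and dosages residualized on the covariates, then
#' per-SNP simple regression with the joint model's residual degrees of
#' freedom). Binary outcomes are analyzed on the observed scale with the same
#' linear model, as mixed-model GWAS tools do; the flag is recorded in the
#' trait metadata only. Missing dosages are mean-imputed within SNP;
#' \code{n_eff} records the per-SNP observed-call count among analyzed rows.
#'
#' @param panel a \code{\link{genotype_panel}} (ideally QC-passed).
#' @param outcome numeric vector, one value per panel sample.
#' @param covariates optional numeric matrix/data.frame of covariates (no
#'   intercept column; one is added). Rank deficiency raises an error naming
#'   the offending column.
#' @param binary logical flag recorded in the output metadata.
#' @param trait_label name attached to the resulting sumstats.
#' @param one_per_family down-sample to the first member of each family
#'   cluster, so the fixed-effect scan runs on unrelated individuals.
#' @return a \code{\link{new_sumstats}} object with chrom/pos columns.
#' @export
run_gwas <- function(panel, outcome, covariates = NULL, binary = FALSE,
                     trait_label = "trait", one_per_family = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  n0 <- nrow(panel$dosages)
  if (length(outcome) != n0) stop_param("outcome length must match panel samples")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n0) stop_param("covariates rows must match panel samples")
  }
  keep <- !is.na(outcome)
  if (isTRUE(one_per_family)) keep <- keep & !duplicated(panel$family_ids)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  X <- panel$dosages[keep, , drop = FALSE]
  y <- outcome[keep]
  n <- length(y)
  C <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) covariates[keep, , drop = FALSE])
  qC <- qr(C)
  if (qC$rank < ncol(C)) {
    bad <- colnames(C)[setdiff(seq_len(ncol(C)), qC$pivot[seq_len(qC$rank)])]
    stop(errorCondition(paste0("rank-deficient covariates: ", paste(bad, collapse = ", ")),
                        class = c("smokesub_singular_error", "error")))
  }
  if (n <= ncol(C) + 1L) stop_param("too few complete cases for the covariate set")

  n_eff <- colSums(!is.na(X))
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    idx <- which(is.na(X))
    X[idx] <- mu[((idx - 1L) %/% nrow(X)) + 1L]
  }
  yr <- qr.resid(qC, y)
  Xr <- qr.resid(qC, X)
  sxx <- colSums(Xr^2)
  sxy <- colSums(Xr * yr)
  syy <- sum(yr^2)
  beta <- ifelse(sxx > 0, sxy / sxx, 0)
  df <- n - ncol(C) - 1L
  sigma2 <- pmax(syy - beta * sxy, 0) / df
  se <- ifelse(sxx > 0, sqrt(sigma2 / sxx), Inf)
  se[se == 0] <- .Machine$double.xmin  # exact fits: keep se positive

  meta <- panel$snp_meta
  ss <- data.frame(id = meta$id, chrom = meta$chrom, pos_bp = meta$pos_bp,
                   a1 = meta$a1, a2 = meta$a2,
                   freq_a1 = pmin(pmax(mu / 2, 1e-12), 1 - 1e-12),
                   beta = beta, se = se, n_eff = n_eff,
                   stringsAsFactors = FALSE)
  out <- new_sumstats(ss, trait_label = trait_label)
  attr(out, "binary") <- isTRUE(binary)
  out
}
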
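#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' expectations at the observed allele frequency. Monomorphic input carries no
#' information and returns p = 1 by convention.
#'
#' @param n_aa,n_ab,n_bb genotype counts (homozygote, heterozygote, homozygote).
#' @return two-sided p-value in (0, 1].
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions -> 1
#' hwe_test(100, 0, 100)  # complete heterozygote deficit -> ~0
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  cnt <- c(n_aa, n_ab, n_bb)
  if (any(!is.finite(cnt)) || any(cnt < 0)) stop_param("genotype counts must be non-negative")
  n <- sum(cnt)
  if (n < 1) stop_param("need at least one genotype")
  p_a <- (2 * n_aa + n_ab) / (2 * n)
  if (p_a <= 0 || p_a >= 1) return(1)
  expd <- n * c(p_a^2, 2 * p_a * (1 - p_a), (1 - p_a)^2)
  chi2 <- sum((cnt - expd)^2 / expd)
  max(stats::pchisq(chi2, df = 1, lower.tail = FALSE), .Machine$double.xmin)
}

#' SNP quality-control filter
#'
#' Keeps SNPs with minor allele frequency at or above \code{maf_min}, HWE
#' p-value at or above \code{hwe_p_min} and call rate at or above
#' \code{callrate_min} (all boundaries inclusive; defaults are the standard
#' MAF 1% / HWE 1e-10 / 95% call-rate filters). Failures are attributed with
#' precedence MAF, then HWE, then call rate, so the report counts partition
#' the input. MAF and HWE are computed on observed (non-missing) calls;
#' genotype classes for HWE come from rounding dosages.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param maf_min,hwe_p_min,callrate_min thresholds.
#' @return list with elements \code{panel} (filtered) and \code{report}
#'   (class \code{qc_report}: counts n_input, n_fail_maf, n_fail_hwe,
#'   n_fail_callrate, n_pass, thresholds, and per-SNP fail reason).
#' @export
qc_filter <- function(panel, maf_min = 0.01, hwe_p_min = 1e-10, callrate_min = 0.95) {
  stopifnot(inherits(panel, "genotype_panel"))
  check_scalar(maf_min, "maf_min", 0, 0.5)
  check_scalar(hwe_p_min, "hwe_p_min", 0, 1)
  check_scalar(callrate_min, "callrate_min", 0, 1)
  X <- panel$dosages
  n <- nrow(X)
  callrate <- colMeans(!is.na(X))
  freq <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  geno <- round(X)
  hwe_p <- vapply(seq_len(ncol(X)), function(j) {
    g <- geno[, j]
    hwe_test(sum(g == 2, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
             sum(g == 0, na.rm = TRUE))
  }, numeric(1))

  reason <- rep("pass", ncol(X))
  reason[callrate < callrate_min] <- "callrate"
  reason[hwe_p < hwe_p_min] <- "hwe"
  reason[maf < maf_min | is.nan(maf)] <- "maf"
  keep <- reason == "pass"

  report <- structure(list(n_input = ncol(X),
                           n_fail_maf = sum(reason == "maf"),
                           n_fail_hwe = sum(reason == "hwe"),
                           n_fail_callrate = sum(reason == "callrate"),
                           n_pass = sum(keep),
                           thresholds = c(maf_min = maf_min, hwe_p_min = hwe_p_min,
                                          callrate_min = callrate_min),
                           snp_fail_reason = stats::setNames(reason, colnames(X))),
                      class = "qc_report")
  if (!any(keep))
    stop(errorCondition("no SNP survives QC", class = c("smokesub_empty_panel", "error")))
  out <- genotype_panel(X[, keep, drop = FALSE], panel$snp_meta[keep, , drop = FALSE],
                        panel$sample_ids, panel$family_ids)
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d SNPs in: %d fail MAF, %d fail HWE, %d fail call rate, %d pass\n",
              x$n_input, x$n_fail_maf, x$n_fail_hwe, x$n_fail_callrate, x$n_pass))
  invisible(x)
}
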
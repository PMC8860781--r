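#' Per-block LD correlation matrices
#'
#' Computes the dosage correlation matrix of each LD block of a panel, the
#' reference structure consumed by \code{\link{sblup_weights}}.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @return named list, one element per block: \code{list(ids, R)}.
#' @export
ld_block_cor <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X))
    X[idx] <- mu[((idx - 1L) %/% nrow(X)) + 1L]
  }
  blocks <- panel$snp_meta$block_id
  out <- lapply(sort(unique(blocks)), function(b) {
    j <- which(blocks == b)
    R <- suppressWarnings(stats::cor(X[, j, drop = FALSE]))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    list(ids = panel$snp_meta$id[j], R = R)
  })
  names(out) <- paste0("block", sort(unique(blocks)))
  out
}

#' SBLUP shrinkage of marginal GWAS effects
#'
#' Summary-statistic BLUP: within each LD block B the joint weights solve the
#' ridge system \eqn{(N R_B + \lambda I) w_B = N \beta_B} with
#' \eqn{\lambda = m (1 - h^2) / h^2}, the whole genome entering without any
#' p-value threshold. Block-diagonal solves only; N is the median per-SNP
#' sample size. Because \eqn{R_B} is a correlation matrix, the system lives on
#' the standardized-genotype scale: marginal dosage-scale betas are converted
#' in via \eqn{\beta_{std,j} = \beta_j \sqrt{2 f_j (1 - f_j)}} and the solved
#' weights converted back, so the result scores raw dosages directly and
#' matches the individual-level ridge solution on standardized genotypes.
#' SNPs without frequency information stay on their original scale.
#'
#' @param ss sumstats providing marginal \code{beta} estimates.
#' @param ld_blocks \code{\link{ld_block_cor}} output covering all SNPs in
#'   \code{ss}.
#' @param h2 trait SNP-heritability in (0, 1).
#' @param m total SNP count entering the shrinkage (default \code{nrow(ss)}).
#' @return object of class \code{pgs_weights}: data.frame (id, a1, a2,
#'   freq_a1, weight) with attributes \code{lambda} and \code{source_trait}.
#' @export
sblup_weights <- function(ss, ld_blocks, h2, m = NULL) {
  stopifnot(inherits(ss, "sumstats"))
  check_scalar(h2, "h2", 1e-12, 1 - 1e-12)
  m <- m %||% nrow(ss)
  lambda <- m * (1 - h2) / h2
  N <- stats::median(ss$n_eff)
  sdx <- ifelse(is.na(ss$freq_a1), 1, sqrt(2 * ss$freq_a1 * (1 - ss$freq_a1)))
  w <- stats::setNames(rep(NA_real_, nrow(ss)), ss$id)
  for (blk in ld_blocks) {
    j <- match(blk$ids, ss$id)
    ok <- !is.na(j)
    if (!any(ok)) next
    R <- blk$R[ok, ok, drop = FALSE]
    beta_std <- ss$beta[j[ok]] * sdx[j[ok]]
    sol <- tryCatch(solve(N * R + diag(lambda, nrow(R)), N * beta_std),
                    error = function(e) stop_param("singular SBLUP system in a block"))
    w[j[ok]] <- sol / sdx[j[ok]]
  }
  if (anyNA(w)) stop_param("LD blocks do not cover all sumstats SNPs")
  structure(data.frame(id = ss$id, a1 = ss$a1, a2 = ss$a2,
                       freq_a1 = ss$freq_a1, weight = unname(w),
                       stringsAsFactors = FALSE),
            lambda = lambda, h2 = h2, m = m, N = N,
            source_trait = trait_label(ss),
            class = c("pgs_weights", "data.frame"))
}

#' Score individuals with per-SNP weights
#'
#' Raw score \eqn{s_i = \sum_j d_{ij} w_j} over the SNPs shared between panel
#' and weights, with allele harmonization (weight sign flipped when a1/a2 are
#' swapped; mismatches dropped) and missing dosages replaced by twice the
#' panel allele frequency. Scores are standardized to mean 0, SD 1 in the
#' scoring sample.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param w a \code{\link{sblup_weights}} object (any data.frame with id, a1,
#'   a2, weight works).
#' @return object of class \code{pgs_vector}: named numeric vector with
#'   attributes \code{raw}, \code{n_snps_used}, \code{source_trait}.
#' @export
score_individuals <- function(panel, w) {
  stopifnot(inherits(panel, "genotype_panel"))
  j <- match(w$id, panel$snp_meta$id)
  found <- !is.na(j)
  a1p <- panel$snp_meta$a1[j]; a2p <- panel$snp_meta$a2[j]
  same <- found & w$a1 == a1p & w$a2 == a2p
  flip <- found & w$a1 == a2p & w$a2 == a1p
  use <- same | flip
  if (!any(use))
    stop(errorCondition("no overlapping SNPs between panel and weights",
                        class = c("smokesub_alignment_error", "error")))
  X <- panel$dosages[, j[use], drop = FALSE]
  freq <- colMeans(X, na.rm = TRUE) / 2
  if (anyNA(X)) {
    idx <- which(is.na(X))
    X[idx] <- 2 * freq[((idx - 1L) %/% nrow(X)) + 1L]
  }
  wt <- ifelse(flip[use], -w$weight[use], w$weight[use])
  raw <- drop(X %*% wt)
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0)
    stop(errorCondition("polygenic score has zero variance; cannot standardize",
                        class = c("smokesub_zero_variance", "error")))
  structure(stats::setNames((raw - mean(raw)) / s, panel$sample_ids),
            raw = raw, n_snps_used = sum(use),
            source_trait = attr(w, "source_trait") %||% "trait",
            class = "pgs_vector")
}

#' @export
print.pgs_vector <- function(x, ...) {
  cat(sprintf("<pgs_vector> %d samples, %d SNPs, trait '%s' (standardized)\n",
              length(x), attr(x, "n_snps_used"), attr(x, "source_trait")))
  invisible(x)
}
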
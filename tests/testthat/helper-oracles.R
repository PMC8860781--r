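# Independent oracles used across tests; none of these call the package's
# own estimation paths.

# P(Z1 < a, Z2 < b) for standard bivariate normal with correlation rho,
# by 1-D quadrature: int_{-inf}^{a} phi(x) Phi((b - rho x)/sqrt(1-rho^2)) dx
bvn_lower_cdf <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a) * pnorm(b))
  stats::integrate(function(x) dnorm(x) * pnorm((b - rho * x) / sqrt(1 - rho^2)),
                   -Inf, a, rel.tol = 1e-10)$value
}

# correlation of two dosages built from thresholded latent gametes with
# latent correlation rho, by enumeration over the 9 dosage-pair cells
dosage_cor_oracle <- function(maf1, maf2, rho) {
  q1 <- qnorm(maf1); q2 <- qnorm(maf2)
  p11 <- bvn_lower_cdf(q1, q2, rho)
  gam <- matrix(c(1 - maf1 - maf2 + p11, maf2 - p11,
                  maf1 - p11, p11), 2, 2, byrow = TRUE)  # P(A=a, B=b)
  # dosage pmf: convolution of two independent gametes
  pmf <- matrix(0, 3, 3)
  for (a1 in 0:1) for (b1 in 0:1) for (a2 in 0:1) for (b2 in 0:1)
    pmf[a1 + a2 + 1, b1 + b2 + 1] <- pmf[a1 + a2 + 1, b1 + b2 + 1] +
      gam[a1 + 1, b1 + 1] * gam[a2 + 1, b2 + 1]
  d <- 0:2
  e1 <- sum(rowSums(pmf) * d); e2 <- sum(colSums(pmf) * d)
  e12 <- sum(outer(d, d) * pmf)
  v1 <- sum(rowSums(pmf) * d^2) - e1^2
  v2 <- sum(colSums(pmf) * d^2) - e2^2
  (e12 - e1 * e2) / sqrt(v1 * v2)
}

# greedy clumping enumerated directly from a p-vector, r2 matrix and
# positions (hand transcription of the procedure, no package code)
clump_oracle <- function(p, chrom, pos, r2, p_thresh, r2_thresh, dist_bp) {
  sig <- which(p <= p_thresh)
  sig <- sig[order(p[sig])]
  loci <- list()
  while (length(sig)) {
    lead <- sig[1]
    absorb <- sig[r2[lead, sig] >= r2_thresh |
                    (chrom[sig] == chrom[lead] & abs(pos[sig] - pos[lead]) <= dist_bp)]
    absorb <- union(lead, absorb)
    loci[[length(loci) + 1]] <- sort(absorb)
    sig <- setdiff(sig, absorb)
  }
  loci
}

# small cohort with merged true-effect PGS columns, for gxe/ladder tests
make_analysis_table <- function(n = 1200, m = 150, seed = 5, delta_gxe = 0,
                                gamma_rge = 0.14, b_med = -0.3, n_pcs = 5,
                                cluster_size = 1) {
  panel <- simulate_genotypes(n, m, block_size = 5, rho = 0.5, seed = seed,
                              cluster_size = cluster_size)
  eff <- make_true_effects(m, h2_ea = 0.3, h2_direct = 0.3, b_med = b_med,
                           gamma_rge = gamma_rge, delta_gxe = delta_gxe,
                           seed = seed + 1)
  tab <- simulate_phenotypes(panel, eff, n_pcs = n_pcs, seed = seed + 2,
                             exposure_missing_rate = 0)
  g <- attr(tab, "genetic_values")
  sdx <- apply(panel$dosages, 2, sd)
  wt <- function(beta) data.frame(id = panel$snp_meta$id, a1 = panel$snp_meta$a1,
                                  a2 = panel$snp_meta$a2,
                                  weight = ifelse(sdx > 0, beta / pmax(sdx, 1e-8), 0))
  tab <- as.data.frame(tab)
  tab$pgs_allsmok <- as.numeric(score_individuals(panel, wt(eff$beta_direct + eff$beta_ea)))
  tab$pgs_ea <- as.numeric(score_individuals(panel, wt(eff$beta_ea)))
  tab$pgs_smok_noea <- as.numeric(score_individuals(panel, wt(eff$beta_direct)))
  attr(tab, "panel") <- panel
  attr(tab, "effects") <- eff
  attr(tab, "genetic_values") <- g
  tab
}
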
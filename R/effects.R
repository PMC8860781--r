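#' Generative per-SNP effects and path coefficients
#'
#' Defines the causal structure used by \code{\link{simulate_phenotypes}}:
#' per-SNP effects on EA liability (\code{beta_ea}) and directly on smoking
#' liability (\code{beta_direct}, realizing the direct path c'), a genome-wide
#' EA-to-smoking mediation path \code{b_med}, a gene-environment correlation
#' path \code{gamma_rge} from the EA genetic value to the neighborhood
#' exposure, and an optional liability-scale interaction \code{delta_gxe}
#' between the standardized direct genetic value and the standardized
#' exposure. Effects are drawn i.i.d. normal over the designated causal SNPs.
#'
#' Defaults reflect the study system: EA SNP-heritability 14.2%, direct
#' smoking heritability 7.2%, a negative mediation path sized so total smoking
#' heritability is about 9.2%, an rGE path giving roughly 2% of exposure
#' variance, lifetime-smoking prevalence 43%, and no generative interaction.
#'
#' @param m number of SNPs.
#' @param h2_ea,h2_direct liability-scale variance of the EA and direct
#'   genetic values, each in \code{[0, 1]}.
#' @param b_med EA-to-smoking path coefficient (liability units).
#' @param gamma_rge slope of the exposure on the standardized EA genetic value.
#' @param delta_gxe coefficient of std(direct genetic value) x std(exposure).
#' @param prevalence lifetime-smoking prevalence in \code{(0, 1)}.
#' @param prop_causal_ea,prop_causal_direct fraction of SNPs carrying each
#'   effect (causal sets drawn independently, so the two architectures share
#'   no systematic overlap and EA-smoking genetic overlap is purely mediated).
#' @param seed integer seed.
#' @return an object of class \code{true_effects}.
#' @export
make_true_effects <- function(m, h2_ea = 0.142, h2_direct = 0.072,
                              b_med = -0.375, gamma_rge = 0.14,
                              delta_gxe = 0, prevalence = 0.43,
                              prop_causal_ea = 1, prop_causal_direct = 1,
                              seed = 1) {
  m <- check_count(m, "m")
  check_scalar(h2_ea, "h2_ea", 0, 1)
  check_scalar(h2_direct, "h2_direct", 0, 1)
  check_scalar(b_med, "b_med")
  check_scalar(gamma_rge, "gamma_rge")
  check_scalar(delta_gxe, "delta_gxe")
  check_scalar(prevalence, "prevalence", 1e-12, 1 - 1e-12)
  if (h2_direct + b_med^2 + delta_gxe^2 >= 1)
    stop_param("variance budget exceeded: h2_direct + b_med^2 + delta_gxe^2 must be < 1")
  set.seed(seed)
  draw <- function(prop) {
    beta <- numeric(m)
    k <- max(1L, round(prop * m))
    beta[sample.int(m, k)] <- stats::rnorm(k)
    beta
  }
  structure(list(beta_ea = if (h2_ea > 0) draw(prop_causal_ea) else numeric(m),
                 beta_direct = if (h2_direct > 0) draw(prop_causal_direct) else numeric(m),
                 b_med = b_med, gamma_rge = gamma_rge, delta_gxe = delta_gxe,
                 h2_ea = h2_ea, h2_direct = h2_direct, prevalence = prevalence),
            class = "true_effects")
}

#' @export
print.true_effects <- function(x, ...) {
  cat(sprintf(paste0("<true_effects> m = %d | h2_ea = %.3f, h2_direct = %.3f, ",
                     "b_med = %.3f, gamma_rge = %.3f, delta_gxe = %.3f, prev = %.2f\n"),
              length(x$beta_ea), x$h2_ea, x$h2_direct, x$b_med, x$gamma_rge,
              x$delta_gxe, x$prevalence))
  invisible(x)
}
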
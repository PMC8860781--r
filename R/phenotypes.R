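#' Simulate phenotypes on a genotype panel under the mediation model
#'
#' Generates, per sample: continuous EA (\code{ea_years}, unit variance, with
#' genetic value scaled to hit \code{h2_ea} exactly), a neighborhood exposure
#' with gene-environment correlation \code{gamma_rge} through the EA genetic
#' value, a smoking liability
#' \deqn{L = G_{direct} + b\,EA + \delta\,std(G_{direct})\,std(E) + e}
#' thresholded at the empirical \code{1 - prevalence} quantile to give the
#' binary \code{smoker}, plus age, sex (1 = male, 2 = female), principal
#' components, genotyping batch, an auxiliary wellbeing outcome loading on the
#' EA genetic value, and missing-at-random item missingness in the exposure
#' (missingness probability depends on age, count fixed to the configured
#' rate). The continuous liability is retained in \code{smoking_liability}
#' since path coefficients are defined on the liability scale.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param eff a \code{\link{make_true_effects}} object with matching SNP count.
#' @param exposure_noise_sd SD of the exposure's non-genetic part.
#' @param n_pcs number of simulated (genotype-independent) PCs.
#' @param seed integer seed.
#' @param exposure_missing_rate fraction of exposure values set missing
#'   (default 10.3%, the study's imputed share).
#' @param n_batches number of genotyping batches.
#' @return a data.frame of class \code{phenotype_table} with attribute
#'   \code{genetic_values} (list with \code{g_ea}, \code{g_direct}).
#' @export
simulate_phenotypes <- function(panel, eff, exposure_noise_sd = 1, n_pcs = 10,
                                seed = 1, exposure_missing_rate = 0.103,
                                n_batches = 3) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(eff, "true_effects"))
  n <- nrow(panel$dosages); m <- ncol(panel$dosages)
  if (length(eff$beta_ea) != m) stop_param("panel and effects disagree on SNP count")
  check_scalar(exposure_noise_sd, "exposure_noise_sd", 1e-12)
  n_pcs <- check_count(n_pcs, "n_pcs", min = 0L)
  check_scalar(exposure_missing_rate, "exposure_missing_rate", 0, 1)
  if (eff$h2_direct + eff$b_med^2 + eff$delta_gxe^2 >= 1)
    stop_param("variance budget exceeded on the smoking liability scale")
  set.seed(seed)

  X <- panel$dosages
  if (anyNA(X)) { # mean-impute for genetic-value construction
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X))
    X[idx] <- mu[((idx - 1L) %/% nrow(X)) + 1L]
  }
  Z <- scale(X)
  Z[, !is.finite(colSums(Z))] <- 0

  gvalue <- function(beta, h2) {
    if (h2 <= 0 || all(beta == 0)) return(rep(0, n))
    g <- drop(Z %*% beta)
    g * sqrt(h2) / stats::sd(g)
  }
  g_ea <- gvalue(eff$beta_ea, eff$h2_ea)
  g_direct <- gvalue(eff$beta_direct, eff$h2_direct)

  ea <- g_ea + stats::rnorm(n, 0, sqrt(1 - eff$h2_ea))
  exposure <- eff$gamma_rge * std(g_ea) + stats::rnorm(n, 0, exposure_noise_sd)
  e3_sd <- sqrt(1 - eff$h2_direct - eff$b_med^2 - eff$delta_gxe^2)
  liability <- g_direct + eff$b_med * ea +
    eff$delta_gxe * std(g_direct) * std(exposure) +
    stats::rnorm(n, 0, e3_sd)
  smoker <- as.integer(liability > stats::quantile(liability, 1 - eff$prevalence))

  age <- stats::rnorm(n, 43.3, 17.1)
  sex <- ifelse(stats::runif(n) < 0.631, 2L, 1L)
  pcs <- if (n_pcs > 0) matrix(stats::rnorm(n * n_pcs), n, n_pcs,
                               dimnames = list(NULL, paste0("pc", seq_len(n_pcs))))
         else NULL
  batch <- paste0("b", sample.int(n_batches, n, replace = TRUE))
  aux <- 0.1 * std(g_ea) + stats::rnorm(n, 0, sqrt(1 - 0.01))

  # MAR in the exposure: older samples more likely missing, exact count
  n_miss <- round(exposure_missing_rate * n)
  if (n_miss > 0) {
    w <- exp(0.03 * (age - mean(age)))
    exposure[sample.int(n, n_miss, prob = w)] <- NA_real_
  }

  tab <- data.frame(sample_id = panel$sample_ids, cluster_id = panel$family_ids,
                    ea_years = ea, smoker = smoker,
                    smoking_liability = liability, exposure = exposure,
                    age = age, sex = sex, batch = batch, aux_outcome = aux,
                    stringsAsFactors = FALSE)
  if (!is.null(pcs)) tab <- cbind(tab, as.data.frame(pcs))
  attr(tab, "genetic_values") <- list(g_ea = g_ea, g_direct = g_direct)
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Winsorize a numeric vector
#'
#' Clips values into \code{[lo, hi]}, leaving order and untouched elements
#' unchanged; used for bounding skewed exposures such as neighborhood income
#' (default bounds 500 and 10000 monthly household income).
#'
#' @param values numeric vector (NA preserved).
#' @param lo,hi lower/upper bound, \code{lo <= hi}.
#' @return the clipped vector.
#' @examples
#' winsorize(c(400, 2678.64, 12000), 500, 10000)
#' @export
winsorize <- function(values, lo = 500, hi = 10000) {
  if (!is.numeric(values)) stop_param("values must be numeric")
  if (length(lo) != 1L || length(hi) != 1L || is.na(lo) || is.na(hi) || lo > hi)
    stop_param("need lo <= hi")
  pmin(pmax(values, lo), hi)
}
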
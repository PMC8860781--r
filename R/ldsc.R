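#' LD scores from a genotype panel
#'
#' For SNP j, the LD score is the sum of squared correlations with reference
#' SNPs in its own LD block (and, optionally, \code{window_blocks} neighboring
#' blocks on each side), including the self term. The small-sample-unbiased
#' estimator \eqn{r^2_{adj} = r^2 - (1 - r^2)/(n - 2)} is used, so scores may
#' dip slightly below 1.
#'
#' @param panel a QC-passed \code{\link{genotype_panel}} with n > 3 samples.
#' @param window_blocks how many neighboring blocks to include per side
#'   (0 = own block only, matching the generator's independent-block LD).
#' @return object of class \code{ldscores}: data.frame (id, block_id, ell)
#'   with attributes \code{m_ref} and \code{window_blocks}.
#' @export
compute_ld_scores <- function(panel, window_blocks = 0) {
  stopifnot(inherits(panel, "genotype_panel"))
  window_blocks <- check_count(window_blocks, "window_blocks", min = 0L)
  X <- panel$dosages
  n <- nrow(X)
  if (n <= 3) stop_param("LD score estimation needs n > 3 samples")
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X))
    X[idx] <- mu[((idx - 1L) %/% nrow(X)) + 1L]
  }
  blocks <- panel$snp_meta$block_id
  ublocks <- sort(unique(blocks))
  ell <- numeric(ncol(X))
  for (b in ublocks) {
    own <- which(blocks == b)
    win <- which(blocks %in% (b - window_blocks):(b + window_blocks))
    r2 <- suppressWarnings(stats::cor(X[, own, drop = FALSE], X[, win, drop = FALSE]))^2
    r2[!is.finite(r2)] <- 0
    r2 <- r2 - (1 - r2) / (n - 2)
    ell[own] <- rowSums(r2)
  }
  structure(data.frame(id = panel$snp_meta$id, block_id = blocks, ell = ell,
                       stringsAsFactors = FALSE),
            m_ref = ncol(X), window_blocks = window_blocks, n_ref = n,
            class = c("ldscores", "data.frame"))
}

# weighted regression of y on (1, x) plus delete-one-block leave-one-out fits;
# blocks is a list of index vectors
.wls_loo <- function(x, y, w, blocks) {
  sums <- function(idx) c(sum(w[idx]), sum(w[idx] * x[idx]), sum(w[idx] * x[idx]^2),
                          sum(w[idx] * y[idx]), sum(w[idx] * x[idx] * y[idx]))
  tot <- sums(seq_along(x))
  slope_int <- function(s) {
    den <- s[1] * s[3] - s[2]^2
    slope <- (s[1] * s[5] - s[2] * s[4]) / den
    c(slope = slope, intercept = (s[4] - slope * s[2]) / s[1])
  }
  full <- slope_int(tot)
  loo <- vapply(blocks, function(idx) slope_int(tot - sums(idx)), numeric(2))
  list(slope = unname(full[1]), intercept = unname(full[2]),
       slope_loo = unname(loo[1, ]), intercept_loo = unname(loo[2, ]))
}

.align_ld <- function(ss, ld) {
  j <- match(ss$id, ld$id)
  if (anyNA(j)) stop_param("sumstats and LD scores share no alignment for some SNPs")
  ld$ell[j]
}

#' SNP-heritability by LD score regression
#'
#' Regresses per-SNP chi-square statistics on LD scores; the slope times
#' \code{m / N} (N = median per-SNP sample size) estimates the SNP
#' heritability, with a free intercept absorbing confounding inflation.
#' Heteroskedasticity weights \eqn{1/(\ell_j (1 + N h^2 \ell_j / m)^2)} are
#' updated once after an initial \eqn{1/\ell_j}-weighted pass. Standard errors
#' come from a delete-one block jackknife over contiguous SNP blocks.
#'
#' @param ss a \code{\link{new_sumstats}} object.
#' @param ld matching \code{\link{compute_ld_scores}} output.
#' @param m number of reference SNPs (defaults to the LD panel's).
#' @param n_blocks jackknife blocks (default 20).
#' @return object of class \code{h2_estimate}: h2, se, intercept,
#'   intercept_se, n_blocks, plus leave-one-out vectors for downstream paired
#'   jackknifes.
#' @export
estimate_h2 <- function(ss, ld, m = NULL, n_blocks = 20) {
  stopifnot(inherits(ss, "sumstats"), inherits(ld, "ldscores"))
  m <- m %||% attr(ld, "m_ref")
  n_blocks <- check_count(n_blocks, "n_blocks", min = 2L)
  ell <- .align_ld(ss, ld)
  chi2 <- ss$z^2
  N <- stats::median(ss$n_eff)
  blocks <- contiguous_blocks(length(ell), n_blocks)
  ell_f <- pmax(ell, 1)

  f0 <- .wls_loo(ell, chi2, 1 / ell_f, blocks)
  h2_0 <- min(max(f0$slope * m / N, 0), 1)
  w <- 1 / (ell_f * (1 + N * h2_0 * ell / m)^2)
  f <- .wls_loo(ell, chi2, w, blocks)

  h2 <- f$slope * m / N
  h2_loo <- f$slope_loo * m / N
  structure(list(h2 = h2, se = jackknife_se(h2_loo),
                 intercept = f$intercept,
                 intercept_se = jackknife_se(f$intercept_loo),
                 n_blocks = n_blocks, m = m, N = N,
                 h2_loo = h2_loo, intercept_loo = f$intercept_loo,
                 trait_label = trait_label(ss)),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("<h2_estimate> %s: h2 = %.4f (SE %.4f), intercept = %.3f (SE %.3f)\n",
              x$trait_label, x$h2, x$se, x$intercept, x$intercept_se))
  invisible(x)
}

#' Cross-trait LD score regression
#'
#' Regresses the per-SNP z-score product on LD scores; the slope times
#' \code{m / sqrt(N1 N2)} estimates the genetic covariance, and the free
#' cross-trait intercept absorbs phenotypic correlation from overlapping
#' samples. The genetic correlation is the covariance scaled by the two
#' traits' LDSC heritabilities, clamped into \code{[-1, 1]} with the raw value
#' retained. Jackknife deletions are paired across the numerator and the two
#' heritability fits.
#'
#' @param ss1,ss2 sumstats aligned on SNP id (intersection used).
#' @param ld LD scores covering both traits' SNPs.
#' @param m reference SNP count; \code{n_blocks} jackknife blocks.
#' @inheritParams estimate_h2
#' @return object of class \code{rg_estimate}: rg (clamped), rg_raw, gcov,
#'   cross_intercept, se_rg, se_gcov, the two h2 fits, and leave-one-out
#'   vectors.
#' @export
estimate_rg <- function(ss1, ss2, ld, m = NULL, n_blocks = 20) {
  stopifnot(inherits(ss1, "sumstats"), inherits(ss2, "sumstats"))
  m <- m %||% attr(ld, "m_ref")
  ids <- intersect(ss1$id, ss2$id)
  if (!length(ids)) stop_param("sumstats share no SNPs")
  s1 <- ss1[match(ids, ss1$id), ]
  s2 <- ss2[match(ids, ss2$id), ]
  flip <- s1$a1 == s2$a2 & s1$a2 == s2$a1
  same <- s1$a1 == s2$a1 & s1$a2 == s2$a2
  usable <- same | flip
  s1 <- s1[usable, ]; s2 <- s2[usable, ]
  z2 <- ifelse(flip[usable], -s2$z, s2$z)

  ldi <- ld[match(s1$id, ld$id), ]
  attr(ldi, "m_ref") <- m
  class(ldi) <- class(ld)
  h1 <- estimate_h2(new_sumstats(s1, trait_label(ss1)), ldi, m, n_blocks)
  h2f <- estimate_h2(new_sumstats(s2, trait_label(ss2)), ldi, m, n_blocks)

  ell <- ldi$ell
  ell_f <- pmax(ell, 1)
  N1 <- stats::median(s1$n_eff); N2 <- stats::median(s2$n_eff)
  zz <- s1$z * z2
  blocks <- contiguous_blocks(length(ell), n_blocks)
  a1 <- 1 + N1 * max(h1$h2, 0) * ell / m
  a2 <- 1 + N2 * max(h2f$h2, 0) * ell / m
  f <- .wls_loo(ell, zz, 1 / (ell_f * a1 * a2), blocks)

  scale <- m / sqrt(N1 * N2)
  gcov <- f$slope * scale
  gcov_loo <- f$slope_loo * scale
  if (h1$h2 <= 0 || h2f$h2 <= 0) {
    cond <- errorCondition("undefined rg: non-positive estimated h2",
                           class = c("smokesub_undefined_rg", "error"))
    # carry the well-defined parts so callers can keep the genetic covariance
    cond$gcov <- gcov
    cond$gcov_loo <- gcov_loo
    cond$cross_intercept <- f$intercept
    cond$se_gcov <- jackknife_se(gcov_loo)
    cond$n_blocks <- n_blocks
    cond$h2_1 <- h1
    cond$h2_2 <- h2f
    stop(cond)
  }
  rg_raw <- gcov / sqrt(h1$h2 * h2f$h2)
  rg_loo <- gcov_loo / sqrt(pmax(h1$h2_loo, 1e-8) * pmax(h2f$h2_loo, 1e-8))
  structure(list(rg = min(max(rg_raw, -1), 1), rg_raw = rg_raw,
                 gcov = gcov, cross_intercept = f$intercept,
                 se_rg = jackknife_se(rg_loo), se_gcov = jackknife_se(gcov_loo),
                 h2_1 = h1, h2_2 = h2f, n_blocks = n_blocks, m = m,
                 gcov_loo = gcov_loo, rg_loo = rg_loo,
                 n_snps = length(ell),
                 traits = c(trait_label(ss1), trait_label(ss2))),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("<rg_estimate> %s ~ %s: rg = %.3f (SE %.3f), gcov = %.4f, cross-intercept = %.3f\n",
              x$traits[1], x$traits[2], x$rg, x$se_rg, x$gcov, x$cross_intercept))
  invisible(x)
}
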
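#' Genome-wide EA-to-smoking mediation path
#'
#' The genetic regression of smoking on EA is the ratio of the cross-trait
#' genetic covariance to the EA SNP-heritability,
#' \eqn{b = gcov(EA, smok) / h^2_{EA}}. Its standard error propagates the
#' jackknife uncertainty of numerator and denominator through paired
#' delete-one-block pseudovalues, so both estimates must come from the same
#' LD scores and block partition.
#'
#' @param rg_ea_smok \code{\link{estimate_rg}} fit with EA as the first trait.
#' @param h2_ea \code{\link{estimate_h2}} fit for EA.
#' @return object of class \code{mediation_path}: \code{b_med_hat}, \code{se},
#'   leave-one-out ratios, and the overlap (cross-trait intercept) term.
#' @export
estimate_mediation_path <- function(rg_ea_smok, h2_ea) {
  stopifnot(inherits(rg_ea_smok, "rg_estimate"), inherits(h2_ea, "h2_estimate"))
  if (h2_ea$h2 <= 0)
    stop(errorCondition("undefined mediation path: h2_EA <= 0",
                        class = c("smokesub_undefined_path", "error")))
  if (rg_ea_smok$n_blocks != h2_ea$n_blocks)
    stop_param("rg and h2 fits use different jackknife partitions")
  b <- rg_ea_smok$gcov / h2_ea$h2
  b_loo <- rg_ea_smok$gcov_loo / pmax(h2_ea$h2_loo, 1e-8)
  structure(list(b_med_hat = b, se = jackknife_se(b_loo), b_loo = b_loo,
                 overlap_term = rg_ea_smok$cross_intercept,
                 n_blocks = h2_ea$n_blocks),
            class = "mediation_path")
}

#' @export
print.mediation_path <- function(x, ...) {
  cat(sprintf("<mediation_path> b = %.4f (SE %.4f), overlap intercept = %.3f\n",
              x$b_med_hat, x$se, x$overlap_term))
  invisible(x)
}

# harmonize ss_other onto ss_ref by SNP id and allele orientation.
# Returns index into ss_other, sign flips, and drop log.
.harmonize <- function(ss_ref, ss_other, drop_ambiguous = TRUE) {
  j <- match(ss_ref$id, ss_other$id)
  found <- !is.na(j)
  a1o <- ss_other$a1[j]; a2o <- ss_other$a2[j]
  same <- found & ss_ref$a1 == a1o & ss_ref$a2 == a2o
  flip <- found & ss_ref$a1 == a2o & ss_ref$a2 == a1o
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- ss_ref$a1 == comp[ss_ref$a2]
  keep <- (same | flip) & (!drop_ambiguous | !ambiguous)
  reason <- rep(NA_character_, nrow(ss_ref))
  reason[!found] <- "absent"
  reason[found & !(same | flip)] <- "allele_mismatch"
  reason[(same | flip) & drop_ambiguous & ambiguous] <- "strand_ambiguous"
  if (!any(keep))
    stop(errorCondition("no alignable SNPs between sumstats",
                        class = c("smokesub_alignment_error", "error")))
  list(keep = keep, idx = j, sign = ifelse(flip, -1, 1),
       dropped = data.frame(id = ss_ref$id[!keep], reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Subtract EA effects from smoking summary statistics
#'
#' Produces per-SNP direct-path estimates
#' \eqn{c'_j = \beta_{smok,j} - b\,\beta_{EA,j}} with delta-method variance
#' \deqn{se^2 = se_s^2 + b^2 se_e^2 + \beta_{EA}^2 se_b^2 - 2 b\,cov_j,}
#' where \eqn{cov_j = intercept \cdot se_s se_e} is the sample-overlap
#' covariance carried by the cross-trait LDSC intercept. Alleles are
#' harmonized by id (effect sign flipped when a1/a2 are swapped) and
#' strand-ambiguous A/T, C/G SNPs are dropped; drops are logged in the
#' \code{dropped} attribute.
#'
#' @param ss_smok,ss_ea smoking and EA sumstats.
#' @param fit a \code{\link{estimate_mediation_path}} object, or a list with
#'   \code{b_med_hat} and \code{se} (set \code{se = 0} to treat b as fixed).
#' @param cross_intercept sample-overlap term (default the fit's own).
#' @return sumstats labelled \code{"smoking_without_EA"} with extra columns
#'   \code{a_ea} (the EA path per SNP) and attributes \code{b_med}, \code{se_b},
#'   \code{dropped}.
#' @export
subtract_ea <- function(ss_smok, ss_ea, fit, cross_intercept = NULL) {
  stopifnot(inherits(ss_smok, "sumstats"), inherits(ss_ea, "sumstats"))
  b <- fit$b_med_hat; se_b <- fit$se %||% 0
  cross_intercept <- cross_intercept %||% fit$overlap_term %||% 0
  h <- .harmonize(ss_smok, ss_ea)
  k <- which(h$keep)
  s <- ss_smok[k, , drop = FALSE]
  beta_ea <- h$sign[k] * ss_ea$beta[h$idx[k]]
  se_ea <- ss_ea$se[h$idx[k]]

  cprime <- s$beta - b * beta_ea
  # the overlap term acts as a correlation between the two sampling errors;
  # clamping keeps the delta-method variance positive-definite
  r_ov <- min(max(cross_intercept, -0.99), 0.99)
  cov_j <- r_ov * s$se * se_ea
  var_c <- s$se^2 + b^2 * se_ea^2 + beta_ea^2 * se_b^2 - 2 * b * cov_j
  se_c <- sqrt(pmax(var_c, 1e-24))

  out <- s
  out$beta <- cprime
  out$se <- se_c
  out$z <- NULL; out$p <- NULL
  out$a_ea <- beta_ea
  out <- new_sumstats(out, trait_label = "smoking_without_EA")
  attr(out, "b_med") <- b
  attr(out, "se_b") <- se_b
  attr(out, "cross_intercept") <- cross_intercept
  attr(out, "dropped") <- h$dropped
  out
}
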
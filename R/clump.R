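#' Greedy clumping of significant loci
#'
#' Significant SNPs (p at or below \code{p_thresh}) are sorted by ascending
#' p-value; the best remaining SNP becomes a locus lead and absorbs every
#' remaining significant SNP that is either in LD with it (dosage \eqn{r^2 \ge}
#' \code{r2_thresh}) or within \code{dist_bp} of it on the same chromosome.
#' The procedure repeats until no significant SNP remains. Defaults follow
#' standard genome-wide practice: p = 5e-8, r^2 = 0.1, 250 kb.
#'
#' @param ss sumstats with chrom/pos columns.
#' @param panel genotype panel providing pairwise dosage LD for the candidates.
#' @param p_thresh,r2_thresh,dist_bp clumping thresholds.
#' @return list of loci (class \code{locus_set}), each with \code{lead_snp},
#'   \code{lead_p}, \code{chrom}, \code{pos_bp}, \code{member_snps}; empty
#'   list when nothing is significant.
#' @export
clump_loci <- function(ss, panel, p_thresh = 5e-8, r2_thresh = 0.1,
                       dist_bp = 250000) {
  stopifnot(inherits(ss, "sumstats"), inherits(panel, "genotype_panel"))
  if (is.null(ss$chrom) || is.null(ss$pos_bp))
    stop_param("sumstats need chrom and pos_bp columns for clumping")
  cand <- ss[ss$p <= p_thresh, , drop = FALSE]
  cand <- cand[order(cand$p, cand$id), , drop = FALSE]
  if (!nrow(cand)) return(structure(list(), class = "locus_set"))
  gi <- match(cand$id, panel$snp_meta$id)
  if (anyNA(gi)) stop_param("significant SNP(s) missing from the LD panel")
  G <- panel$dosages[, gi, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G))
    G[idx] <- mu[((idx - 1L) %/% nrow(G)) + 1L]
  }
  loci <- list()
  remaining <- seq_len(nrow(cand))
  while (length(remaining)) {
    lead <- remaining[1]
    r2 <- suppressWarnings(drop(stats::cor(G[, lead], G[, remaining, drop = FALSE]))^2)
    r2[!is.finite(r2)] <- 0
    near <- cand$chrom[remaining] == cand$chrom[lead] &
      abs(cand$pos_bp[remaining] - cand$pos_bp[lead]) <= dist_bp
    absorb <- remaining[r2 >= r2_thresh | near]
    absorb <- union(lead, absorb)
    loci[[length(loci) + 1L]] <- list(lead_snp = cand$id[lead],
                                      lead_p = cand$p[lead],
                                      chrom = cand$chrom[lead],
                                      pos_bp = cand$pos_bp[lead],
                                      member_snps = sort(cand$id[absorb]))
    remaining <- setdiff(remaining, absorb)
  }
  structure(loci, class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set> %d independent loci\n", length(x)))
  for (l in x)
    cat(sprintf("  %s (chr%s:%d, p = %.3g, %d member SNPs)\n",
                l$lead_snp, l$chrom, l$pos_bp, l$lead_p, length(l$member_snps)))
  invisible(x)
}
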
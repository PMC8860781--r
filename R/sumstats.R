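#' Summary-statistics container
#'
#' A data.frame with one row per SNP and columns \code{id}, \code{a1},
#' \code{a2}, \code{freq_a1}, \code{beta}, \code{se}, \code{z}, \code{p},
#' \code{n_eff} (plus optional \code{chrom}, \code{pos_bp}); \code{z} and
#' \code{p} are recomputed from \code{beta/se} when absent and validated for
#' consistency otherwise.
#'
#' @param df data.frame holding at least id, a1, a2, beta, se, n_eff.
#' @param trait_label name of the measured trait.
#' @return object of class \code{sumstats}.
#' @export
new_sumstats <- function(df, trait_label = "trait") {
  need <- c("id", "a1", "a2", "beta", "se", "n_eff")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_param("sumstats missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$se <= 0, na.rm = TRUE)) stop_param("se must be positive")
  z <- df$beta / df$se
  if (!is.null(df[["z"]]) && any(abs(df[["z"]] - z) > 1e-10, na.rm = TRUE))
    stop_param("z inconsistent with beta/se")
  df$z <- z
  p <- two_sided_p(z)
  if (!is.null(df[["p"]]) && any(abs(df[["p"]] - p) > 1e-10 & df[["p"]] > 1e-300, na.rm = TRUE))
    stop_param("p inconsistent with z")
  df$p <- p
  if (is.null(df[["freq_a1"]])) df$freq_a1 <- NA_real_
  bad <- !is.na(df$freq_a1) & (df$freq_a1 <= 0 | df$freq_a1 >= 1)
  if (any(bad)) stop_param("freq_a1 must lie in (0, 1)")
  if (anyDuplicated(df$id)) stop_param("duplicate SNP ids in sumstats")
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            trait_label = trait_label,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s': %d SNPs, median N = %s\n",
              attr(x, "trait_label"), nrow(x),
              format(stats::median(x$n_eff))))
  NextMethod()
}

trait_label <- function(ss) attr(ss, "trait_label") %||% "trait"
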
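# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("smokesub_parameter_error", "error")))
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_param(name, " must be a finite numeric scalar")
  if (x < lo || x > hi)
    stop_param(name, " must lie in [", lo, ", ", hi, "]")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != floor(x) || x < min)
    stop_param(name, " must be an integer >= ", min)
  as.integer(x)
}

# standardize to mean 0, sd 1; constant vectors stay 0
std <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# delete-one-block jackknife SE from leave-one-out estimates
jackknife_se <- function(loo) {
  B <- length(loo)
  if (B < 2L) stop_param("jackknife needs at least 2 blocks")
  sqrt((B - 1) / B * sum((loo - mean(loo))^2))
}

# contiguous index blocks for jackknifing m items into n_blocks groups
contiguous_blocks <- function(m, n_blocks) {
  if (m < n_blocks) stop_param("fewer items (", m, ") than jackknife blocks (", n_blocks, ")")
  split(seq_len(m), cut(seq_len(m), n_blocks, labels = FALSE))
}

two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}
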
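# TSV formats with '#'-prefixed metadata header lines (version, seed, config
# hash); every writer's output is re-readable by its own reader.

.meta_lines <- function(extra = character()) {
  c(paste0("# smokesub_version: ",
           as.character(utils::packageVersion("smokesub"))), extra)
}

.read_table <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop_param("empty table file: ", path)
  utils::read.delim(text = body, stringsAsFactors = FALSE, check.names = FALSE)
}

.write_table <- function(df, path, extra_meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_lines(extra_meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read GWAS summary statistics
#'
#' TSV with columns SNP, CHR, BP, A1, A2, FREQ, BETA, SE, Z, P, N and
#' '#'-metadata lines. Reading requires SNP, A1, A2, BETA, SE, N (a missing
#' required column raises a format error naming it); FREQ, Z and P are
#' recomputed when absent, and malformed (non-numeric) rows are rejected with
#' their line numbers.
#'
#' @param ss a sumstats object; \code{path} a file path.
#' @return \code{read_sumstats} returns a \code{\link{new_sumstats}} object.
#' @export
write_sumstats <- function(ss, path) {
  stopifnot(inherits(ss, "sumstats"))
  df <- data.frame(SNP = ss$id,
                   CHR = ss$chrom %||% NA_integer_,
                   BP = ss$pos_bp %||% NA_integer_,
                   A1 = ss$a1, A2 = ss$a2, FREQ = ss$freq_a1,
                   BETA = sprintf("%.*g", 17, ss$beta),
                   SE = sprintf("%.*g", 17, ss$se),
                   Z = sprintf("%.*g", 17, ss$z),
                   P = sprintf("%.*g", 17, ss$p),
                   N = ss$n_eff, stringsAsFactors = FALSE)
  .write_table(df, path, paste0("# trait: ", trait_label(ss)))
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  df <- .read_table(path)
  need <- c("SNP", "A1", "A2", "BETA", "SE", "N")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(errorCondition(paste0("missing required column: ", paste(miss, collapse = ", ")),
                        class = c("smokesub_format_error", "error")))
  num_cols <- intersect(c("BETA", "SE", "N", "FREQ", "Z", "P"), names(df))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "NA")
    if (length(bad)) {
      offset <- length(meta) + 1L  # metadata plus header line
      stop(errorCondition(
        paste0("malformed ", cc, " value(s) at line(s) ",
               paste(bad + offset, collapse = ", "), " of ", path),
        class = c("smokesub_format_error", "error")))
    }
    df[[cc]] <- v
  }
  trait <- sub("^# trait: ", "", grep("^# trait: ", meta, value = TRUE)[1])
  if (is.na(trait)) trait <- "trait"
  out <- data.frame(id = df$SNP, a1 = df$A1, a2 = df$A2,
                    freq_a1 = if ("FREQ" %in% names(df)) df$FREQ else NA_real_,
                    beta = df$BETA, se = df$SE, n_eff = df$N,
                    stringsAsFactors = FALSE)
  if ("CHR" %in% names(df)) out$chrom <- df$CHR
  if ("BP" %in% names(df)) out$pos_bp <- df$BP
  if ("Z" %in% names(df)) out$z <- df$Z
  if ("P" %in% names(df)) out$p <- df$P
  new_sumstats(out, trait_label = trait)
}

#' Write / read a genotype panel
#'
#' The dosage matrix goes to \code{<prefix>.raw} in PLINK raw style (header
#' FID IID PAT MAT SEX PHENOTYPE then one \code{<snp>_<a1>} column per SNP,
#' whitespace-separated, NA for missing calls) and the variant table to
#' \code{<prefix>.var.tsv}.
#'
#' @param panel a \code{\link{genotype_panel}}; \code{prefix} a path prefix.
#' @return \code{read_panel} returns a \code{\link{genotype_panel}}.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  meta <- panel$snp_meta
  hdr <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
           paste0(meta$id, "_", meta$a1))
  df <- data.frame(FID = panel$family_ids, IID = panel$sample_ids,
                   PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(panel$dosages))
  names(df) <- hdr
  utils::write.table(df, paste0(prefix, ".raw"), sep = " ", quote = FALSE,
                     row.names = FALSE)
  .write_table(meta, paste0(prefix, ".var.tsv"))
  invisible(prefix)
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix) {
  raw <- utils::read.table(paste0(prefix, ".raw"), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  meta <- .read_table(paste0(prefix, ".var.tsv"))
  dos <- as.matrix(raw[, -(1:6), drop = FALSE])
  colnames(dos) <- sub("_[ACGT]$", "", colnames(dos))
  if (!identical(colnames(dos), meta$id))
    stop(errorCondition("raw/variant files disagree on SNP ids",
                        class = c("smokesub_format_error", "error")))
  genotype_panel(dos, meta, sample_ids = raw$IID, family_ids = raw$FID)
}

#' Write / read a phenotype table
#'
#' One-line-header TSV with '#' metadata lines; missing values as NA.
#'
#' @param table a data.frame; \code{path} a file path.
#' @return \code{read_phenotypes} returns the data.frame.
#' @export
write_phenotypes <- function(table, path) .write_table(as.data.frame(table), path)

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) .read_table(path)

#' Default run configuration
#'
#' Stage parameters with the pipeline's standard thresholds: QC at MAF 0.01,
#' HWE 1e-10, call rate 0.95; clumping at p 5e-8, r2 0.1, 250 kb; multiple
#' testing at alpha 0.05 over 8 tests; 25 imputations; plus synthetic-cohort
#' defaults.
#'
#' @param ... overrides as name = value pairs.
#' @return named list of class \code{run_config}.
#' @export
default_config <- function(...) {
  cfg <- list(seed = 1, n = 2000, m = 500, block_size = 10, rho = 0.8,
              maf_lo = 0.05, maf_hi = 0.5,
              qc_maf_min = 0.01, qc_hwe_p_min = 1e-10, qc_callrate_min = 0.95,
              clump_p = 5e-8, clump_r2 = 0.1, clump_dist_bp = 250000,
              alpha = 0.05, n_tests = 8, m_imputations = 25,
              exposure_missing_rate = 0.103, n_pcs = 10)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop_param("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write flat key:value configuration files
#'
#' One \code{key: value} pair per line; '#' lines are comments. Unknown keys
#' raise a parameter error, so configs stay in step with
#' \code{\link{default_config}}.
#'
#' @param path file path; \code{cfg} a \code{run_config}.
#' @return \code{read_config} returns a \code{run_config}.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")), character(1))
  do.call(default_config, stats::setNames(as.list(as.numeric(vals)), keys))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  writeLines(c("# smokesub run configuration",
               sprintf("%s: %s", names(cfg),
                       vapply(cfg, function(v) format(v, scientific = TRUE), character(1)))),
             path)
  invisible(path)
}
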
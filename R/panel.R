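#' Genotype panel constructor
#'
#' Bundles an additive dosage matrix (values in \code{[0, 2]}, \code{NA} for
#' missing calls) with per-SNP metadata, sample identifiers and family
#' (cluster) identifiers. Dosages count copies of allele \code{a1}.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns.
#' @param snp_meta data.frame with columns \code{id}, \code{chrom},
#'   \code{pos_bp}, \code{a1}, \code{a2}, \code{block_id}; one row per SNP,
#'   \code{pos_bp} strictly increasing within chromosome.
#' @param sample_ids character vector of sample identifiers.
#' @param family_ids character vector; samples sharing an id form one cluster.
#' @return an object of class \code{genotype_panel}.
#' @export
genotype_panel <- function(dosages, snp_meta, sample_ids = NULL, family_ids = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); m <- ncol(dosages)
  if (n < 1L || m < 1L) stop_param("panel needs n_samples >= 1 and m_snps >= 1")
  if (nrow(snp_meta) != m) stop_param("snp_meta rows must match ncol(dosages)")
  need <- c("id", "chrom", "pos_bp", "a1", "a2", "block_id")
  miss <- setdiff(need, names(snp_meta))
  if (length(miss)) stop_param("snp_meta missing column(s): ", paste(miss, collapse = ", "))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop_param("dosages must lie in [0, 2] or be NA")
  for (ch in unique(snp_meta$chrom)) {
    pos <- snp_meta$pos_bp[snp_meta$chrom == ch]
    if (any(diff(pos) <= 0)) stop_param("pos_bp must be strictly increasing within chromosome ", ch)
  }
  sample_ids <- sample_ids %||% sprintf("S%05d", seq_len(n))
  family_ids <- family_ids %||% sample_ids
  if (length(sample_ids) != n || length(family_ids) != n)
    stop_param("sample_ids/family_ids must have one entry per sample")
  colnames(dosages) <- snp_meta$id
  rownames(dosages) <- sample_ids
  structure(list(dosages = dosages,
                 snp_meta = as.data.frame(snp_meta, stringsAsFactors = FALSE),
                 sample_ids = as.character(sample_ids),
                 family_ids = as.character(family_ids)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d SNPs, %d LD blocks, %d clusters\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$snp_meta$block_id)),
              length(unique(x$family_ids))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

# non-strand-ambiguous allele pairs (excludes A/T and C/G)
.allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate a genotype panel with blockwise AR(1) linkage disequilibrium
#'
#' Each SNP's per-gamete allele indicator is obtained by thresholding a latent
#' standard-normal variable at \code{qnorm(maf)}; within an LD block the latent
#' variables of adjacent SNPs follow an AR(1) process with correlation
#' \code{rho}, and blocks are mutually independent. A dosage is the sum of two
#' independent gametes, so LD between dosages is the tetrachoric-induced
#' correlation of the thresholded process. Blocks are laid out contiguously
#' over up to 22 chromosomes with 100 kb between adjacent SNPs.
#'
#' @param n,m number of samples and SNPs.
#' @param block_size SNPs per LD block (the last block may be shorter).
#' @param rho AR(1) latent correlation in \code{[0, 1)}.
#' @param maf_range interval within \code{(0, 0.5]} from which per-SNP minor
#'   allele frequencies are drawn uniformly.
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @param cluster_size samples per family cluster (consecutive samples share a
#'   family id); family granularity is a free parameter of the design.
#' @param missing_rate per-call probability of a missing dosage (default 0).
#' @return a \code{\link{genotype_panel}}.
#' @examples
#' p <- simulate_genotypes(100, 20, block_size = 5, rho = 0.8, seed = 1)
#' dim(p)
#' @export
simulate_genotypes <- function(n, m, block_size = 10, rho = 0.8,
                               maf_range = c(0.05, 0.5), seed = 1,
                               cluster_size = 1, missing_rate = 0) {
  n <- check_count(n, "n"); m <- check_count(m, "m")
  block_size <- check_count(block_size, "block_size")
  check_scalar(rho, "rho", 0, 1 - 1e-12)
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_param("maf_range must be an ordered interval within (0, 0.5]")
  check_scalar(missing_rate, "missing_rate", 0, 1)
  cluster_size <- check_count(cluster_size, "cluster_size")
  set.seed(seed)

  maf <- stats::runif(m, maf_range[1], maf_range[2])
  thr <- stats::qnorm(maf)
  block_id <- rep(seq_len(ceiling(m / block_size)), each = block_size)[seq_len(m)]
  new_block <- c(TRUE, diff(block_id) != 0)

  latent <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    sc <- sqrt(1 - rho^2)
    for (j in seq_len(m)[-1]) {
      if (!new_block[j]) z[, j] <- rho * z[, j - 1] + sc * z[, j]
    }
    z
  }
  g1 <- sweep(latent(), 2, thr, "<")
  g2 <- sweep(latent(), 2, thr, "<")
  dos <- g1 + g2
  storage.mode(dos) <- "double"
  if (missing_rate > 0) dos[stats::runif(n * m) < missing_rate] <- NA_real_

  alleles <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), , drop = FALSE]
  n_blocks <- max(block_id)
  n_chrom <- min(22L, n_blocks)
  chrom_of_block <- ((seq_len(n_blocks) - 1L) * n_chrom) %/% n_blocks + 1L
  chrom <- chrom_of_block[block_id]
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- 100000L * seq_along(idx)
  }
  meta <- data.frame(id = sprintf("rs%06d", seq_len(m)), chrom = chrom,
                     pos_bp = pos, a1 = alleles[, 1], a2 = alleles[, 2],
                     block_id = block_id, maf = maf,
                     stringsAsFactors = FALSE)
  fam <- sprintf("F%05d", rep(seq_len(ceiling(n / cluster_size)),
                              each = cluster_size)[seq_len(n)])
  genotype_panel(dos, meta, family_ids = fam)
}
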
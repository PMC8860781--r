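fake_rg <- function(gcov, gcov_loo, intercept = 0, n_blocks = 20) {
  structure(list(gcov = gcov, gcov_loo = gcov_loo, cross_intercept = intercept,
                 n_blocks = n_blocks), class = "rg_estimate")
}
fake_h2 <- function(h2, h2_loo, n_blocks = 20) {
  structure(list(h2 = h2, h2_loo = h2_loo, n_blocks = n_blocks),
            class = "h2_estimate")
}
toy_ss <- function(beta, se, a1 = "A", a2 = "G", label = "t") {
  k <- length(beta)
  new_sumstats(data.frame(id = paste0("rs", seq_len(k)), chrom = 1L,
                          pos_bp = seq_len(k) * 1e5,
                          a1 = rep_len(a1, k), a2 = rep_len(a2, k),
                          freq_a1 = 0.3, beta = beta, se = se, n_eff = 1000L),
               label)
}

test_that("mediation path ratio identities hold", {
  loo <- rep(0, 20)
  expect_equal(estimate_mediation_path(fake_rg(0, loo), fake_h2(0.2, rep(0.2, 20)))$b_med_hat, 0)
  expect_equal(estimate_mediation_path(fake_rg(0.2, rep(0.2, 20)),
                                       fake_h2(0.2, rep(0.2, 20)))$b_med_hat, 1)
  expect_error(estimate_mediation_path(fake_rg(0.1, loo), fake_h2(0, rep(0, 20))),
               class = "smokesub_undefined_path")
  expect_error(estimate_mediation_path(fake_rg(0.1, loo, n_blocks = 10),
                                       fake_h2(0.2, rep(0.2, 20))),
               class = "smokesub_parameter_error")
})

test_that("per-SNP subtraction follows c' = beta_smok - b * beta_ea exactly", {
  ss_smok <- toy_ss(c(0.10, -0.05), c(0.02, 0.02), label = "smoking")
  ss_ea <- toy_ss(c(0.05, 0.01), c(0.01, 0.01), label = "EA")
  out <- subtract_ea(ss_smok, ss_ea, list(b_med_hat = 0.4, se = 0, overlap_term = 0))
  expect_equal(out$beta, c(0.10 - 0.4 * 0.05, -0.05 - 0.4 * 0.01))
  expect_equal(out$beta[1], 0.08)
  expect_equal(attr(out, "trait_label"), "smoking_without_EA")
  # delta-method SE without overlap or b uncertainty
  expect_equal(out$se, sqrt(c(0.02^2 + 0.16 * 0.01^2, 0.02^2 + 0.16 * 0.01^2)))
})

test_that("b = 0 subtraction is the identity on the smoking sumstats", {
  ss_smok <- toy_ss(rnorm(10, 0, 0.05), runif(10, 0.01, 0.03), label = "smoking")
  ss_ea <- toy_ss(rnorm(10, 0, 0.05), runif(10, 0.01, 0.03), label = "EA")
  out <- subtract_ea(ss_smok, ss_ea, list(b_med_hat = 0, se = 0, overlap_term = 0))
  expect_equal(out$beta, ss_smok$beta)
  expect_equal(out$se, ss_smok$se)
  expect_equal(out$z, ss_smok$z)
})

test_that("the exact subtraction identity holds on every SNP of a pipeline run", {
  p <- simulate_genotypes(1000, 200, block_size = 10, rho = 0.8, seed = 3)
  eff <- make_true_effects(200, seed = 4)
  ph <- simulate_phenotypes(p, eff, seed = 5)
  ss_ea <- run_gwas(p, ph$ea_years, trait_label = "EA")
  ss_smok <- run_gwas(p, ph$smoking_liability, trait_label = "smoking")
  fit <- list(b_med_hat = 0.37, se = 0.05, overlap_term = 0.2)
  out <- subtract_ea(ss_smok, ss_ea, fit)
  j <- match(out$id, ss_smok$id)
  expect_equal(out$beta + 0.37 * out$a_ea - ss_smok$beta[j],
               rep(0, nrow(out)), tolerance = 1e-12)
  # delta-method variance never undershoots the no-overlap lower bound
  expect_true(all(out$se >= abs(ss_smok$se[j] - abs(0.37) * ss_ea$se[match(out$id, ss_ea$id)]) - 1e-12))
})

test_that("allele harmonization flips swapped records and is involutive", {
  ss_smok <- toy_ss(c(0.10, 0.06), c(0.02, 0.02), label = "smoking")
  ss_ea <- toy_ss(c(0.05, 0.02), c(0.01, 0.015), label = "EA")
  flipped <- ss_ea
  flipped$a1 <- ss_ea$a2; flipped$a2 <- ss_ea$a1
  flipped$beta <- -ss_ea$beta
  flipped$freq_a1 <- 1 - ss_ea$freq_a1
  flipped <- new_sumstats(flipped[, setdiff(names(flipped), c("z", "p"))], "EA")
  fit <- list(b_med_hat = 0.4, se = 0.02, overlap_term = 0.1)
  expect_equal(subtract_ea(ss_smok, flipped, fit)$beta,
               subtract_ea(ss_smok, ss_ea, fit)$beta)
})

test_that("strand-ambiguous and unalignable SNPs are dropped with reasons", {
  ss_smok <- new_sumstats(data.frame(
    id = c("rs1", "rs2", "rs3", "rs4"), chrom = 1L, pos_bp = (1:4) * 1e5,
    a1 = c("A", "A", "A", "C"), a2 = c("G", "T", "G", "G"),
    freq_a1 = 0.3, beta = 0.1, se = 0.02, n_eff = 100L), "smoking")
  ss_ea <- new_sumstats(data.frame(
    id = c("rs1", "rs2", "rs3", "rs4"), chrom = 1L, pos_bp = (1:4) * 1e5,
    a1 = c("A", "A", "C", "C"), a2 = c("G", "T", "T", "G"),
    freq_a1 = 0.3, beta = 0.05, se = 0.01, n_eff = 100L), "EA")
  out <- subtract_ea(ss_smok, ss_ea, list(b_med_hat = 0.4, se = 0, overlap_term = 0))
  drops <- attr(out, "dropped")
  expect_equal(out$id, "rs1")                       # rs4 is ambiguous C/G
  expect_setequal(drops$id, c("rs2", "rs3", "rs4"))
  expect_equal(drops$reason[drops$id == "rs2"], "strand_ambiguous")
  expect_equal(drops$reason[drops$id == "rs3"], "allele_mismatch")
  disjoint <- new_sumstats(data.frame(id = "zz99", a1 = "A", a2 = "G",
                                      freq_a1 = 0.3, beta = 0.1, se = 0.01,
                                      n_eff = 100L), "x")
  expect_error(subtract_ea(ss_smok, disjoint,
                           list(b_med_hat = 0, se = 0, overlap_term = 0)),
               class = "smokesub_alignment_error")
})

test_that("full-mediation simulation leaves near-zero direct effects on shared SNPs", {
  reps <- sapply(1:5, function(r) {
    p <- simulate_genotypes(3000, 300, block_size = 10, rho = 0.8, seed = 40 + r)
    eff <- make_true_effects(300, h2_ea = 0.4, h2_direct = 0, b_med = 0.4,
                             gamma_rge = 0, seed = 50 + r)
    ph <- simulate_phenotypes(p, eff, seed = 60 + r)
    ss_ea <- run_gwas(p, ph$ea_years, trait_label = "EA")
    ss_smok <- run_gwas(p, ph$smoking_liability, trait_label = "smoking")
    out <- subtract_ea(ss_smok, ss_ea, list(b_med_hat = 0.4, se = 0,
                                            overlap_term = 0))
    mean(out$beta / out$se)   # mean standardized direct effect
  })
  expect_lt(abs(mean(reps)), 2 * sd(reps) / sqrt(5) + 0.1)
})

test_that("clumping handles LD absorption, chromosomes and the empty case", {
  # two significant SNPs 100 kb apart in one high-LD block -> one locus
  p <- simulate_genotypes(2000, 10, block_size = 10, rho = 0.95, seed = 71)
  ss <- run_gwas(p, p$dosages[, 1] + p$dosages[, 2] + rnorm(2000, 0, 0.5))
  loci <- clump_loci(ss, p)
  expect_equal(length(loci), 1)
  expect_true(all(c("rs000001", "rs000002") %in% loci[[1]]$member_snps))

  # two significant SNPs on different chromosomes -> two loci
  p2 <- simulate_genotypes(2000, 46, block_size = 1, rho = 0, seed = 72)
  stopifnot(p2$snp_meta$chrom[1] != p2$snp_meta$chrom[40])
  ss2 <- run_gwas(p2, p2$dosages[, 1] + p2$dosages[, 40] + rnorm(2000, 0, 0.5))
  expect_equal(length(clump_loci(ss2, p2)), 2)

  expect_length(clump_loci(run_gwas(p2, rnorm(2000)), p2), 0)
})

test_that("clumping matches the hand-enumerated greedy oracle and ignores input order", {
  p <- simulate_genotypes(3000, 25, block_size = 5, rho = 0.9, seed = 81)
  set.seed(82)
  y <- p$dosages[, 3] + 0.8 * p$dosages[, 13] + 0.7 * p$dosages[, 23] + rnorm(3000, 0, 0.4)
  ss <- run_gwas(p, y)
  loci <- clump_loci(ss, p)

  r2 <- cor(p$dosages)^2
  oracle <- clump_oracle(ss$p, ss$chrom, ss$pos_bp, r2, 5e-8, 0.1, 250000)
  expect_equal(length(loci), length(oracle))
  for (k in seq_along(loci))
    expect_equal(sort(loci[[k]]$member_snps), sort(ss$id[oracle[[k]]]))
  for (l in loci)
    expect_true(all(l$lead_p <= ss$p[match(l$member_snps, ss$id)]))

  perm <- sample(nrow(ss))
  ss_perm <- new_sumstats(as.data.frame(ss)[perm, ], "t")
  loci_perm <- clump_loci(ss_perm, p)
  expect_equal(sapply(loci_perm, `[[`, "lead_snp"), sapply(loci, `[[`, "lead_snp"))
})
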
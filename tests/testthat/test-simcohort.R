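test_that("genotype simulation is bit-identical for a fixed seed", {
  p1 <- simulate_genotypes(80, 30, block_size = 6, rho = 0.7, seed = 42)
  p2 <- simulate_genotypes(80, 30, block_size = 6, rho = 0.7, seed = 42)
  expect_identical(p1, p2)
  e1 <- make_true_effects(30, seed = 9)
  ph1 <- simulate_phenotypes(p1, e1, seed = 3)
  ph2 <- simulate_phenotypes(p2, make_true_effects(30, seed = 9), seed = 3)
  expect_identical(ph1, ph2)
  expect_false(identical(p1$dosages,
                         simulate_genotypes(80, 30, block_size = 6, rho = 0.7,
                                            seed = 43)$dosages))
})

test_that("panel structure invariants hold", {
  p <- simulate_genotypes(60, 45, block_size = 7, rho = 0.5, seed = 2)
  expect_true(all(p$dosages %in% 0:2))
  expect_equal(dim(p), c(60L, 45L))
  for (ch in unique(p$snp_meta$chrom))
    expect_true(all(diff(p$snp_meta$pos_bp[p$snp_meta$chrom == ch]) > 0))
  expect_equal(length(unique(p$snp_meta$block_id)), ceiling(45 / 7))
  # one block per SNP, blocks never straddle chromosomes
  expect_true(all(table(p$snp_meta$block_id, p$snp_meta$chrom) %in%
                    c(0, table(p$snp_meta$block_id))))
})

test_that("rho = 0 gives uncorrelated dosages within blocks", {
  n <- 4000
  p <- simulate_genotypes(n, 40, block_size = 10, rho = 0, seed = 7)
  r <- sapply(seq(1, 39), function(j)
    cor(p$dosages[, j], p$dosages[, j + 1]))
  expect_lt(abs(mean(r)), 3 / sqrt(n))
})

test_that("AR(1) dosage correlation matches the two-gamete enumeration oracle", {
  n <- 5000; rho <- 0.9
  p <- simulate_genotypes(n, 30, block_size = 10, rho = rho, seed = 11)
  adj <- which(diff(p$snp_meta$block_id) == 0)   # within-block adjacent pairs
  emp <- sapply(adj, function(j) cor(p$dosages[, j], p$dosages[, j + 1]))
  maf <- p$snp_meta$maf
  theo <- sapply(adj, function(j) dosage_cor_oracle(maf[j], maf[j + 1], rho))
  expect_lt(abs(mean(emp) - mean(theo)), 0.05)
})

test_that("liability thresholding reproduces the configured prevalence", {
  n <- 10000
  p <- simulate_genotypes(n, 50, block_size = 5, rho = 0.5, seed = 13)
  eff <- make_true_effects(50, prevalence = 0.43, seed = 14)
  ph <- simulate_phenotypes(p, eff, seed = 15)
  expect_gte(mean(ph$smoker), 0.41)
  expect_lte(mean(ph$smoker), 0.45)
})

test_that("cross-path knobs off decouple EA from the smoking liability", {
  n <- 6000
  p <- simulate_genotypes(n, 60, block_size = 6, rho = 0.5, seed = 21)
  eff <- make_true_effects(60, b_med = 0, gamma_rge = 0, delta_gxe = 0, seed = 22)
  ph <- simulate_phenotypes(p, eff, seed = 23)
  expect_lt(abs(cor(ph$ea_years, ph$smoking_liability)), 3 / sqrt(n))
})

test_that("the rGE path is recovered by regression on the EA genetic value", {
  n <- 8000
  p <- simulate_genotypes(n, 80, block_size = 8, rho = 0.5, seed = 31)
  for (gamma in c(0, 0.2)) {
    eff <- make_true_effects(80, gamma_rge = gamma, seed = 32)
    ph <- simulate_phenotypes(p, eff, seed = 33, exposure_missing_rate = 0)
    g <- scale(attr(ph, "genetic_values")$g_ea)
    fit <- summary(lm(ph$exposure ~ g))$coefficients
    expect_lt(abs(fit[2, 1] - gamma), 2 * fit[2, 2])
    if (gamma > 0) expect_gt(fit[2, 1], 0)
  }
})

test_that("realized heritability share matches h2_ea across replicates", {
  ratios <- sapply(1:20, function(r) {
    p <- simulate_genotypes(400, 40, block_size = 5, rho = 0.5, seed = 100 + r)
    eff <- make_true_effects(40, h2_ea = 0.3, seed = 200 + r)
    ph <- simulate_phenotypes(p, eff, seed = 300 + r)
    var(attr(ph, "genetic_values")$g_ea) / var(ph$ea_years)
  })
  expect_lt(abs(mean(ratios) - 0.3), 2 * sd(ratios) / sqrt(20))
})

test_that("exposure missingness hits the configured rate and is MAR-tilted by age", {
  p <- simulate_genotypes(2000, 30, block_size = 5, rho = 0.5, seed = 41)
  eff <- make_true_effects(30, seed = 42)
  ph <- simulate_phenotypes(p, eff, seed = 43, exposure_missing_rate = 0.103)
  expect_lte(abs(sum(is.na(ph$exposure)) - round(0.103 * 2000)), 1)
  expect_gt(mean(ph$age[is.na(ph$exposure)]), mean(ph$age[!is.na(ph$exposure)]))
})

test_that("winsorize clips to the configured bounds and nothing else", {
  expect_equal(winsorize(c(400, 2678.64, 12000), 500, 10000),
               c(500, 2678.64, 10000))
  x <- rnorm(50)
  expect_equal(winsorize(x, -Inf, Inf), x)
  expect_equal(winsorize(c(5, 5, 5), 5, 5), c(5, 5, 5))
  expect_error(winsorize(1:3, 2, 1), "lo <= hi")
})

test_that("parameter violations raise parameter errors", {
  expect_error(simulate_genotypes(0, 10), class = "smokesub_parameter_error")
  expect_error(simulate_genotypes(10, 10, rho = 1.2), class = "smokesub_parameter_error")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0.3, 0.1)),
               class = "smokesub_parameter_error")
  expect_error(make_true_effects(10, h2_direct = 0.5, b_med = 0.8),
               class = "smokesub_parameter_error")
  p <- simulate_genotypes(50, 10, seed = 1)
  expect_error(simulate_phenotypes(p, make_true_effects(20, seed = 1)),
               class = "smokesub_parameter_error")
})
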
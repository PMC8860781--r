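test_that("Keller design adds the full interaction-column count", {
  tab <- make_analysis_table(n = 300, n_pcs = 10, seed = 3)
  base <- function(pgs, keller) model_spec("smoker", pgs = pgs, env = "exposure",
                                           pcs = paste0("pc", 1:10), keller = keller)
  d1 <- build_design(tab, base("pgs_allsmok", TRUE))
  expect_equal(d1$n_interactions, 1 + 10 + 10)
  d2 <- build_design(tab, base(c("pgs_ea", "pgs_smok_noea"), TRUE))
  expect_equal(d2$n_interactions, 2 + 10 + 20)
  d0 <- build_design(tab, base("pgs_allsmok", FALSE))
  expect_equal(d0$n_interactions, 0)
  expect_equal(ncol(d1$X) - ncol(d0$X), 21)
  # continuous predictors standardized before products
  expect_lt(abs(mean(d1$X[, "pgs_allsmok"])), 1e-8)
  expect_lt(abs(sd(d1$X[, "exposure"]) - 1), 1e-8)
  expect_error(build_design(tab, model_spec("nope")), class = "smokesub_schema_error")
})

test_that("logistic fit reproduces closed-form 2x2 and intercept-only results", {
  x <- rep(c(1, 0), c(100, 100))
  y <- c(rep(c(1, 0), c(20, 80)), rep(c(1, 0), c(40, 60)))
  fit <- fit_logistic(list(X = cbind(`(Intercept)` = 1, x = x), y = y))
  expect_equal(fit$coefficients$b[2], log((20 * 60) / (80 * 40)), tolerance = 1e-6)
  expect_equal(fit$coefficients$or[2], 0.375, tolerance = 1e-6)

  y2 <- rep(c(1, 0), c(30, 70))
  fit2 <- fit_logistic(list(X = cbind(`(Intercept)` = rep(1, 100)), y = y2))
  expect_equal(fit2$coefficients$b[1], log(0.3 / 0.7), tolerance = 1e-6)
  expect_equal(fit2$r2, 0)                     # Nagelkerke of the null model
  expect_error(fit_logistic(list(X = cbind(rep(1, 10)), y = rep(1, 10))),
               class = "smokesub_parameter_error")
})

test_that("separation raises a non-convergence error", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  expect_error(fit_logistic(list(X = cbind(1, x = x), y = y)),
               class = "smokesub_nonconvergence")
})

test_that("GEE with singleton clusters reduces to the independence fit", {
  tab <- make_analysis_table(n = 400, seed = 7)
  spec <- model_spec("smoker", pgs = "pgs_allsmok", env = "exposure",
                     pcs = paste0("pc", 1:5))
  d <- build_design(tab, spec)
  glm_fit <- fit_logistic(d)
  gee_fit <- fit_gee_exchangeable(d, cluster_ids = seq_along(d$y))
  expect_equal(gee_fit$coefficients$b, glm_fit$coefficients$b, tolerance = 1e-6)
  expect_equal(gee_fit$alpha, 0)

  lin <- fit_linear(list(X = d$X, y = tab$exposure[complete.cases(tab)]))
  gee_lin <- fit_gee_exchangeable(list(X = d$X, y = tab$exposure[complete.cases(tab)]),
                                  cluster_ids = seq_len(nrow(d$X)),
                                  family = "gaussian")
  expect_equal(gee_lin$coefficients$b, lin$coefficients$b, tolerance = 1e-8)
  expect_error(fit_gee_exchangeable(d, cluster_ids = rep(1, nrow(d$X))),
               class = "smokesub_degenerate_clustering")
})

test_that("independence-working GEE sandwich matches sandwich::vcovCL", {
  skip_if_not_installed("sandwich")
  set.seed(11)
  n_cl <- 60; size <- 4
  cl <- rep(seq_len(n_cl), each = size)
  x <- rnorm(n_cl * size)
  u <- rnorm(n_cl)[cl]
  y <- rbinom(n_cl * size, 1, plogis(0.3 * x + u))
  X <- cbind(`(Intercept)` = 1, x = x)
  ours <- fit_gee_exchangeable(list(X = X, y = y), cluster_ids = cl, alpha = 0)
  ref <- glm(y ~ x, family = binomial)
  vc <- sandwich::vcovCL(ref, cluster = cl, type = "HC0", cadjust = FALSE)
  expect_equal(ours$coefficients$se, unname(sqrt(diag(vc))), tolerance = 1e-4)
})

test_that("robust SEs exceed naive SEs for cluster-constant covariates under clustering", {
  wins <- sapply(1:100, function(r) {
    set.seed(400 + r)
    n_cl <- 50; size <- 4
    cl <- rep(seq_len(n_cl), each = size)
    xc <- rnorm(n_cl)[cl]                       # cluster-constant covariate
    u <- rnorm(n_cl, 0, 1)[cl]                  # strong shared intercept (ICC ~ 0.5)
    y <- 0.2 * xc + u + rnorm(n_cl * size)
    X <- cbind(`(Intercept)` = 1, xc = xc)
    gee <- fit_gee_exchangeable(list(X = X, y = y), cluster_ids = cl,
                                family = "gaussian", alpha = 0)
    naive <- fit_linear(list(X = X, y = y))
    gee$coefficients$se[2] > naive$coefficients$se[2]
  })
  expect_gte(mean(wins), 0.95)
})

test_that("the exchangeable working correlation recovers a generative ICC", {
  alphas <- sapply(1:20, function(r) {
    set.seed(500 + r)
    n_cl <- 100; size <- 4
    cl <- rep(seq_len(n_cl), each = size)
    x <- rnorm(n_cl * size)
    y <- 0.3 * x + sqrt(0.3) * rnorm(n_cl)[cl] + sqrt(0.7) * rnorm(n_cl * size)
    fit_gee_exchangeable(list(X = cbind(1, x = x), y = y), cluster_ids = cl,
                         family = "gaussian")$alpha
  })
  expect_lt(abs(mean(alphas) - 0.3), 0.1)
})

test_that("the model ladder is nested, labelled and thresholded as configured", {
  tab <- make_analysis_table(n = 1500, seed = 13, gamma_rge = 0.1)
  pgs_set <- c(allsmok = "pgs_allsmok", ea = "pgs_ea", smok_noea = "pgs_smok_noea")
  lad <- run_model_ladder(tab, pgs_set, "exposure", "smoker",
                          pcs = paste0("pc", 1:5))
  expect_named(lad, c("m0", "m1a", "m1b", "m2a", "m2b", "m3a", "m3b"))
  r2 <- vapply(lad, `[[`, numeric(1), "r2")
  expect_true(all(diff(r2[c("m0", "m1a", "m2a", "m3a")]) >= -1e-10))
  expect_true(all(diff(r2[c("m0", "m1b", "m2b", "m3b")]) >= -1e-10))
  expect_equal(lad$m0$delta_r2, 0)
  expect_equal(lad$m3b$delta_r2, lad$m3b$r2 - lad$m0$r2)
  expect_true(all(vapply(lad, function(f) all(f$r2 >= 0 & f$r2 <= 1), logical(1))))
  thr <- attr(lad, "threshold")
  expect_equal(as.numeric(thr), 0.05 / 8)
  expect_equal(attr(thr, "display"), "0.006")
  # GEE route agrees on point estimates and reports refit R2
  tabc <- make_analysis_table(n = 800, seed = 14, cluster_size = 2)
  ladc <- run_model_ladder(tabc, pgs_set, "exposure", "smoker",
                           cluster = "cluster_id", pcs = paste0("pc", 1:5))
  expect_false(is.na(ladc$m3a$r2))
  expect_true("alpha" %in% names(ladc$m1a))
})

test_that("rGE checks detect the generative path and its subtraction", {
  tab0 <- make_analysis_table(n = 2000, seed = 17, gamma_rge = 0)
  f0 <- rge_check(tab0, "pgs_ea", "exposure", pcs = paste0("pc", 1:5))
  row0 <- f0$coefficients[f0$coefficients$term == "pgs_ea", ]
  expect_lt(abs(row0$b), 2 * row0$se)

  tab1 <- make_analysis_table(n = 4000, seed = 18, gamma_rge = 0.25)
  f1 <- rge_check(tab1, "pgs_ea", "exposure", pcs = paste0("pc", 1:5))
  row1 <- f1$coefficients[f1$coefficients$term == "pgs_ea", ]
  expect_gt(row1$b, 0)
  expect_lt(row1$p, 0.05)
  # the EA-free smoking PGS shows attenuated rGE relative to the all-smoking PGS
  fa <- rge_check(tab1, "pgs_allsmok", "exposure", pcs = paste0("pc", 1:5))
  fs <- rge_check(tab1, "pgs_smok_noea", "exposure", pcs = paste0("pc", 1:5))
  ba <- abs(fa$coefficients$b[fa$coefficients$term == "pgs_allsmok"])
  bs <- abs(fs$coefficients$b[fs$coefficients$term == "pgs_smok_noea"])
  expect_lt(bs, ba)
})

test_that("imputation is proper, deterministic, and degenerates to the identity", {
  tab <- data.frame(z = rnorm(200), y = rnorm(200))
  tab$e <- 0.5 * tab$z + rnorm(200, 0, 0.5)
  full <- impute_missing(tab, predictors = c("z", "y"), target = "e", m = 3, seed = 1)
  expect_true(all(vapply(full, identical, logical(1), tab)))

  tab$e[1:30] <- NA
  i1 <- impute_missing(tab, predictors = c("z", "y"), target = "e", m = 5, seed = 9)
  i2 <- impute_missing(tab, predictors = c("z", "y"), target = "e", m = 5, seed = 9)
  expect_identical(i1, i2)
  expect_false(identical(i1[[1]]$e[1:30], i1[[2]]$e[1:30]))
  expect_true(all(!is.na(i1[[1]]$e)))
  expect_error(impute_missing(tab, predictors = c("z", "y"), target = "e", m = 1),
               class = "smokesub_parameter_error")
  expect_error(impute_missing(transform(tab, e = NA_real_),
                              predictors = c("z", "y"), target = "e", m = 3),
               class = "smokesub_imputation_error")
})

test_that("pooled MI slope matches the complete-data slope under MCAR", {
  set.seed(21)
  n <- 800
  z <- rnorm(n); e <- 0.6 * z + rnorm(n, 0, 0.8); y <- 0.3 * e + rnorm(n)
  complete_fit <- fit_linear(list(X = cbind(1, e = e), y = y))
  b_full <- complete_fit$coefficients$b[2]
  tab <- data.frame(z = z, e = e, y = y)
  tab$e[sample(n, 80)] <- NA
  imp <- impute_missing(tab, predictors = c("z", "y"), target = "e", m = 10, seed = 22)
  pooled <- pool_rubin(lapply(imp, function(d)
    fit_linear(list(X = cbind(1, e = d$e), y = d$y))))
  row <- pooled$coefficients[pooled$coefficients$term == "e", ]
  expect_lt(abs(row$b - b_full), 2 * row$se)
  expect_equal(row$T, row$W + (1 + 1 / 10) * row$B)
})

test_that("Rubin pooling reproduces hand arithmetic and the B = 0 degenerate case", {
  mk <- function(b, se) structure(list(coefficients = data.frame(
    term = "x", b = b, se = se, or = NA_real_, p = 0.5), family = "gaussian"),
    class = "fit_result")
  pooled <- pool_rubin(list(mk(1, 1), mk(3, 1)))
  row <- pooled$coefficients
  expect_equal(row$b, 2)
  expect_equal(row$B, 2)            # var(c(1, 3))
  expect_equal(row$T, 1 + 1.5 * 2)  # W + (1 + 1/m) B
  expect_equal(row$se, 2)

  same <- pool_rubin(list(mk(1.5, 0.4), mk(1.5, 0.4), mk(1.5, 0.4)))
  expect_equal(same$coefficients$T, same$coefficients$W)
  expect_equal(same$coefficients$se, 0.4)
  expect_error(pool_rubin(list(mk(1, 1))), class = "smokesub_parameter_error")
})

test_that("fallback carry-forward fills only jointly resolvable gaps", {
  tab <- data.frame(now = c(1, NA, NA, 4), base = c(9, 2, NA, 9))
  out <- fill_from_fallback(tab, "now", "base")
  expect_equal(out$now, c(1, 2, NA, 4))
  expect_error(fill_from_fallback(tab, "now", "gone"),
               class = "smokesub_schema_error")
})

test_that("Bonferroni thresholds divide exactly and round only for display", {
  t8 <- bonferroni_threshold(0.05, 8)
  expect_equal(as.numeric(t8), 0.00625)
  expect_equal(attr(t8, "display"), "0.006")
  t15 <- bonferroni_threshold(0.05, 15)
  expect_equal(as.numeric(t15), 0.05 / 15)
  expect_equal(attr(t15, "display"), "0.003")
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), class = "smokesub_parameter_error")
})
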
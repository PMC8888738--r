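test_that("permutation importance singles out the informative predictor", {
  set.seed(12)
  firsts <- replicate(5, {
    n <- 300
    x <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(x) <- c("signal", paste0("noise", 1:5))
    y <- 1.5 * x$signal + rnorm(n, 0, 0.5)
    rk <- rank_drivers(y, x, seed = sample.int(1e6, 1))
    rk$predictor[1]
  })
  expect_true(all(firsts == "signal"))
})

test_that("importances sit near zero when the response is pure noise", {
  set.seed(13)
  n <- 300
  x <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  y <- rnorm(n)
  rk <- rank_drivers(y, x, seed = 7)
  expect_true(all(abs(rk$importance_pct_inc_mse) < 5))
})

test_that("duplicated predictors split importance but keep the union on top", {
  set.seed(14)
  n <- 300
  x <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  names(x) <- c("signal", paste0("noise", 1:3))
  y <- 2 * x$signal + rnorm(n, 0, 0.4)
  x$signal_copy <- x$signal
  rk <- rank_drivers(y, x, seed = 8)
  top2 <- rk$predictor[1:2]
  expect_setequal(top2, c("signal", "signal_copy"))
})

test_that("constant predictors are flagged with zero importance", {
  set.seed(15)
  x <- data.frame(a = rnorm(100), flat = rep(1, 100), b = rnorm(100))
  y <- x$a + rnorm(100, 0, 0.3)
  rk <- rank_drivers(y, x, seed = 3)
  expect_equal(rk$importance_pct_inc_mse[rk$predictor == "flat"], 0)
  expect_true(rk$constant[rk$predictor == "flat"])
})

test_that("marginal association signs come from weighted slopes", {
  set.seed(16)
  n <- 200
  x <- data.frame(up = rnorm(n), down = rnorm(n))
  y <- x$up - x$down + rnorm(n, 0, 0.2)
  rk <- rank_drivers(y, x, seed = 4)
  expect_equal(rk$direction[rk$predictor == "up"], 1)
  expect_equal(rk$direction[rk$predictor == "down"], -1)
})

test_that("forward AIC admits interactions without site-condition main effects", {
  d <- simulate_dataset(sim_config(n_sites = 120, seed = 51))
  tab <- assemble_analysis_table(d)
  mod <- fit_interaction_model(tab, "soc_rr", "pes_rr", "biomass_rr",
                               weights = "w_data")
  expect_true("pes_rr" %in% mod$selected)
  # site conditions never enter as direct effects
  expect_false(any(mod$selected %in% c("f_climate", "sand", "ph", "plu")))
  # the trait effect weakens as the climate becomes favourable:
  # positive pes:f_climate coefficient under a negative trait effect
  expect_true("pes_rr:f_climate" %in% mod$selected)
  cf <- stats::coef(mod$fit)
  expect_lt(cf[["pes_rr"]], 0)
  expect_gt(cf[[grep("pes_rr.f_climate|f_climate.pes_rr", names(cf), value = TRUE)]], 0)
})

test_that("a null trait effect is usually excluded by selection", {
  excluded <- vapply(52:56, function(s) {
    d <- simulate_dataset(sim_config(beta_trait = 0, harshness_interaction = 0,
                                     n_sites = 60, seed = s))
    tab <- assemble_analysis_table(d)
    mod <- fit_interaction_model(tab, "soc_rr", "pes_rr", "biomass_rr",
                                 weights = "w_data")
    !"pes_rr" %in% mod$selected
  }, logical(1))
  expect_gte(mean(excluded), 0.6)
})

test_that("weighted fits honour case weights exactly", {
  set.seed(18)
  n <- 60
  dat <- data.frame(
    soc_rr = rnorm(n), pes_rr = rnorm(n), biomass_rr = rnorm(n),
    f_climate = runif(n), sand = runif(n, 100, 900), ph = runif(n, 4, 7)
  )
  m1 <- fit_interaction_model(dat, "soc_rr", "pes_rr", "biomass_rr",
                              include_plu = FALSE, force_full = TRUE)
  dat$w <- rep(3.7, n)
  m2 <- fit_interaction_model(dat, "soc_rr", "pes_rr", "biomass_rr",
                              weights = "w", include_plu = FALSE,
                              force_full = TRUE)
  expect_equal(stats::coef(m2$fit), stats::coef(m1$fit))
  # a duplicated record equals one record with doubled weight
  dat$w2 <- c(2, rep(1, n - 1))
  dup <- rbind(dat[1, ], dat)
  dup$w2 <- 1
  m3 <- fit_interaction_model(dat, "soc_rr", "pes_rr", "biomass_rr",
                              weights = "w2", include_plu = FALSE,
                              force_full = TRUE)
  m4 <- fit_interaction_model(dup, "soc_rr", "pes_rr", "biomass_rr",
                              weights = "w2", include_plu = FALSE,
                              force_full = TRUE)
  expect_equal(stats::coef(m3$fit), stats::coef(m4$fit))
})

test_that("two-class contrasts gate on normality and detect real shifts", {
  expect_error(two_class_contrast(c(0.1, 0.2)), ">= 3")
  deg <- two_class_contrast(rep(0.3, 10))
  expect_equal(deg$method, "degenerate")
  set.seed(19)
  norm <- two_class_contrast(rnorm(20, 0, 0.1))
  expect_equal(norm$method, "t")
  skewed <- two_class_contrast(exp(rnorm(40, 0, 1.5)) - 0.5)
  expect_equal(skewed$method, "wilcoxon")
  # power at a log(1.5) shift, n = 30, sigma = 0.4
  hits <- replicate(200, two_class_contrast(rnorm(30, log(1.5), 0.4))$p < 0.05)
  expect_gte(mean(hits), 0.9)
})

test_that("Bonferroni adjusts within a contrast family", {
  expect_equal(adjust_contrast_family(c(0.01, 0.04)), c(0.02, 0.08))
})

test_that("validation correction factors rescale shallow-profile values", {
  expect_equal(as.numeric(apply_validation_correction(0.2, "ff_esm_0000_1000")),
               0.223)
  expect_equal(as.numeric(apply_validation_correction(0.2, "ff_esm_0000_2000")),
               0.2128)
  expect_equal(as.numeric(apply_validation_correction(0, "ff_esm_0000_1000")), 0)
  expect_error(apply_validation_correction(0.2, "ff_esm_0000_3000"))
})

test_that("exact texture collinearity collapses to the sand representative", {
  set.seed(20)
  n <- 80
  sand <- runif(n, 100, 900)
  silt <- runif(n, 50, 1000 - sand)
  cov <- data.frame(sand = sand, silt = silt, clay = 1000 - sand - silt,
                    ph = runif(n, 4, 8))
  sc <- collinearity_screen(cov)
  expect_true("sand" %in% sc$retained)
  expect_false(any(c("clay") %in% sc$retained) && !"clay" %in% unlist(sc$blocks[lengths(sc$blocks) == 1]))
  expect_true("ph" %in% sc$retained)
})

test_that("independent covariates all survive the screen", {
  set.seed(21)
  cov <- as.data.frame(matrix(rnorm(300), 100, 3))
  sc <- collinearity_screen(cov)
  expect_setequal(sc$retained, names(cov))
})

test_that("block representatives carry the highest first-axis loading", {
  set.seed(22)
  n <- 200
  z <- rnorm(n)
  cov <- data.frame(a = z + rnorm(n, 0, 0.6), b = z + rnorm(n, 0, 0.2),
                    c = z + rnorm(n, 0, 0.9), other = rnorm(n))
  sc <- collinearity_screen(cov, threshold = 0.5, preferred = character(0))
  blk <- sc$blocks[lengths(sc$blocks) > 1][[1]]
  pca <- stats::prcomp(cov[, blk], center = TRUE, scale. = TRUE)
  brute <- blk[which.max(abs(pca$rotation[, 1]))]
  expect_true(brute %in% sc$retained)
})

test_that("the site random-intercept variant mirrors the fixed-effect fit", {
  d <- simulate_dataset(tiny_config(n_sites = 25, seed = 61))
  tab <- assemble_analysis_table(d)
  mod <- fit_interaction_model(tab, "soc_rr", "pes_rr", "biomass_rr",
                               weights = "w_data", include_plu = FALSE,
                               random_site = TRUE)
  expect_s4_class(mod$mixed_fit, "lmerMod")
  fe <- lme4::fixef(mod$mixed_fit)
  shared <- intersect(names(fe), rownames(mod$coefficients))
  expect_gt(length(shared), 1)
  # rr responses carry little between-site variance, so the mixed and
  # fixed estimates agree closely
  expect_equal(fe[shared], mod$coefficients[shared, "Estimate"],
               tolerance = 0.15, ignore_attr = TRUE)
})
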
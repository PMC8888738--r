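test_that("species means collapse duplicate sources before averaging", {
  expect_equal(species_mean(c(10, 20)), 15)
  expect_equal(species_mean(7), 7)
  expect_equal(species_mean(c(10, 10, 20), c("srcA", "srcA", "srcB")), 15)
  expect_error(species_mean(numeric(0)), "at least one")
})

test_that("the C/N/C:N identity closes any single missing member", {
  expect_equal(close_triplet(500, 20, NA)$cn, 25)
  expect_equal(close_triplet(NA, 20, 25)$c, 500)
  expect_equal(close_triplet(500, NA, 25)$n, 20)
  r <- close_triplet(500, 20, 30) # inconsistent but complete
  expect_false(r$consistent)
  expect_equal(r$cn, 30) # measured values kept
  expect_error(close_triplet(500, NA, NA), "at least two")
})

test_that("triplet closure over a table fills cells and flags conflicts", {
  obs <- data.frame(
    species = rep(c("sp1", "sp2"), each = 2),
    trait = c("leaf_c", "leaf_n", "leaf_c", "leaf_cn"),
    value = c(480, 16, 510, 30)
  )
  x <- trait_table(obs)
  x2 <- close_triplets(x)
  expect_equal(x2["sp1", "leaf_cn"], 30)
  expect_equal(x2["sp2", "leaf_n"], 17)
  expect_equal(attr(x2, "provenance")["sp1", "leaf_cn"], "closed")
})

test_that("regression gap-filling only touches missing cells", {
  set.seed(2)
  n <- 40
  p <- runif(n, 1, 10)
  x <- matrix(c(3 + 2 * p, p), n, 2,
              dimnames = list(paste0("sp", 1:n), c("target", "pred")))
  attr(x, "provenance") <- ifelse(is.na(x), NA, "measured")
  # no missing cells: unchanged
  expect_equal(suppressWarnings(gap_fill_regression(x, "target", "pred")), x,
               ignore_attr = TRUE)
  # noiseless relation: exact recovery
  x2 <- x
  x2[1:8, "target"] <- NA
  f2 <- suppressWarnings(gap_fill_regression(x2, "target", "pred")) # exact fit
  expect_equal(attr(f2, "fit_report")$r_squared, 1)
  expect_equal(f2[1:8, "target"], x[1:8, "target"], ignore_attr = TRUE)
  # observed cells never altered
  expect_equal(f2[9:n, ], x[9:n, ], ignore_attr = TRUE)
})

test_that("noisy gap-filling lands within two residual SDs almost always", {
  set.seed(9)
  hits <- 0; total <- 0
  for (rep in 1:20) {
    n <- 300
    p <- runif(n, 0, 10)
    sd_res <- 0.5
    y <- 1 + 0.8 * p + rnorm(n, 0, sd_res)
    x <- cbind(target = y, pred = p)
    rownames(x) <- paste0("sp", 1:n)
    attr(x, "provenance") <- ifelse(is.na(x), NA, "measured")
    miss <- sample(n, 60)
    truth <- x[miss, "target"]
    x[miss, "target"] <- NA
    f <- gap_fill_regression(x, "target", "pred")
    hits <- hits + sum(abs(f[miss, "target"] - truth) <= 2 * sd_res)
    total <- total + 60
  }
  # expected coverage of a +/-2 sigma band is 95.4%; allow two binomial
  # standard errors of Monte-Carlo noise around the 95% requirement
  expect_gte(hits / total, 0.95 - 2 * sqrt(0.954 * 0.046 / total))
})

test_that("degenerate predictors are refused", {
  x <- cbind(target = c(1:5, NA), pred = rep(3, 6))
  rownames(x) <- paste0("sp", 1:6)
  expect_error(gap_fill_regression(x, "target", "pred", min_n = 5),
               "degenerate")
})

test_that("clade means fill hierarchically", {
  x <- matrix(c(10, NA, 30, NA), 4, 1,
              dimnames = list(c("s1", "s2", "s3", "s4"), "leaf_c"))
  attr(x, "provenance") <- ifelse(is.na(x), NA, "measured")
  lin <- data.frame(species = c("s1", "s2", "s3", "s4"),
                    genus = c("g1", "g1", "g2", "g3"),
                    family = c("f1", "f1", "f1", "f2"),
                    class = "c1")
  f <- clade_mean_fill(x, "leaf_c", lin)
  expect_equal(f["s2", "leaf_c"], 10)          # genus mean
  expect_equal(f["s4", "leaf_c"], 20)          # family f2 empty -> class mean
  expect_equal(attr(f, "provenance")["s2", "leaf_c"], "clade_mean")
})

test_that("a complete rank-one table gives a perfect first axis", {
  d <- simulate_dataset(tiny_config(trait_noise_sd = 0, seed = 4))
  x <- trait_table(d$traits)
  # centring removes the trait baselines; rank one remains
  expect_equal(qr(scale(x, scale = FALSE))$rank, 1)
  idx <- build_index(x, anchor = "amax")
  expect_equal(idx$variance_explained_axis1, 1, tolerance = 1e-9)
  r <- cor(idx$scores[d$species$species], d$species$pes_score)
  expect_equal(abs(r), 1, tolerance = 1e-9)
})

test_that("the index recovers the latent factor under noise and missingness", {
  set.seed(21)
  n <- 100; p <- 10
  loads <- c(1, 0.9, 0.8, 0.7, 0.6, -0.8, -0.7, -0.6, 0.5, -0.4)
  f <- rnorm(n)
  x <- outer(f, loads) + matrix(rnorm(n * p, 0, 0.3), n, p)
  dimnames(x) <- list(paste0("sp", 1:n),
                      c("amax", paste0("t", 2:p)))
  x[sample(length(x), round(0.2 * length(x)))] <- NA
  idx <- build_index(x, anchor = "amax")
  expect_gte(abs(cor(idx$scores, f)), 0.9)
})

test_that("the axis orientation is anchored on Amax", {
  set.seed(3)
  x <- outer(rnorm(30), c(1, 0.8, -0.5, 0.3, -0.7)) +
    matrix(rnorm(150, 0, 0.2), 30, 5)
  colnames(x) <- c("amax", "b", "c", "d", "e")
  rownames(x) <- paste0("sp", 1:30)
  i1 <- build_index(x, anchor = "amax")
  i2 <- build_index(-x, anchor = "amax")
  expect_gt(i1$loadings["amax"], 0)
  expect_gt(i2$loadings["amax"], 0)
  # flipping every column flips the raw axis; the anchor restores it
  expect_equal(unname(i2$scores), unname(-i1$scores), tolerance = 1e-8)
})

test_that("index scores are invariant to affine trait rescaling", {
  set.seed(13)
  x <- outer(rnorm(40), c(1, 0.5, -0.8, 0.6)) + matrix(rnorm(160, 0, 0.3), 40, 4)
  colnames(x) <- c("amax", "b", "c", "d")
  rownames(x) <- paste0("sp", 1:40)
  x[sample(length(x), 16)] <- NA
  i1 <- build_index(x, anchor = "amax", rank = 1)
  y <- x
  y[, "b"] <- 100 + 7 * y[, "b"]
  y[, "c"] <- -2 * y[, "c"] + 1
  i2 <- build_index(y, anchor = "amax", rank = 1)
  expect_equal(i2$scores, i1$scores, tolerance = 1e-6)
})

test_that("imputation never alters observed cells and matches PCA when complete", {
  set.seed(17)
  x <- outer(rnorm(25), c(1, 0.7, -0.6)) + matrix(rnorm(75, 0, 0.2), 25, 3)
  colnames(x) <- c("amax", "b", "c")
  rownames(x) <- paste0("sp", 1:25)
  xm <- x
  miss <- sample(length(x), 10)
  xm[miss] <- NA
  comp <- impute_pca(xm, rank = 1)
  expect_equal(comp[-miss], x[-miss])
  # complete table: imputation path and plain PCA coincide
  i_imp <- build_index(x, anchor = "amax", rank = 1)
  i_pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  s <- i_pca$x[, 1] * sign(i_pca$rotation["amax", 1])
  expect_equal(unname(i_imp$scores), unname(s), tolerance = 1e-8)
})

test_that("degenerate index inputs are rejected or repaired with a warning", {
  x <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("s", 1:5), c("amax", "b", "c", "d")))
  x[, "d"] <- NA
  expect_warning(idx <- build_index(x, anchor = "amax"), "all-missing")
  expect_length(idx$scores, 5)
  expect_error(suppressWarnings(build_index(x[1:4, ], anchor = "amax")),
               ">= 5 species")
})
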
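test_that("SOM converts to SOC by the fixed divisor and round-trips", {
  expect_equal(convert_som(10), 5)
  expect_error(convert_som(0), "positive")
  soc <- runif(20, 1, 100)
  expect_equal(convert_som(2 * soc), soc)
})

test_that("bulk-density estimation dispatches by layer kind and SOC level", {
  spec <- pedotransfer_spec()
  ff <- make_layers(kind = "forest_floor", top = NA, bottom = NA)
  expect_equal(estimate_bd(ff, spec)$bd, 0.1346)
  measured <- make_layers(top = 0, bottom = 10, bd = 1.23, soc = 15)
  r <- estimate_bd(measured, spec)
  expect_equal(r$bd, 1.23)
  expect_equal(r$provenance, "measured")
  # dispatch threshold: soc <= 20 uses the texture rule, > 20 the SOC rule
  spec2 <- pedotransfer_spec(
    rule_low_soc = function(soc, clay, silt, sand) 1.1,
    rule_high_soc = function(soc) 0.9
  )
  low <- make_layers(top = 0, bottom = 10, soc = 20, clay = 1, silt = 1, sand = 1)
  high <- make_layers(top = 0, bottom = 10, soc = 20.01)
  expect_equal(estimate_bd(low, spec2)$bd, 1.1)
  expect_equal(estimate_bd(high, spec2)$bd, 0.9)
  bare <- make_layers(top = 0, bottom = 10)
  expect_error(estimate_bd(bare, spec), "BD unrecoverable")
})

test_that("injecting the generator's BD(SOC) coupling recovers BD exactly", {
  cfg <- tiny_config()
  rule <- bd_coupling_rule(cfg)
  spec <- pedotransfer_spec(rule_low_soc = rule,
                            rule_high_soc = rule)
  soc <- c(5, 15, 25, 60)
  lay <- make_layers(top = c(0, 10, 20, 30), bottom = c(10, 20, 30, 40),
                     soc = soc)
  for (i in seq_along(soc)) {
    expect_equal(estimate_bd(lay[i, ], spec)$bd, rule(soc[i]))
  }
})

test_that("pool-based BD fallback fits a monotone log-log regression", {
  pool <- exp(seq(log(5), log(80), length.out = 30))
  exact <- data.frame(bd_kg_l = exp(0.5 - 0.2 * log(pool)),
                      soc_pool_mg_ha = pool)
  fb <- suppressWarnings(fit_pool_fallback(exact)) # exact fit
  expect_equal(fb$r_squared, 1)
  expect_false(fb$degenerate)
  expect_equal(predict_pool_fallback(fb, 10), exp(0.5 - 0.2 * log(10)))

  set.seed(42)
  n <- 288
  pool <- exp(runif(n, log(5), log(120)))
  noisy <- data.frame(
    bd_kg_l = exp(0.4 - 0.15 * log(pool) + rnorm(n, 0, 0.1)),
    soc_pool_mg_ha = pool
  )
  fb2 <- fit_pool_fallback(noisy)
  se <- summary(fb2$fit)$coefficients[2, 2]
  expect_lt(abs(fb2$slope - (-0.15)), 2 * se)
  expect_equal(fb2$n, n)

  flat <- data.frame(bd_kg_l = rep(1.2, 30), soc_pool_mg_ha = pool[1:30])
  expect_true(suppressWarnings(fit_pool_fallback(flat))$degenerate)
  expect_error(fit_pool_fallback(exact[1:5, ]), ">= 10")
})

test_that("uniform single- and two-layer profiles give the forced arithmetic", {
  one <- make_layers(top = 0, bottom = 10, bd = 1.0, soc = 10)
  p <- to_esm(one)
  expect_equal(p$total_mass, 1000)
  expect_equal(unname(p$esm_pools[1]), 10)
  expect_true(all(is.na(p$esm_pools[-1])))

  two <- make_layers(top = c(0, 10), bottom = c(10, 20), bd = 1.0,
                     soc = c(10, 5))
  p2 <- to_esm(two)
  expect_equal(unname(p2$esm_pools[1:2]), c(10, 5))
})

test_that("constant-concentration profiles yield identical full ESM pools", {
  lay <- make_layers(top = seq(0, 70, 10), bottom = seq(10, 80, 10),
                     bd = 1.25, soc = 12)
  p <- to_esm(lay)
  full <- !is.na(p$esm_pools)
  expect_true(any(full))
  expect_equal(unname(p$esm_pools[full]),
               rep(12, sum(full)))
})

test_that("ESM pools match the analytic integral of the continuous profile", {
  scheme <- seq(0, 50, by = 2.5)
  lay <- profile_layers(scheme, c_surface = 30, k = 4e-4)
  p <- to_esm(lay)
  tru <- analytic_layer_pool(30, 4e-4, (0:7) * 1000, (1:8) * 1000)
  ok <- !is.na(p$esm_pools)
  expect_true(sum(ok) >= 3)
  expect_true(all(abs(p$esm_pools[ok] - tru[ok]) / tru[ok] < 0.02))
})

test_that("piecewise-constant profiles agree with 1-mm slab integration", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    bounds <- c(0, sort(sample(seq(5, 60, 5), n)))
    bd <- runif(n, 0.9, 1.4)
    soc <- sort(runif(n, 3, 40), decreasing = TRUE)
    lay <- make_layers(top = bounds[-length(bounds)], bottom = bounds[-1],
                       bd = bd, soc = soc)
    p <- to_esm(lay)
    oracle <- slab_esm_oracle(bounds[-length(bounds)], bounds[-1], bd, soc)
    ok <- !is.na(p$esm_pools) & !is.na(oracle)
    expect_true(all(abs(p$esm_pools[ok] - oracle[ok]) / oracle[ok] < 1e-3))
  }
})

test_that("thick-layer pools disaggregate by the mean relative distribution", {
  expect_equal(unname(disaggregate_thick_layer(20, 3000)), c(9, 6, 5))
  expect_equal(unname(disaggregate_thick_layer(20, 1000)), 20)
  d2 <- disaggregate_thick_layer(20, 2000)
  expect_equal(unname(d2), 20 * c(0.45, 0.30) / 0.75)
  expect_equal(sum(d2), 20)
  # beyond the printed 3000 case the profile extends geometrically
  d4 <- disaggregate_thick_layer(20, 4000)
  expect_length(d4, 4)
  expect_equal(sum(d4), 20, tolerance = 1e-9)
  expect_true(all(diff(d4) < 0))
  expect_error(disaggregate_thick_layer(20, 1500), "multiple of 1000")
})

test_that("mass is conserved through disaggregation to 1e-9 relative", {
  set.seed(1)
  for (mass in c(1000, 2000, 3000, 5000, 8000)) {
    pool <- runif(1, 1, 200)
    expect_equal(sum(disaggregate_thick_layer(pool, mass)), pool,
                 tolerance = 1e-9)
  }
})

test_that("a single thick measured layer is split by the relative profile", {
  lay <- make_layers(top = 0, bottom = 30, bd = 1.0, soc = 10)
  p <- to_esm(lay) # mass 3000, pool 30
  expect_equal(unname(p$esm_pools[1:3]), 30 * c(0.45, 0.30, 0.25))
  expect_true("disaggregated" %in% p$provenance)
})

test_that("topsoil and combined pools sum their components", {
  prof <- structure(list(
    stand_id = "s", forest_floor_pool = 4,
    esm_pools = c(esm_0000_1000 = 10, esm_1000_2000 = 5, esm_2000_3000 = 3,
                  esm_3000_4000 = NA, esm_4000_5000 = NA, esm_5000_6000 = NA,
                  esm_6000_7000 = NA, esm_7000_8000 = NA),
    topsoil_pool = NA_real_, combined_pool = NA_real_,
    total_mass = 3000, provenance = "measured"
  ), class = "esm_profile")
  p <- pool_topsoil(prof)
  expect_equal(p$topsoil_pool, 18)
  expect_equal(p$combined_pool, 22)
  prof$forest_floor_pool <- 0
  expect_equal(pool_topsoil(prof)$combined_pool, 18)
  prof$esm_pools[3] <- NA
  expect_true(is.na(pool_topsoil(prof)$combined_pool))
})

test_that("malformed profiles error rather than interpolate silently", {
  overlap <- make_layers(top = c(0, 5), bottom = c(10, 20), bd = 1, soc = 10)
  expect_error(to_esm(overlap), "overlap")
  gap <- make_layers(top = c(0, 12), bottom = c(10, 20), bd = 1, soc = 10)
  expect_error(to_esm(gap), "gap")
  histosol <- make_layers(top = 0, bottom = 10, bd = 1, soc = 250)
  expect_error(to_esm(histosol), "Histosol")
})

test_that("harmonised profiles recover the generator's stand-level truth", {
  d <- simulate_dataset(tiny_config(n_sites = 6, seed = 7))
  prof <- harmonize_profiles(d$soil_layers)
  m <- merge(prof, d$truth, by = "stand_id")
  expect_equal(nrow(m), nrow(d$truth))
  expect_equal(m$ff_pool, m$ff_true)
  ok <- !is.na(m$topsoil_pool)
  expect_true(mean(ok) > 0.9)
  rel <- abs(m$topsoil_pool[ok] - m$topsoil_true[ok]) / m$topsoil_true[ok]
  expect_lt(stats::median(rel), 0.05)
  expect_lt(max(rel), 0.15)
  expect_gt(cor(m$topsoil_pool[ok], m$topsoil_true[ok]), 0.99)
})
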
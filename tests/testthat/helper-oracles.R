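# Shared fixtures and independent oracles used across test files.

# Small, fast generator configuration (the full-scale default is used
# only where a check's sample size demands it).
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_sites = 8, seed = 1L,
                   missingness = list(bd = 0, trait = 0, litterfall = 0))
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Build a soil-layer table with explicit per-layer values.
make_layers <- function(stand_id = "s1", kind = "mineral",
                        top, bottom, bd = NA_real_, soc = NA_real_,
                        som = NA_real_, pool = NA_real_,
                        clay = NA_real_, silt = NA_real_, sand = NA_real_) {
  data.frame(
    stand_id = stand_id, layer_kind = kind,
    top_depth_cm = top, bottom_depth_cm = bottom,
    bd_kg_l = bd, soc_mg_g = soc, som_mg_g = som, soc_pool_mg_ha = pool,
    clay_mg_g = clay, silt_mg_g = silt, sand_mg_g = sand
  )
}

# Brute-force oracle: 1-mm slab numerical integration of a
# piecewise-constant profile onto the ESM mass grid. Independent of
# the interpolation logic in to_esm().
slab_esm_oracle <- function(top, bottom, bd, soc, n_increments = 8,
                            slab_cm = 0.1) {
  z <- seq(0, max(bottom), by = slab_cm)
  mids <- z[-1] - slab_cm / 2
  idx <- findInterval(mids, top, rightmost.closed = TRUE)
  slab_mass <- 100 * bd[idx] * slab_cm
  slab_pool <- slab_mass * soc[idx] / 1000
  cum_mass <- c(0, cumsum(slab_mass))
  cum_pool <- c(0, cumsum(slab_pool))
  # a slab straddling a mass breakpoint is split pro rata (its
  # concentration is constant, so pool accrues linearly with mass)
  cum_at <- function(b) {
    j <- findInterval(b, cum_mass, rightmost.closed = TRUE)
    frac <- (b - cum_mass[j]) / slab_mass[j]
    cum_pool[j] + frac * slab_pool[j]
  }
  pools <- rep(NA_real_, n_increments)
  total <- cum_mass[length(cum_mass)]
  for (i in seq_len(n_increments)) {
    if (total < i * 1000) break
    pools[i] <- cum_at(i * 1000) - cum_at((i - 1) * 1000)
  }
  pools
}

# Layers of the generator's continuous exponential profile, measured
# on an arbitrary depth scheme: every reported value is the exact
# layer aggregate of the continuous truth.
profile_layers <- function(scheme, c_surface = 30, k = 4e-4,
                           coupling = list(bd_min = 0.8, bd_range = 0.7,
                                           soc_scale = 40),
                           stand_id = "s1") {
  mb <- soctraits:::.mass_at_depth(scheme, c_surface, k, coupling, dz = 0.02)
  pl <- analytic_layer_pool(c_surface, k, mb[-length(mb)], mb[-1])
  ml <- diff(mb)
  make_layers(stand_id = stand_id,
              top = scheme[-length(scheme)], bottom = scheme[-1],
              bd = ml / (100 * diff(scheme)), soc = 1000 * pl / ml)
}

# A small synthetic clade tree with controllable resolution.
toy_tree <- function(ages = NULL) {
  lineage <- data.frame(
    species = c("Aa x1", "Aa x2", "Ab y1", "Ba z1", "Ca q1", "Ca q2"),
    genus   = c("Aa", "Aa", "Ab", "Ba", "Ca", "Ca"),
    family  = c("Fam1", "Fam1", "Fam1", "Fam2", "Fam3", "Fam3"),
    order   = c("Ord1", "Ord1", "Ord1", "Ord1", "Ord2", "Ord2"),
    class   = c("ClA", "ClA", "ClA", "ClA", "ClB", "ClB")
  )
  if (is.null(ages)) {
    ages <- data.frame(
      clade = c("Spermatophyta", "ClA", "ClB", "Ord1", "Ord2",
                "Fam1", "Fam2", "Fam3", "Aa", "Ca"),
      crown_age_myr = c(350, 140, 273, 120, 200, 100, 90, 150, 20, 30)
    )
  }
  clade_tree(ages, lineage)
}
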
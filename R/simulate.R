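#' Configuration for the multi-site common-garden generator
#'
#' Defines the statistical structure of the synthetic datasets: sites
#' with climate/soil covariates, harshness and past land-use; 2-6
#' mono-specific stands per site with optional 50-50 two-species
#' mixtures; per-stand soil profiles (forest floor + mineral layers)
#' generated from a continuous exponential SOC-mass profile with a
#' monotone-decreasing BD(SOC) coupling; species traits from a
#' one-factor latent plant-economics-spectrum (PES) model; and log SOC
#' driven by a site baseline, a PES effect whose magnitude grows with
#' site harshness, and a standing-biomass effect.
#'
#' @param n_sites Number of sites.
#' @param stands_per_site Integer range (length 2) of mono-specific
#'   stands per site; minimum 2.
#' @param mixture_fraction Probability a site carries one 50-50
#'   two-species mixed stand.
#' @param trait_loading_vector Named per-trait loadings on the latent
#'   PES factor (positive pole = acquisitive; `amax` loads positively).
#' @param trait_noise_sd Species-level deviation from the rank-one
#'   trait structure (unitless).
#' @param beta_trait Effect of the species PES score on log SOC at
#'   harshness 0 (negative: acquisitive species store less SOC).
#' @param beta_biomass Effect of within-site centred log standing
#'   biomass on log SOC.
#' @param harshness_interaction Multiplier h of `beta_trait` with site
#'   harshness in \[0, 1\]: trait effect = `beta_trait * (1 + h *
#'   harshness)`.
#' @param overyield_effect Slope linking biomass overyielding of a
#'   mixture to its SOC overyielding.
#' @param soc_surface_mean Mean surface SOC concentration, mg C g^-1.
#' @param soc_site_sd,soc_resid_sd Log-scale SD of the site baseline
#'   and of the stand residual.
#' @param depth_decay_rate Exponential decay rate of SOC concentration
#'   per Mg soil ha^-1 of cumulative mass.
#' @param bd_soc_coupling List `bd_min`, `bd_range`, `soc_scale`: BD =
#'   `bd_min + bd_range * exp(-soc / soc_scale)` (kg L^-1); defaults
#'   keep mineral BD in the forest-soil range 0.8-1.5 kg L^-1.
#' @param missingness List of per-field missingness probabilities:
#'   `bd` (site-homogeneous: all of a site's stands lose BD together),
#'   `trait` (per-cell MCAR), `litterfall` (per stand).
#' @param seed Integer seed; a fixed seed gives identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 136,
                       stands_per_site = c(2, 5),
                       mixture_fraction = 0.14,
                       trait_loading_vector = c(
                         amax = 1.0, sla = 0.8, leaf_n = 0.9, leaf_p = 0.7,
                         srl = 0.6, leaf_size = 0.5, leaf_ca = 0.4,
                         leaf_c = -0.3, ldmc = -0.8, lignin = -0.6
                       ),
                       trait_noise_sd = 0.3,
                       beta_trait = -0.15,
                       beta_biomass = 0.10,
                       harshness_interaction = 1.0,
                       overyield_effect = 0.5,
                       soc_surface_mean = 25,
                       soc_site_sd = 0.4,
                       soc_resid_sd = 0.15,
                       depth_decay_rate = 4e-4,
                       bd_soc_coupling = list(bd_min = 0.8, bd_range = 0.7,
                                              soc_scale = 40),
                       missingness = list(bd = 0.3, trait = 0.1,
                                          litterfall = 0.1),
                       seed = 1L) {
  cfg <- as.list(environment())
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid config field '", field, "': ", msg)
  }
  chk(is.numeric(n_sites) && n_sites >= 1, "n_sites", "must be >= 1")
  chk(length(stands_per_site) == 2 && stands_per_site[1] >= 2 &&
        stands_per_site[2] >= stands_per_site[1],
      "stands_per_site", "must be a range with minimum >= 2")
  chk(mixture_fraction >= 0 && mixture_fraction <= 1,
      "mixture_fraction", "must be a probability in [0, 1]")
  chk(!is.null(names(trait_loading_vector)) &&
        all(nzchar(names(trait_loading_vector))),
      "trait_loading_vector", "must be a named numeric vector")
  chk(trait_noise_sd >= 0, "trait_noise_sd", "must be >= 0")
  chk(harshness_interaction >= 0 && harshness_interaction <= 1,
      "harshness_interaction", "must be in [0, 1]")
  chk(soc_surface_mean > 0 && soc_surface_mean < 200,
      "soc_surface_mean", "must be in (0, 200) mg g^-1")
  chk(depth_decay_rate > 0, "depth_decay_rate", "must be > 0")
  chk(all(c("bd_min", "bd_range", "soc_scale") %in% names(bd_soc_coupling)),
      "bd_soc_coupling", "needs bd_min, bd_range, soc_scale")
  for (nm in names(missingness)) {
    chk(missingness[[nm]] >= 0 && missingness[[nm]] <= 1,
        paste0("missingness$", nm), "must be a probability in [0, 1]")
  }
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be an integer")
  structure(cfg, class = "sim_config")
}

#' The generator's BD(SOC) coupling rule
#'
#' Monotone decreasing bulk density as a function of SOC concentration;
#' useful to inject into [pedotransfer_spec()] when testing recovery.
#'
#' @param config A [sim_config()].
#' @return `function(soc, ...) -> bd` (extra arguments ignored).
#' @export
bd_coupling_rule <- function(config) {
  cp <- config$bd_soc_coupling
  function(soc, ...) cp$bd_min + cp$bd_range * exp(-soc / cp$soc_scale)
}

#' Analytic SOC pool of a mass slice of the generator's profile
#'
#' The generator's continuous profile is `c(m) = c_surface *
#' exp(-k m)` (mg g^-1) against cumulative mineral mass m (Mg ha^-1);
#' the pool between masses `m1 < m2` is its exact integral.
#'
#' @param c_surface Surface SOC concentration, mg g^-1.
#' @param k Decay rate per Mg ha^-1.
#' @param m1,m2 Mass bounds, Mg ha^-1.
#' @return SOC pool, Mg C ha^-1.
#' @export
analytic_layer_pool <- function(c_surface, k, m1, m2) {
  c_surface * (exp(-k * m1) - exp(-k * m2)) / (1000 * k)
}

# cumulative mineral mass (Mg/ha) at depths (cm) under the BD(SOC(m))
# coupling, by fine-step Euler integration: dm/dz = 100 * BD(c(m))
.mass_at_depth <- function(depths_cm, c_surface, k, coupling, dz = 0.1) {
  zmax <- max(depths_cm)
  n <- ceiling(zmax / dz)
  m <- numeric(n + 1)
  for (i in seq_len(n)) {
    cm <- c_surface * exp(-k * m[i])
    bd <- coupling$bd_min + coupling$bd_range * exp(-cm / coupling$soc_scale)
    m[i + 1] <- m[i] + 100 * bd * dz
  }
  stats::approx(seq(0, n) * dz, m, xout = depths_cm)$y
}

.depth_schemes <- list(
  c(0, 10, 20, 30), c(0, 5, 15, 30), c(0, 15, 30), c(0, 10, 25, 40),
  c(0, 10, 20, 30, 45), c(0, 5, 10, 20, 30, 50)
)

#' Generate a synthetic multi-site dataset
#'
#' Draws a complete dataset with the structure the analysis pipeline
#' assumes, together with its generating truth. The truth tables exist
#' for validation only and are never consumed by pipeline stages.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset`: data frames `sites`, `stands`,
#'   `soil_layers`, `traits` (long observations), `mixtures`, `truth`
#'   (stand-level: expected log SOC multiplier, surface concentration,
#'   true pools, species PES score, generating betas), plus `species`
#'   (species-level latent PES) and the `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  lineage <- utils::read.csv(system.file("extdata", "lineage.csv",
                                         package = "soctraits"))
  pool <- lineage$species
  loads <- config$trait_loading_vector
  k <- config$depth_decay_rate
  cp <- config$bd_soc_coupling
  seed0 <- as.integer(config$seed) %% .Machine$integer.max

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  sub_seed <- function(offset) set.seed((seed0 + offset * 131L) %% .Machine$integer.max)

  ## species: latent PES factor and trait cells
  sub_seed(1L)
  pes <- stats::rnorm(length(pool))
  names(pes) <- pool
  base <- 5 + 2 * abs(loads)
  cells <- outer(pes, loads) +
    matrix(stats::rnorm(length(pool) * length(loads), 0, config$trait_noise_sd),
           length(pool), length(loads))
  cells <- sweep(cells, 2, base, "+")
  dimnames(cells) <- list(pool, names(loads))

  ## trait observations (long), with duplicate sources and MCAR gaps
  sub_seed(2L)
  obs <- list()
  srcs <- c("src_a", "src_b", "src_c", "src_d")
  for (sp in pool) {
    for (tr in names(loads)) {
      if (stats::runif(1) < config$missingness$trait) next
      n_obs <- 1 + stats::rbinom(1, 2, 0.4)
      obs[[length(obs) + 1]] <- data.frame(
        species = sp, trait = tr,
        value = cells[sp, tr] +
          stats::rnorm(n_obs, 0, 0.1 * config$trait_noise_sd),
        unit = "standardised",
        source_id = sample(srcs, n_obs, replace = TRUE)
      )
    }
  }
  traits <- do.call(rbind, obs)
  rownames(traits) <- NULL

  ## sites
  sub_seed(3L)
  ns <- config$n_sites
  harsh <- stats::runif(ns)
  f_climate <- pmin(pmax(1 - harsh + stats::rnorm(ns, 0, 0.05), 0), 1)
  sand <- stats::runif(ns, 100, 900)
  clay <- (1000 - sand) * stats::runif(ns, 0.3, 0.7)
  sites <- data.frame(
    site_id = sprintf("site_%03d", seq_len(ns)),
    harshness = harsh, f_climate = f_climate,
    mat_c = -5 + 25 * f_climate + stats::rnorm(ns, 0, 2),
    map_mm = 300 + 1500 * f_climate + stats::rnorm(ns, 0, 150),
    n_dep = pmax(1 + 18 * f_climate + stats::rnorm(ns, 0, 2), 0.1),
    sand_mg_g = sand, clay_mg_g = clay, silt_mg_g = 1000 - sand - clay,
    ph = stats::runif(ns, 3.5, 7.5),
    plu = sample(c("agriculture", "forest"), ns, TRUE, c(0.35, 0.65)),
    design_class = sample(
      c("common_garden", "comparative_plantation", "spontaneous",
        "heterogeneous"), ns, TRUE, c(0.5, 0.3, 0.15, 0.05)),
    n_blocks = sample(1:6, ns, TRUE),
    n_profiles = sample(1:12, ns, TRUE)
  )

  ## stands and true SOC profiles
  sub_seed(4L)
  stands <- list(); layers <- list(); truth <- list(); mixtures <- list()
  site_bd_missing <- stats::runif(ns) < config$missingness$bd
  for (s in seq_len(ns)) {
    n_st <- sample(config$stands_per_site[1]:config$stands_per_site[2], 1)
    spp <- sample(pool, n_st)
    biomass <- stats::rlnorm(n_st, log(150), 0.4)
    bnorm <- log(biomass) - mean(log(biomass))
    eff_trait <- config$beta_trait *
      (1 + config$harshness_interaction * harsh[s])
    site_b <- stats::rnorm(1, 0, config$soc_site_sd)
    mu <- site_b + eff_trait * pes[spp] + config$beta_biomass * bnorm
    eps <- stats::rnorm(n_st, 0, config$soc_resid_sd)
    c_surf <- pmin(config$soc_surface_mean * exp(mu + eps), 190)
    age <- pmax(round(stats::rlnorm(n_st, log(40), 0.35)), 11)
    litter <- 0.025 * biomass * exp(stats::rnorm(n_st, 0, 0.2))
    litter[stats::runif(n_st) < config$missingness$litterfall] <- NA
    stability <- exp(0.1 * pes[spp] + stats::rnorm(n_st, 0, 0.2))
    ids <- sprintf("%s_st%02d", sites$site_id[s], seq_len(n_st))

    topsoil_true <- ff_true <- numeric(n_st)
    for (j in seq_len(n_st)) {
      scheme <- .depth_schemes[[sample(length(.depth_schemes), 1)]]
      mass_b <- .mass_at_depth(scheme, c_surf[j], k, cp)
      pool_l <- analytic_layer_pool(c_surf[j], k, mass_b[-length(mass_b)],
                                    mass_b[-1])
      mass_l <- diff(mass_b)
      thick <- diff(scheme)
      has_ff <- stats::runif(1) < 0.9
      topsoil_true[j] <- analytic_layer_pool(c_surf[j], k, 0, 3000)
      ff_true[j] <- if (has_ff) {
        0.25 * topsoil_true[j] * exp(stats::rnorm(1, 0, 0.3))
      } else 0
      lay <- data.frame(
        stand_id = ids[j], layer_kind = "mineral",
        top_depth_cm = scheme[-length(scheme)], bottom_depth_cm = scheme[-1],
        bd_kg_l = mass_l / (100 * thick),
        soc_mg_g = 1000 * pool_l / mass_l,
        som_mg_g = NA_real_, soc_pool_mg_ha = NA_real_,
        clay_mg_g = clay[s], silt_mg_g = 1000 - sand[s] - clay[s],
        sand_mg_g = sand[s]
      )
      if (has_ff) {
        lay <- rbind(data.frame(
          stand_id = ids[j], layer_kind = "forest_floor",
          top_depth_cm = NA_real_, bottom_depth_cm = NA_real_,
          bd_kg_l = NA_real_, soc_mg_g = NA_real_, som_mg_g = NA_real_,
          soc_pool_mg_ha = ff_true[j],
          clay_mg_g = NA_real_, silt_mg_g = NA_real_, sand_mg_g = NA_real_
        ), lay)
      }
      if (site_bd_missing[s]) lay$bd_kg_l <- NA_real_
      layers[[length(layers) + 1]] <- lay
    }

    stands[[length(stands) + 1]] <- data.frame(
      stand_id = ids, site_id = sites$site_id[s], species = spp,
      age_yr = age, standing_biomass = biomass, litterfall = litter,
      soc_stability = stability
    )
    truth[[length(truth) + 1]] <- data.frame(
      stand_id = ids, site_id = sites$site_id[s], species = spp,
      pes_score = unname(pes[spp]), expected_log_soc = unname(mu),
      c_surface = c_surf, topsoil_true = topsoil_true, ff_true = ff_true,
      combined_true = topsoil_true + ff_true,
      beta_trait = config$beta_trait, beta_biomass = config$beta_biomass,
      harshness_interaction = config$harshness_interaction
    )

    if (stats::runif(1) < config$mixture_fraction && n_st >= 2) {
      ab <- sample(n_st, 2)
      comb <- topsoil_true[ab] + ff_true[ab]
      rr_b <- stats::rnorm(1, 0.1, 0.15)
      b_ab <- mean(biomass[ab]) * exp(rr_b)
      soc_ab <- mean(comb) *
        exp(config$overyield_effect * rr_b + stats::rnorm(1, 0, 0.1))
      mixtures[[length(mixtures) + 1]] <- data.frame(
        site_id = sites$site_id[s],
        stand_a = ids[ab[1]], stand_b = ids[ab[2]],
        species_a = spp[ab[1]], species_b = spp[ab[2]],
        soc_a = comb[1], soc_b = comb[2], soc_ab = soc_ab,
        biomass_a = biomass[ab[1]], biomass_b = biomass[ab[2]],
        biomass_ab = b_ab
      )
    }
  }

  empty_mix <- data.frame(
    site_id = character(0), stand_a = character(0), stand_b = character(0),
    species_a = character(0), species_b = character(0),
    soc_a = numeric(0), soc_b = numeric(0), soc_ab = numeric(0),
    biomass_a = numeric(0), biomass_b = numeric(0), biomass_ab = numeric(0)
  )
  out <- list(
    sites = sites,
    stands = do.call(rbind, stands),
    soil_layers = do.call(rbind, layers),
    traits = traits,
    mixtures = if (length(mixtures)) do.call(rbind, mixtures) else empty_mix,
    truth = do.call(rbind, truth),
    species = data.frame(species = pool, pes_score = unname(pes)),
    config = config
  )
  for (nm in c("stands", "soil_layers", "mixtures", "truth")) {
    rownames(out[[nm]]) <- NULL
  }
  class(out) <- "sim_dataset"
  out
}
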
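#' Assemble the stand-level analysis table from raw tables
#'
#' Runs the full harmonisation chain: soil layers onto the ESM grid
#' ([harmonize_profiles()]), study weights ([weigh_stands()]),
#' site-relative response ratios for the combined SOC pool and
#' standing biomass ([normalise_continuous()]), and the PES index from
#' the trait observations ([build_index()], expressed per stand as the
#' within-site centred species score). Site conditions are joined for
#' the interaction models. The generating truth is never consumed.
#'
#' @param dataset A `sim_dataset` (or any list with `sites`, `stands`,
#'   `soil_layers`, `traits` tables of the same schema).
#' @param spec A [pedotransfer_spec()] for missing bulk densities.
#' @param index Optional precomputed [build_index()] result; default
#'   builds the PES index (anchor `amax`) from `dataset$traits`.
#' @return Data frame with one row per stand that has a complete
#'   combined SOC pool: `stand_id`, `site_id`, `species`, `soc_rr`,
#'   `biomass_rr`, `pes_score`, `pes_rr` (site-centred), `f_climate`,
#'   `sand`, `ph`, `plu`, `w_data`.
#' @export
assemble_analysis_table <- function(dataset, spec = pedotransfer_spec(),
                                    index = NULL) {
  prof <- harmonize_profiles(dataset$soil_layers, spec)
  stands <- merge(dataset$stands,
                  prof[, c("stand_id", "ff_pool", "topsoil_pool",
                           "combined_pool")],
                  by = "stand_id", sort = FALSE)
  stands <- weigh_stands(stands, dataset$sites)
  rr_soc <- normalise_continuous(stands, "combined_pool")
  rr_bio <- normalise_continuous(stands, "standing_biomass")
  if (is.null(index)) {
    index <- build_index(trait_table(dataset$traits), anchor = "amax")
  }
  out <- merge(
    stands[, c("stand_id", "site_id", "species", "w_data")],
    data.frame(stand_id = rr_soc$stand_id, soc_rr = rr_soc$rr),
    by = "stand_id"
  )
  out <- merge(out, data.frame(stand_id = rr_bio$stand_id,
                               biomass_rr = rr_bio$rr),
               by = "stand_id", all.x = TRUE)
  out$pes_score <- unname(index$scores[out$species])
  out$pes_rr <- out$pes_score -
    stats::ave(out$pes_score, out$site_id, FUN = mean)
  sites <- dataset$sites
  out <- merge(out, data.frame(
    site_id = sites$site_id, f_climate = sites$f_climate,
    sand = sites$sand_mg_g, ph = sites$ph, plu = sites$plu
  ), by = "site_id", sort = FALSE)
  out[order(out$stand_id), ]
}

#' Estimate the generating trait and biomass effects from a dataset
#'
#' Estimator used for parameter-recovery validation: the PES index is
#' rescaled to unit variance across species (the latent-factor scale),
#' and normalised SOC is regressed (weighted by `w_data`) on the
#' site-centred unit-scale PES score, its interaction with the climate
#' favourability covariate, and normalised biomass. Because site
#' harshness is `1 - f_climate` (up to noise), the trait effect at
#' harshness zero -- the generating `beta_trait` -- is the PES main
#' effect plus the PES-by-climate interaction evaluated at
#' `f_climate = 1`.
#'
#' @param dataset A `sim_dataset` (truth tables are not consumed).
#' @param index Optional precomputed [build_index()] result.
#' @param table Optional precomputed [assemble_analysis_table()].
#' @return List: `beta_trait_hat`, `beta_biomass_hat`,
#'   `trait_climate_interaction`, `fit`.
#' @export
recover_generating_effects <- function(dataset, index = NULL, table = NULL) {
  if (is.null(table)) table <- assemble_analysis_table(dataset, index = index)
  sp <- table[!duplicated(table$species), c("species", "pes_score")]
  scale_u <- stats::sd(sp$pes_score)
  table$pes_u <- table$pes_rr / scale_u
  fit <- stats::lm(soc_rr ~ pes_u + pes_u:f_climate + biomass_rr,
                   data = table, weights = w_data)
  b <- stats::coef(fit)
  list(
    beta_trait_hat = unname(b["pes_u"] + b["pes_u:f_climate"]),
    beta_biomass_hat = unname(b["biomass_rr"]),
    trait_climate_interaction = unname(b["pes_u:f_climate"]),
    fit = fit
  )
}
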
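#' Convert soil organic matter to soil organic carbon concentration
#'
#' Applies the fixed conversion SOC = SOM / 2.0.
#'
#' @param som_concentration Numeric vector, SOM in mg g^-1 (> 0).
#' @return SOC concentration in mg C g^-1.
#' @export
#' @examples
#' convert_som(10) # 5
convert_som <- function(som_concentration) {
  if (any(!is.finite(som_concentration) | som_concentration <= 0)) {
    stop("SOM concentration must be strictly positive")
  }
  som_concentration / 2.0
}

#' Pedo-transfer specification for bulk-density estimation
#'
#' Bundles the rules used to fill missing bulk density (BD) values.
#' Mineral layers with SOC concentration at or below `soc_threshold`
#' (20 mg g^-1) use the texture-based rule; richer layers use the
#' SOC-only rule; layers carrying only a SOC pool use a regression
#' fitted from complete records ([fit_pool_fallback()]); forest-floor
#' layers use a fixed constant (default 0.1346 kg L^-1).
#'
#' The default functional forms are generic monotone-decreasing
#' literature-style pedo-transfer shapes and are intended to be replaced
#' by coefficients calibrated for the data at hand; they are
#' configuration, not fixed constants of the method (unlike the
#' threshold and the forest-floor constant, which are).
#'
#' @param rule_low_soc `function(soc, clay, silt, sand) -> bd` used when
#'   SOC <= `soc_threshold` mg g^-1 (texture in mg g^-1).
#' @param rule_high_soc `function(soc) -> bd` used when SOC > threshold.
#' @param forest_floor_bd Constant BD for forest-floor layers, kg L^-1.
#' @param pool_fallback Optional object from [fit_pool_fallback()].
#' @param soc_threshold Dispatch threshold in mg g^-1; fixed default 20.
#' @return An object of class `pedotransfer_spec`.
#' @export
pedotransfer_spec <- function(rule_low_soc = NULL,
                              rule_high_soc = NULL,
                              forest_floor_bd = 0.1346,
                              pool_fallback = NULL,
                              soc_threshold = 20) {
  if (is.null(rule_low_soc)) {
    # generic texture + SOC linear form; replace with calibrated coefficients
    rule_low_soc <- function(soc, clay, silt, sand) {
      bd <- 1.45 + 0.00045 * sand - 0.0006 * clay - 0.006 * soc
      pmin(pmax(bd, 0.05), 2.5)
    }
  }
  if (is.null(rule_high_soc)) {
    # two-component mixing model on SOM% (= 2 * SOC / 10)
    rule_high_soc <- function(soc) {
      som_pct <- soc / 5
      bd <- 100 / (som_pct / 0.244 + (100 - som_pct) / 1.64)
      pmin(pmax(bd, 0.05), 2.5)
    }
  }
  structure(
    list(
      rule_low_soc = rule_low_soc, rule_high_soc = rule_high_soc,
      forest_floor_bd = forest_floor_bd, pool_fallback = pool_fallback,
      soc_threshold = soc_threshold
    ),
    class = "pedotransfer_spec"
  )
}

#' Fit the pool-based bulk-density fallback regression
#'
#' For layers reporting a SOC pool but no concentration, BD is predicted
#' from the pool through a log-log linear regression fitted on records
#' with both values known. The fitted mapping must be monotone
#' decreasing; a non-negative slope is flagged degenerate.
#'
#' @param layers Data frame with positive columns `bd_kg_l` and
#'   `soc_pool_mg_ha` (>= 10 complete rows).
#' @return Object of class `pool_fallback` with elements `fit`, `n`,
#'   `r_squared`, `slope`, `degenerate`; use [predict_pool_fallback()].
#' @export
fit_pool_fallback <- function(layers) {
  ok <- stats::complete.cases(layers[, c("bd_kg_l", "soc_pool_mg_ha")])
  d <- layers[ok, ]
  if (nrow(d) < 10) stop("need >= 10 complete (BD, SOC pool) rows, got ", nrow(d))
  if (any(d$bd_kg_l <= 0) || any(d$soc_pool_mg_ha <= 0)) {
    stop("BD and SOC pool must be strictly positive")
  }
  fit <- stats::lm(log(bd_kg_l) ~ log(soc_pool_mg_ha), data = d)
  slope <- unname(stats::coef(fit)[2])
  structure(
    list(
      fit = fit, n = nrow(d), r_squared = summary(fit)$r.squared,
      slope = slope, degenerate = !is.finite(slope) || slope >= -1e-12
    ),
    class = "pool_fallback"
  )
}

#' Predict bulk density from a SOC pool
#' @param object A `pool_fallback` object.
#' @param soc_pool SOC pool values, Mg C ha^-1.
#' @return Predicted BD, kg L^-1.
#' @export
predict_pool_fallback <- function(object, soc_pool) {
  stopifnot(inherits(object, "pool_fallback"))
  unname(exp(stats::predict(object$fit,
    newdata = data.frame(soc_pool_mg_ha = soc_pool)
  )))
}

#' Estimate bulk density for a soil layer
#'
#' Dispatches on layer kind and data availability: measured BD is kept;
#' forest floors get the fixed constant; mineral layers with a SOC
#' concentration use the low- or high-SOC pedo-transfer rule (threshold
#' 20 mg g^-1); layers with only a SOC pool use the pool fallback.
#'
#' @param layer One-row data frame (or list) with fields `layer_kind`,
#'   `bd_kg_l`, `soc_mg_g`, `som_mg_g`, `soc_pool_mg_ha`, `clay_mg_g`,
#'   `silt_mg_g`, `sand_mg_g` (missing as `NA`).
#' @param spec A [pedotransfer_spec()].
#' @return List with `bd` (kg L^-1) and `provenance` (one of
#'   `"measured"`, `"bd_estimated"`).
#' @export
estimate_bd <- function(layer, spec) {
  stopifnot(inherits(spec, "pedotransfer_spec"))
  g <- function(nm) {
    v <- layer[[nm]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[1])
  }
  bd <- g("bd_kg_l")
  if (is.finite(bd)) return(list(bd = bd, provenance = "measured"))
  if (identical(as.character(layer[["layer_kind"]][1]), "forest_floor")) {
    return(list(bd = spec$forest_floor_bd, provenance = "bd_estimated"))
  }
  soc <- g("soc_mg_g")
  if (!is.finite(soc) && is.finite(g("som_mg_g"))) soc <- convert_som(g("som_mg_g"))
  if (is.finite(soc)) {
    bd <- if (soc <= spec$soc_threshold) {
      spec$rule_low_soc(soc, g("clay_mg_g"), g("silt_mg_g"), g("sand_mg_g"))
    } else {
      spec$rule_high_soc(soc)
    }
    return(list(bd = bd, provenance = "bd_estimated"))
  }
  if (is.finite(g("soc_pool_mg_ha")) && !is.null(spec$pool_fallback)) {
    return(list(
      bd = predict_pool_fallback(spec$pool_fallback, g("soc_pool_mg_ha")),
      provenance = "bd_estimated"
    ))
  }
  stop(
    "BD unrecoverable for stand ",
    if (!is.null(layer[["stand_id"]])) layer[["stand_id"]][1] else "<unknown>",
    ": no measured BD, concentration, or usable pool fallback"
  )
}

# Mean relative SOC distribution over 1000 Mg ha^-1 increments.
# The first three fractions are the fixed 45/30/25 profile; deeper
# increments extend it with the geometric decay fitted to those three.
.esm_fractions <- function(n_increments) {
  base <- c(0.45, 0.30, 0.25)
  if (n_increments <= 3) return(base[seq_len(n_increments)])
  fit <- stats::lm(log(base) ~ seq_along(base))
  ratio <- exp(stats::coef(fit)[2])
  extra <- base[3] * ratio^seq_len(n_increments - 3)
  c(base, extra)
}

#' Disaggregate a thick-layer SOC pool into 1000 Mg ha^-1 increments
#'
#' Splits a single pooled SOC value measured over a soil mass of
#' `mass` Mg ha^-1 into per-increment pools using the mean relative
#' distribution of SOC with mass: 45%, 30% and 25% for the first three
#' increments (renormalised when fewer are covered; extended by the
#' fitted geometric decay beyond 3000 Mg ha^-1, flagged low-confidence).
#'
#' @param pool Total SOC pool, Mg C ha^-1.
#' @param mass Soil mass covered, a positive multiple of 1000 Mg ha^-1.
#' @return Numeric vector of per-increment pools summing to `pool`.
#' @export
#' @examples
#' disaggregate_thick_layer(20, 3000) # 9, 6, 5
disaggregate_thick_layer <- function(pool, mass) {
  stopifnot(pool >= 0, mass > 0)
  k <- mass / 1000
  if (abs(k - round(k)) > 1e-9) stop("mass must be a multiple of 1000 Mg ha^-1")
  k <- as.integer(round(k))
  f <- .esm_fractions(k)
  pools <- pool * f / sum(f)
  names(pools) <- sprintf("esm_%04d_%04d", (seq_len(k) - 1) * 1000, seq_len(k) * 1000)
  pools
}

#' Harmonise one stand's soil layers onto the equivalent-soil-mass grid
#'
#' Converts measured mineral layers (depth, BD, SOC concentration or
#' pool) into SOC pools in successive soil-mass increments of
#' 1000 Mg ha^-1 ("ESM layers"), by interpolating cumulative SOC
#' against cumulative dry soil mass. Pools are reported only down to
#' the deepest measured mass (never extrapolated); the forest floor is
#' kept outside the mineral-mass ledger. A stand reporting a single
#' thick mineral layer is split by the mean relative SOC distribution
#' (see [disaggregate_thick_layer()]).
#'
#' @param layers Data frame of one stand's layers with columns
#'   `stand_id`, `layer_kind` (`"forest_floor"`/`"mineral"`),
#'   `top_depth_cm`, `bottom_depth_cm`, `bd_kg_l`, `soc_mg_g`,
#'   `som_mg_g`, `soc_pool_mg_ha`, `clay_mg_g`, `silt_mg_g`,
#'   `sand_mg_g` (missing values `NA`).
#' @param spec A [pedotransfer_spec()].
#' @param n_increments Deepest ESM increment to report (default 8,
#'   i.e. down to ESM.7000-8000).
#' @param gap_tol Largest tolerated gap between successive mineral
#'   layers, cm (default 0.5); larger gaps are an error.
#' @param interpolation `"linear"` (default) or `"monotone"` (Hyman
#'   cubic) interpolation of the cumulative SOC-vs-mass curve.
#' @return List of class `esm_profile`: `stand_id`, `forest_floor_pool`,
#'   `esm_pools` (named vector, `NA` beyond the measured mass),
#'   `topsoil_pool`, `combined_pool`, `total_mass`, `provenance`.
#' @export
to_esm <- function(layers, spec = pedotransfer_spec(), n_increments = 8,
                   gap_tol = 0.5, interpolation = c("linear", "monotone")) {
  interpolation <- match.arg(interpolation)
  stand_id <- layers$stand_id[1]
  prov <- character(0)

  ff <- layers[layers$layer_kind == "forest_floor", , drop = FALSE]
  min_l <- layers[layers$layer_kind == "mineral", , drop = FALSE]
  if (nrow(min_l) == 0) stop("stand ", stand_id, ": no mineral layer")

  ff_pool <- 0
  if (nrow(ff) > 0) {
    for (i in seq_len(nrow(ff))) {
      row <- ff[i, ]
      if (is.finite(row$soc_pool_mg_ha)) {
        ff_pool <- ff_pool + row$soc_pool_mg_ha
      } else {
        soc <- row$soc_mg_g
        if (!is.finite(soc) && is.finite(row$som_mg_g)) {
          soc <- convert_som(row$som_mg_g)
          prov <- union(prov, "som_converted")
        }
        thick <- row$bottom_depth_cm - row$top_depth_cm
        if (!is.finite(soc) || !is.finite(thick)) {
          stop("stand ", stand_id, ": forest floor needs a pool, or concentration + depths")
        }
        bd <- estimate_bd(row, spec)
        if (bd$provenance != "measured") prov <- union(prov, "bd_estimated")
        ff_pool <- ff_pool + 100 * bd$bd * thick * soc / 1000
      }
    }
  }

  min_l <- min_l[order(min_l$top_depth_cm), , drop = FALSE]
  if (any(min_l$bottom_depth_cm <= min_l$top_depth_cm)) {
    stop("stand ", stand_id, ": mineral layer with non-positive thickness")
  }
  if (nrow(min_l) > 1) {
    gaps <- min_l$top_depth_cm[-1] - min_l$bottom_depth_cm[-nrow(min_l)]
    if (any(gaps < -1e-9)) stop("stand ", stand_id, ": overlapping mineral layers")
    if (any(gaps > gap_tol)) {
      stop("stand ", stand_id, ": gap of ", signif(max(gaps), 3),
           " cm between mineral layers exceeds tolerance ", gap_tol, " cm")
    }
  }
  if (min_l$top_depth_cm[1] > gap_tol) {
    stop("stand ", stand_id, ": mineral layers do not start at the surface")
  }

  n <- nrow(min_l)
  mass <- pool <- numeric(n)
  for (i in seq_len(n)) {
    row <- min_l[i, ]
    soc <- row$soc_mg_g
    if (!is.finite(soc) && is.finite(row$som_mg_g)) {
      soc <- convert_som(row$som_mg_g)
      prov <- union(prov, "som_converted")
    }
    if (is.finite(soc) && soc >= 200) {
      stop("stand ", stand_id, ": SOC concentration >= 200 mg g^-1 (Histosol exclusion)")
    }
    bd <- estimate_bd(`if`(is.finite(soc) && !is.finite(row$soc_mg_g),
                           within(row, soc_mg_g <- soc), row), spec)
    if (bd$provenance != "measured") prov <- union(prov, "bd_estimated")
    thick <- row$bottom_depth_cm - row$top_depth_cm
    mass[i] <- 100 * bd$bd * thick          # Mg soil ha^-1
    pool[i] <- if (is.finite(soc)) {
      mass[i] * soc / 1000                  # Mg C ha^-1
    } else if (is.finite(row$soc_pool_mg_ha)) {
      row$soc_pool_mg_ha
    } else {
      stop("stand ", stand_id, ": mineral layer with no SOC information")
    }
  }

  total_mass <- sum(mass)
  breaks <- seq_len(n_increments) * 1000
  esm <- rep(NA_real_, n_increments)
  names(esm) <- sprintf("esm_%04d_%04d",
                        (seq_len(n_increments) - 1) * 1000, breaks)

  if (n == 1 && total_mass > 1000 + 1e-9) {
    # single thick layer: mean relative-distribution device
    k_full <- floor(total_mass / 1000 + 1e-9)
    f <- .esm_fractions(ceiling(total_mass / 1000))
    cumf <- c(0, cumsum(f))
    fr_at <- stats::approx(
      x = seq(0, length(f)) * 1000, y = cumf,
      xout = pmin(breaks, total_mass), rule = 2
    )$y
    fr_tot <- stats::approx(seq(0, length(f)) * 1000, cumf, xout = total_mass)$y
    cum_at <- pool * fr_at / fr_tot
    full <- seq_len(min(k_full, n_increments))
    esm[full] <- diff(c(0, cum_at))[full]
    prov <- union(prov, "disaggregated")
  } else {
    cum_mass <- c(0, cumsum(mass))
    cum_pool <- c(0, cumsum(pool))
    interp <- if (interpolation == "linear") {
      stats::approxfun(cum_mass, cum_pool)
    } else {
      stats::splinefun(cum_mass, cum_pool, method = "hyman")
    }
    reachable <- breaks <= total_mass + 1e-9
    if (any(reachable)) {
      cum_at <- interp(pmin(breaks[reachable], total_mass))
      esm[which(reachable)] <- diff(c(0, cum_at))
    }
  }
  prov <- union(prov, "measured")

  structure(
    list(
      stand_id = stand_id, forest_floor_pool = ff_pool, esm_pools = esm,
      topsoil_pool = NA_real_, combined_pool = NA_real_,
      total_mass = total_mass, provenance = sort(prov)
    ),
    class = "esm_profile"
  ) |> pool_topsoil()
}

#' Pool the topsoil and combined SOC layers of an ESM profile
#'
#' Topsoil is the sum of the first three ESM increments
#' (ESM.0000-3000); the combined pool adds the forest floor. If any of
#' the three increments is missing the pooled values are flagged
#' missing rather than extrapolated.
#'
#' @param profile An `esm_profile` from [to_esm()].
#' @return The profile with `topsoil_pool` and `combined_pool` filled.
#' @export
pool_topsoil <- function(profile) {
  stopifnot(inherits(profile, "esm_profile"))
  top3 <- profile$esm_pools[1:3]
  if (anyNA(top3)) {
    profile$topsoil_pool <- NA_real_
    profile$combined_pool <- NA_real_
  } else {
    profile$topsoil_pool <- sum(top3)
    profile$combined_pool <- profile$topsoil_pool + profile$forest_floor_pool
  }
  profile
}

#' Harmonise a full soil-layer table onto the ESM grid
#'
#' Applies [to_esm()] per stand and binds the results into one table.
#'
#' @param soil_layers Soil-layer table for many stands (see [to_esm()]).
#' @param spec A [pedotransfer_spec()].
#' @param ... Passed to [to_esm()].
#' @return Data frame with one row per stand: `stand_id`, `ff_pool`,
#'   the eight `esm_*` columns, `topsoil_pool`, `combined_pool`,
#'   `provenance` (semicolon-joined flags).
#' @export
harmonize_profiles <- function(soil_layers, spec = pedotransfer_spec(), ...) {
  profs <- lapply(
    split(soil_layers, soil_layers$stand_id),
    to_esm, spec = spec, ...
  )
  out <- do.call(rbind, lapply(profs, function(p) {
    data.frame(
      stand_id = p$stand_id, ff_pool = p$forest_floor_pool,
      as.list(p$esm_pools), topsoil_pool = p$topsoil_pool,
      combined_pool = p$combined_pool,
      provenance = paste(p$provenance, collapse = ";")
    )
  }))
  rownames(out) <- NULL
  out
}
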
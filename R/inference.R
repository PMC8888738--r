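#' Rank SOC drivers by random-forest permutation importance
#'
#' Fits an ensemble of regression trees and ranks predictors by the
#' mean percentage increase in out-of-bag MSE when each predictor is
#' permuted (%IncMSE). The sign of each predictor's marginal
#' association is taken from a univariate weighted least-squares slope.
#'
#' @param response Numeric response vector (site-normalised values).
#' @param predictors Data frame of numeric predictors.
#' @param weights Optional case weights (used for the direction slopes;
#'   the forest itself is unweighted).
#' @param n_trees Number of trees (default 500).
#' @param mtry Predictors tried per split (default `ceiling(p/3)`).
#' @param seed RNG seed for the forest.
#' @return Data frame sorted by decreasing importance: `predictor`,
#'   `importance_pct_inc_mse`, `direction` (+1/-1), `constant` (flag
#'   for zero-variance predictors, importance forced to 0).
#' @export
rank_drivers <- function(response, predictors, weights = NULL,
                         n_trees = 500, mtry = NULL, seed = 1L) {
  stopifnot(length(response) >= 30)
  p <- ncol(predictors)
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  const <- vapply(predictors, function(v) stats::sd(v) < .Machine$double.eps^0.5,
                  logical(1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = predictors, y = response, ntree = n_trees, mtry = mtry,
    importance = TRUE
  )
  imp <- randomForest::importance(rf, type = 1)[, 1]
  imp[const[names(imp)]] <- 0
  dir <- vapply(names(imp), function(nm) {
    if (const[nm]) return(0)
    fit <- stats::lm(response ~ predictors[[nm]], weights = weights)
    sign(unname(stats::coef(fit)[2]))
  }, numeric(1))
  out <- data.frame(
    predictor = names(imp), importance_pct_inc_mse = unname(imp),
    direction = unname(dir), constant = unname(const[names(imp)])
  )
  out[order(-out$importance_pct_inc_mse), ]
}

# Greedy forward selection by AIC over an explicit candidate-term list.
# Unlike stats::step(), interaction terms may enter without their
# marginal main effects (site conditions act only through interactions).
forward_aic <- function(data, response, candidates, weights = NULL) {
  data$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  current <- paste(response, "~ 1")
  fit <- stats::lm(stats::as.formula(current), data = data, weights = .w)
  path <- data.frame(term = "<null>", aic = stats::AIC(fit))
  selected <- character(0)
  remaining <- candidates
  repeat {
    aics <- vapply(remaining, function(tm) {
      f <- stats::as.formula(paste(current, "+", tm))
      cand <- try(stats::lm(f, data = data, weights = .w), silent = TRUE)
      if (inherits(cand, "try-error")) Inf else stats::AIC(cand)
    }, numeric(1))
    if (length(aics) == 0 || min(aics) >= stats::AIC(fit) - 1e-8) break
    best <- names(which.min(aics))
    current <- paste(current, "+", best)
    fit <- stats::lm(stats::as.formula(current), data = data, weights = .w)
    path <- rbind(path, data.frame(term = best, aic = stats::AIC(fit)))
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  list(fit = fit, selected = selected, aic_path = path,
       formula = current)
}

#' Weighted trait-by-biomass-by-site interaction model of normalised SOC
#'
#' Forward-AIC selection of the model
#' `SOC ~ (Trait x Biomass) + {(Trait + Biomass):(f_climate + Sand + pH
#' [+ PLU])}`: trait and biomass main effects, their interaction, and
#' interactions of each with the site conditions. Site conditions
#' never enter as direct effects (site-normalised responses average to
#' ~0 within a site, so site-constant covariates carry no main-effect
#' information).
#'
#' @param data Data frame holding all columns.
#' @param response Name of the normalised SOC column.
#' @param trait,biomass Names of the normalised trait and biomass
#'   columns.
#' @param conditions Character vector of site-condition columns
#'   (default `c("f_climate", "sand", "ph")`).
#' @param weights Optional case-weight column name (e.g. `"w_data"`).
#' @param include_plu Add `"plu"` to the conditions (default TRUE if
#'   the column exists).
#' @param force_full Skip selection and fit the full model.
#' @param random_site Refit the selected fixed-effects structure as a
#'   mixed model with a site random intercept (`lme4`); the result is
#'   attached as `mixed_fit`. Off by default — forward-AIC WLS is the
#'   canonical path.
#' @return List of class `soc_model`: `fit`, `selected`, `aic_path`,
#'   `coefficients`, `adj_r_squared`, `variance_partition` (sequential
#'   sums-of-squares shares of the explained variance), and
#'   `mixed_fit` when `random_site = TRUE`.
#' @export
fit_interaction_model <- function(data, response, trait, biomass,
                                  conditions = c("f_climate", "sand", "ph"),
                                  weights = NULL,
                                  include_plu = "plu" %in% names(data),
                                  force_full = FALSE,
                                  random_site = FALSE) {
  if (include_plu) conditions <- union(conditions, "plu")
  need <- c(response, trait, biomass, conditions)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  w <- if (!is.null(weights)) data[[weights]] else NULL
  keep <- stats::complete.cases(data[, need])
  data <- data[keep, ]
  if (!is.null(w)) w <- w[keep]
  candidates <- c(
    trait, biomass, paste0(trait, ":", biomass),
    paste0(trait, ":", conditions), paste0(biomass, ":", conditions)
  )
  sel <- if (force_full) {
    f <- stats::as.formula(paste(response, "~", paste(candidates, collapse = " + ")))
    data$.w <- if (is.null(w)) rep(1, nrow(data)) else w
    fit <- stats::lm(f, data = data, weights = .w)
    list(fit = fit, selected = candidates,
         aic_path = data.frame(term = "<full>", aic = stats::AIC(fit)),
         formula = deparse(f))
  } else {
    forward_aic(data, response, candidates, weights = w)
  }
  fit <- sel$fit
  if (any(is.na(stats::coef(fit)))) {
    warning("aliased terms dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  }
  sm <- summary(fit)
  av <- try(stats::anova(fit), silent = TRUE)
  vp <- NULL
  if (!inherits(av, "try-error") && nrow(av) > 1) {
    ss <- av[rownames(av) != "Residuals", "Sum Sq"]
    vp <- stats::setNames(ss / sum(av[, "Sum Sq"]),
                          rownames(av)[rownames(av) != "Residuals"])
  }
  mixed <- NULL
  if (random_site) {
    if (!"site_id" %in% names(data)) stop("random_site needs a site_id column")
    terms <- if (length(sel$selected)) paste(sel$selected, collapse = " + ")
             else "1"
    mf <- stats::as.formula(paste(response, "~", terms, "+ (1 | site_id)"))
    data$.w <- if (is.null(w)) rep(1, nrow(data)) else w
    mixed <- lme4::lmer(mf, data = data, weights = .w, REML = TRUE)
  }
  structure(
    list(fit = fit, selected = sel$selected, aic_path = sel$aic_path,
         formula = sel$formula,
         coefficients = sm$coefficients,
         adj_r_squared = sm$adj.r.squared,
         variance_partition = vp,
         mixed_fit = mixed,
         n = nrow(data)),
    class = "soc_model"
  )
}

#' Two-class contrast test with a normality gate
#'
#' Per-site contrasts (one value per site) are tested against zero:
#' a Shapiro-Wilk test at alpha = 0.05 selects a two-sided one-sample
#' t test (normal) or a two-sided Wilcoxon signed-rank test
#' (non-normal).
#'
#' @param contrasts Numeric vector of per-site contrasts (>= 3).
#' @param alpha_normality Gate level (default 0.05).
#' @return List: `method` (`"t"`, `"wilcoxon"` or `"degenerate"`),
#'   `statistic`, `p`, `n`, `shapiro_p`.
#' @export
two_class_contrast <- function(contrasts, alpha_normality = 0.05) {
  x <- contrasts[is.finite(contrasts)]
  n <- length(x)
  if (n < 3) stop("need >= 3 per-site contrasts, got ", n)
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    return(list(method = "degenerate", statistic = NA_real_, p = NA_real_,
                n = n, shapiro_p = NA_real_))
  }
  sw <- stats::shapiro.test(x)
  if (sw$p.value >= alpha_normality) {
    tt <- stats::t.test(x, mu = 0)
    list(method = "t", statistic = unname(tt$statistic), p = tt$p.value,
         n = n, shapiro_p = sw$p.value)
  } else {
    wt <- stats::wilcox.test(x, mu = 0, exact = FALSE)
    list(method = "wilcoxon", statistic = unname(wt$statistic),
         p = wt$p.value, n = n, shapiro_p = sw$p.value)
  }
}

#' Bonferroni correction within a family of contrasts
#'
#' @param p_values Numeric vector of raw p values from one reported
#'   family of two-class contrasts.
#' @return Adjusted p values (`stats::p.adjust`, method "bonferroni").
#' @export
adjust_contrast_family <- function(p_values) {
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Correct shallow-profile validation values to the full-topsoil scale
#'
#' Normalised SOC from validation sites measured only down to
#' ESM.0000-1000 or ESM.0000-2000 (plus forest floor) runs higher than
#' the calibration scale (forest floor + ESM.0000-3000); the fixed
#' multiplicative corrections 1.115 and 1.064 bring the two cases onto
#' the calibration scale.
#'
#' @param rr Normalised SOC values.
#' @param case `"ff_esm_0000_1000"` or `"ff_esm_0000_2000"`.
#' @return Corrected values; attribute `correction_factor`.
#' @export
#' @examples
#' apply_validation_correction(0.2, "ff_esm_0000_1000") # 0.223
apply_validation_correction <- function(rr,
                                        case = c("ff_esm_0000_1000",
                                                 "ff_esm_0000_2000")) {
  case <- match.arg(case)
  f <- switch(case, ff_esm_0000_1000 = 1.115, ff_esm_0000_2000 = 1.064)
  out <- rr * f
  attr(out, "correction_factor") <- f
  out
}

#' Collinearity screen of site covariates
#'
#' Detects blocks of mutually correlated covariates (graph components
#' of |r| >= `threshold`) and retains one representative per block:
#' the conventional representative when its name is in the block
#' (`sand` for texture, `f_climate` for climate), otherwise the
#' covariate with the highest absolute loading on the block's first
#' principal component. Singleton covariates are always retained.
#'
#' @param covariates Data frame of numeric site covariates (>= 2).
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @param preferred Named preferences, block-member -> retained name;
#'   default `c("sand", "f_climate")` retained when present in a block.
#' @return List: `retained` (character), `blocks` (list of character),
#'   `correlations` (matrix), `loadings` (per-block named axis-1
#'   loadings).
#' @export
collinearity_screen <- function(covariates, threshold = 0.7,
                                preferred = c("sand", "f_climate")) {
  stopifnot(ncol(covariates) >= 2)
  cc <- stats::cor(covariates, use = "pairwise.complete.obs")
  p <- ncol(cc)
  adj <- abs(cc) >= threshold
  # connected components by label propagation
  comp <- seq_len(p)
  repeat {
    new <- comp
    for (i in seq_len(p)) new[i] <- min(comp[adj[i, ]])
    if (identical(new, comp)) break
    comp <- new
  }
  nms <- colnames(cc)
  blocks <- split(nms, comp)
  retained <- character(0)
  loadings <- list()
  for (b in blocks) {
    if (length(b) == 1) {
      retained <- c(retained, b)
      next
    }
    pref <- intersect(preferred, b)
    pca <- stats::prcomp(covariates[stats::complete.cases(covariates[, b]), b],
                         center = TRUE, scale. = TRUE)
    loadings[[paste(b, collapse = "+")]] <- pca$rotation[, 1]
    retained <- c(retained,
                  if (length(pref)) pref[1]
                  else b[which.max(abs(pca$rotation[, 1]))])
  }
  list(retained = unname(retained), blocks = unname(blocks),
       correlations = cc, loadings = loadings)
}
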
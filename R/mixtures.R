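#' Mixture overyielding index
#'
#' `ln(AB / mean(A, B))` for a 50-50 two-species mixed stand AB and its
#' mono-specific component stands A and B at the same site. Positive
#' values mean the mixture outperforms the average of its components.
#'
#' @param a,b Values for the two mono-specific stands (> 0).
#' @param ab Value for the mixed stand (> 0).
#' @return Log response ratio (unitless), vectorised.
#' @export
#' @examples
#' overyielding(10, 10, 20) # log(2)
overyielding <- function(a, b, ab) {
  .check_triplet(a, b, ab)
  log(ab / ((a + b) / 2))
}

#' Transgressive overyielding index
#'
#' `ln(AB / max(A, B))`: positive values mean the mixture outperforms
#' the best of its mono-specific component stands. Always less than or
#' equal to [overyielding()].
#'
#' @inheritParams overyielding
#' @return Log response ratio (unitless), vectorised.
#' @export
transgressive_overyielding <- function(a, b, ab) {
  .check_triplet(a, b, ab)
  log(ab / pmax(a, b))
}

.check_triplet <- function(a, b, ab) {
  if (any(!is.finite(a) | !is.finite(b) | !is.finite(ab)) ||
      any(a <= 0 | b <= 0 | ab <= 0)) {
    stop("mixture triplet values must be finite and strictly positive")
  }
  invisible(NULL)
}

#' Compute overyielding indices for a mixture table
#'
#' @param mixtures Data frame with columns `site_id`, `species_a`,
#'   `species_b`, and per-variable triplets `<var>_a`, `<var>_b`,
#'   `<var>_ab` for each name in `variables`.
#' @param variables Variable stems, default `c("soc", "biomass")`.
#' @return `mixtures` with `rr_overyielding_<var>` and
#'   `rr_transgressive_<var>` columns appended.
#' @export
overyielding_table <- function(mixtures, variables = c("soc", "biomass")) {
  for (v in variables) {
    a <- mixtures[[paste0(v, "_a")]]
    b <- mixtures[[paste0(v, "_b")]]
    ab <- mixtures[[paste0(v, "_ab")]]
    if (is.null(a) || is.null(b) || is.null(ab)) {
      stop("missing triplet columns for variable '", v, "'")
    }
    mixtures[[paste0("rr_overyielding_", v)]] <- overyielding(a, b, ab)
    mixtures[[paste0("rr_transgressive_", v)]] <- transgressive_overyielding(a, b, ab)
  }
  mixtures
}

#' One-sample tests of mixture overyielding against zero
#'
#' Reduces records to one value per site (sites holding several
#' mixtures contribute their mean, avoiding pseudo-replication), then
#' runs two-sided one-sample t tests of the overyielding and
#' transgressive-overyielding indices against 0.
#'
#' @param records Data frame with `site_id` and the two index columns
#'   (names given by `over_col`, `transgr_col`).
#' @param over_col,transgr_col Column names of the two indices.
#' @return Data frame with one row per index: `index`, `t`, `df`, `p`,
#'   `n`, `mean_rr`, `degenerate` (TRUE when the site-level values have
#'   zero variance, in which case t/p are `NA` rather than an error).
#' @export
mixture_tests <- function(records,
                          over_col = "rr_overyielding_soc",
                          transgr_col = "rr_transgressive_soc") {
  one <- function(col) {
    x <- tapply(records[[col]], records$site_id, mean)
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 3) stop("need >= 3 site-level records, got ", n)
    if (stats::sd(x) < .Machine$double.eps^0.5) {
      return(data.frame(index = col, t = NA_real_, df = n - 1, p = NA_real_,
                        n = n, mean_rr = mean(x), degenerate = TRUE))
    }
    tt <- stats::t.test(x, mu = 0)
    data.frame(index = col, t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n = n, mean_rr = mean(x), degenerate = FALSE)
  }
  out <- rbind(one(over_col), one(transgr_col))
  rownames(out) <- NULL
  out
}

#' Regression of SOC overyielding on biomass overyielding
#'
#' Fits the (optionally `w_data`-weighted) least-squares line relating
#' SOC overyielding to biomass overyielding across mixtures, testing
#' whether biomass over-production in mixtures translates into SOC
#' over-storage.
#'
#' @param records Data frame with columns `rr_overyielding_soc` and
#'   `rr_overyielding_biomass`, and optionally `w_data`.
#' @return List: `slope`, `intercept`, `r_squared`, `p`, `n`, `fit`.
#' @export
overyielding_regression <- function(records) {
  w <- records$w_data
  fit <- stats::lm(rr_overyielding_soc ~ rr_overyielding_biomass,
                   data = records, weights = w)
  s <- summary(fit)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    p = s$coefficients[2, 4],
    n = nrow(stats::model.frame(fit)),
    fit = fit
  )
}
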
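#' Study-design reliability weight (W_S)
#'
#' Fixed weight for the quality of the site design: purpose-built common
#' gardens score highest, heterogeneous designs (spontaneous stands compared
#' with plantations) score zero.
#'
#' @param design_class Character vector; each element one of
#'   `"common_garden"`, `"comparative_plantation"`, `"spontaneous"`,
#'   `"heterogeneous"`.
#' @return Numeric vector of weights in \[0, 1\].
#' @export
#' @examples
#' design_weight(c("common_garden", "comparative_plantation"))
design_weight <- function(design_class) {
  lut <- c(
    common_garden          = 1.00,
    comparative_plantation = 0.66,
    spontaneous            = 0.33,
    heterogeneous          = 0.00
  )
  bad <- !design_class %in% names(lut)
  if (any(bad)) {
    stop("unknown design class: ", paste(unique(design_class[bad]), collapse = ", "))
  }
  unname(lut[design_class])
}

#' Block-replication weight (W_B)
#'
#' `log10(n_blocks)`, clamped to \[0, 1\] so designs with more than ten
#' blocks do not dominate.
#'
#' @param n_blocks Positive integer vector of experimental blocks. Missing
#'   values are treated as 1 (weight 0) with a warning.
#' @return Numeric vector in \[0, 1\].
#' @export
block_weight <- function(n_blocks) {
  n_blocks <- .default_count(n_blocks, "n_blocks")
  pmin(pmax(log10(n_blocks), 0), 1)
}

#' Soil-profile replication weight (W_P)
#'
#' `log10(n_profiles) / 2`, clamped to \[0, 1\] (100 or more sampled
#' profiles saturate the criterion).
#'
#' @param n_profiles Positive integer vector of sampled soil profiles.
#'   Missing values are treated as 1 (weight 0) with a warning.
#' @return Numeric vector in \[0, 1\].
#' @export
profile_weight <- function(n_profiles) {
  n_profiles <- .default_count(n_profiles, "n_profiles")
  pmin(pmax(log10(n_profiles) / 2, 0), 1)
}

.default_count <- function(n, what) {
  if (anyNA(n)) {
    warning("missing ", what, " treated as 1 (criterion weight 0)")
    n[is.na(n)] <- 1
  }
  if (any(n < 1)) stop(what, " must be >= 1")
  n
}

#' Composite study weight (W_data)
#'
#' Arithmetic mean of the three criterion weights, floored at 0.05 so no
#' study receives a null statistical weight.
#'
#' @param w_s,w_b,w_p Criterion weights in \[0, 1\] (recycled to a common
#'   length).
#' @return Numeric vector in \[0.05, 1\].
#' @seealso [design_weight()], [block_weight()], [profile_weight()]
#' @export
combine_weights <- function(w_s, w_b, w_p) {
  stopifnot(
    all(w_s >= 0 & w_s <= 1), all(w_b >= 0 & w_b <= 1),
    all(w_p >= 0 & w_p <= 1)
  )
  pmax((w_s + w_b + w_p) / 3, 0.05)
}

#' Attach study weights to a stand table
#'
#' Convenience wrapper computing W_S, W_B, W_P and W_data from the site
#' table's design columns and merging them onto the stand table.
#'
#' @param stands Stand table with a `site_id` column.
#' @param sites Site table with `site_id`, `design_class`, `n_blocks`,
#'   `n_profiles`.
#' @return `stands` with columns `w_s`, `w_b`, `w_p`, `w_data` appended.
#' @export
weigh_stands <- function(stands, sites) {
  w <- data.frame(
    site_id = sites$site_id,
    w_s = design_weight(sites$design_class),
    w_b = block_weight(sites$n_blocks),
    w_p = profile_weight(sites$n_profiles)
  )
  w$w_data <- combine_weights(w$w_s, w$w_b, w$w_p)
  merge(stands, w, by = "site_id", sort = FALSE)
}
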
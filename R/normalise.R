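#' Site-relative log response ratios for a continuous variable
#'
#' Removes between-site variability by expressing each stand's value
#' relative to its site: `rr = ln(value / site_mean)`, the site mean
#' being the unweighted arithmetic mean over the site's non-missing
#' stands. Sites with fewer than two non-missing stands contribute no
#' records for that variable. A positive rr means the stand is above
#' its site average.
#'
#' @param stands Data frame with `stand_id`, `site_id` and the value
#'   column named by `variable`.
#' @param variable Name of the (strictly positive) column to normalise.
#' @param drop_nonpositive Log ratios need positive values; by default
#'   a non-positive value is an error. Set `TRUE` for variables where
#'   zero is a legitimate observation (a stand without a forest floor):
#'   such stands are dropped from the site with a warning instead.
#' @return Data frame `stand_id`, `site_id`, `variable`, `rr`.
#' @export
#' @examples
#' d <- data.frame(stand_id = 1:2, site_id = "s", x = c(20, 10))
#' normalise_continuous(d, "x")$rr # log(4/3), log(2/3)
normalise_continuous <- function(stands, variable, drop_nonpositive = FALSE) {
  v <- stands[[variable]]
  if (is.null(v)) stop("no column '", variable, "'")
  bad <- !is.na(v) & v <= 0
  if (any(bad)) {
    if (drop_nonpositive) {
      warning("dropping ", sum(bad), " non-positive '", variable,
              "' stand(s): ", paste(stands$stand_id[bad], collapse = ", "))
      stands[[variable]][bad] <- NA
    } else {
      stop("non-positive '", variable, "' for stand ",
           paste(stands$stand_id[bad], collapse = ", "))
    }
  }
  out <- lapply(split(stands, stands$site_id), function(d) {
    ok <- !is.na(d[[variable]])
    if (sum(ok) < 2) return(NULL)
    d <- d[ok, ]
    data.frame(
      stand_id = d$stand_id, site_id = d$site_id, variable = variable,
      rr = log(d[[variable]] / mean(d[[variable]]))
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-site two-class log response ratio
#'
#' For categorical species contrasts (e.g. angiosperms vs gymnosperms):
#' class means are computed first within each site (avoiding
#' pseudo-replication when a class has several stands), then the
#' meta-analytic log ratio `ln(mean_A / mean_B)` is returned, one value
#' per site containing both classes.
#'
#' @param stands Data frame with `site_id`, the value column
#'   `variable`, and the class column `class_var` (two levels).
#' @param variable Name of the positive value column.
#' @param class_var Name of the two-level class column.
#' @param classes Optional length-2 character vector fixing the
#'   numerator and denominator class (default: sorted unique levels,
#'   first = numerator).
#' @return Data frame `site_id`, `class_a`, `class_b`, `rr`.
#' @export
normalise_categorical <- function(stands, variable, class_var,
                                  classes = NULL) {
  cls <- stands[[class_var]]
  if (is.null(classes)) classes <- sort(unique(as.character(cls)))
  if (length(classes) != 2) stop("exactly two classes required")
  v <- stands[[variable]]
  if (any(!is.na(v) & v <= 0)) stop("values must be strictly positive")
  out <- lapply(split(stands, stands$site_id), function(d) {
    ok <- !is.na(d[[variable]]) & d[[class_var]] %in% classes
    d <- d[ok, ]
    if (!all(classes %in% d[[class_var]])) return(NULL)
    m <- tapply(d[[variable]], factor(d[[class_var]], levels = classes), mean)
    data.frame(
      site_id = d$site_id[1], class_a = classes[1], class_b = classes[2],
      rr = log(m[[1]] / m[[2]])
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Within-site species-pair contrasts versus phylogenetic distance
#'
#' Enumerates all unordered pairs of species measured at the same site
#' and tabulates the absolute difference in their site-normalised SOC
#' against their phylogenetic distance. The same species pair occurring
#' at several sites is kept as separate rows.
#'
#' @param stands Data frame with `site_id`, `species`, and `rr` (the
#'   site-normalised SOC value per stand; one stand per species per
#'   site — duplicated species within a site are averaged first).
#' @param distances Symmetric species-by-species distance matrix in Myr
#'   (dimnames = species), e.g. from [phylo_distance_matrix()]. May be
#'   `NULL`, in which case the distance column is `NA`.
#' @return Data frame `site_id`, `species_a`, `species_b`,
#'   `abs_delta_rr`, `distance_myr`.
#' @export
phylo_contrast_table <- function(stands, distances = NULL) {
  out <- lapply(split(stands, stands$site_id), function(d) {
    m <- tapply(d$rr, d$species, mean)
    sp <- names(m)
    if (length(sp) < 2) return(NULL)
    idx <- utils::combn(length(sp), 2)
    a <- sp[idx[1, ]]; b <- sp[idx[2, ]]
    dist <- rep(NA_real_, length(a))
    if (!is.null(distances)) {
      known <- a %in% rownames(distances) & b %in% colnames(distances)
      dist[known] <- distances[cbind(a[known], b[known])]
    }
    data.frame(
      site_id = d$site_id[1], species_a = a, species_b = b,
      abs_delta_rr = abs(m[a] - m[b]), distance_myr = dist
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
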
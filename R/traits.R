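#' Species-mean trait value with duplicate-source removal
#'
#' Observations duplicated from the same original source are collapsed
#' to one value before averaging, so a measurement reported by several
#' compilations is not over-weighted.
#'
#' @param values Numeric trait observations (>= 1).
#' @param source_ids Optional parallel vector of source identifiers;
#'   duplicated (value within source) entries collapse to their source
#'   mean before the overall mean.
#' @return The species-mean value.
#' @export
#' @examples
#' species_mean(c(10, 10, 20), c("a", "a", "b")) # 15
species_mean <- function(values, source_ids = NULL) {
  if (length(values) < 1) stop("need at least one observation")
  if (is.null(source_ids)) return(mean(values))
  mean(tapply(values, source_ids, mean))
}

#' Build a species-by-trait table from long observations
#'
#' Applies [species_mean()] per species-trait cell.
#'
#' @param obs Data frame with columns `species`, `trait`, `value`, and
#'   optionally `source_id`.
#' @return Numeric matrix species x trait with a `provenance`
#'   character-matrix attribute (`"measured"` or `NA`).
#' @export
trait_table <- function(obs) {
  sp <- sort(unique(obs$species))
  tr <- sort(unique(obs$trait))
  x <- matrix(NA_real_, length(sp), length(tr), dimnames = list(sp, tr))
  for (g in split(obs, list(obs$species, obs$trait), drop = TRUE)) {
    x[g$species[1], g$trait[1]] <- species_mean(g$value, g$source_id)
  }
  prov <- ifelse(is.na(x), NA_character_, "measured")
  attr(x, "provenance") <- prov
  x
}

#' Close an interconnected C / N / C:N trait triplet
#'
#' When exactly one of leaf C, leaf N and leaf C:N is missing it is
#' computed from the identity C:N = C / N. When all three are present
#' their consistency is audited: values inconsistent beyond `tol`
#' (relative) are flagged but the measured values are kept.
#'
#' @param c_val,n_val,cn_val Scalars, `NA` for missing.
#' @param tol Relative consistency tolerance (default 1e-6).
#' @return List: `c`, `n`, `cn`, `filled` (which slot was computed, or
#'   `NA`), `consistent` (FALSE only when all three present and
#'   inconsistent).
#' @export
close_triplet <- function(c_val, n_val, cn_val, tol = 1e-6) {
  present <- !is.na(c(c_val, n_val, cn_val))
  if (sum(present) < 2) stop("need at least two of C, N, C:N")
  filled <- NA_character_
  consistent <- TRUE
  if (all(present)) {
    consistent <- abs(cn_val - c_val / n_val) <= tol * abs(cn_val)
  } else if (is.na(cn_val)) {
    cn_val <- c_val / n_val; filled <- "cn"
  } else if (is.na(c_val)) {
    c_val <- cn_val * n_val; filled <- "c"
  } else {
    n_val <- c_val / cn_val; filled <- "n"
  }
  list(c = c_val, n = n_val, cn = cn_val, filled = filled,
       consistent = consistent)
}

#' Close C/N/C:N triplets across a trait table
#'
#' @param x Trait matrix from [trait_table()].
#' @param c_col,n_col,cn_col Column names of the triplet.
#' @inheritParams close_triplet
#' @return The matrix with closable cells filled (provenance
#'   `"closed"`); inconsistent complete rows get attribute
#'   `inconsistent_rows`.
#' @export
close_triplets <- function(x, c_col = "leaf_c", n_col = "leaf_n",
                           cn_col = "leaf_cn", tol = 1e-6) {
  prov <- attr(x, "provenance")
  bad <- character(0)
  for (i in seq_len(nrow(x))) {
    vals <- c(x[i, c_col], x[i, n_col], x[i, cn_col])
    if (sum(!is.na(vals)) < 2) next
    r <- close_triplet(vals[1], vals[2], vals[3], tol = tol)
    if (!r$consistent) bad <- c(bad, rownames(x)[i])
    if (!is.na(r$filled)) {
      col <- switch(r$filled, c = c_col, n = n_col, cn = cn_col)
      x[i, col] <- switch(r$filled, c = r$c, n = r$n, cn = r$cn)
      prov[i, col] <- "closed"
    }
  }
  attr(x, "provenance") <- prov
  attr(x, "inconsistent_rows") <- bad
  x
}

#' Fill a trait's missing values by regression on another trait
#'
#' Ordinary least squares of the target on the predictor over species
#' with both measured; only missing target cells with a non-missing
#' predictor are filled (observed cells are never altered).
#'
#' @param x Trait matrix from [trait_table()].
#' @param target,predictor Column names.
#' @param min_n Minimum species with both traits (default 8).
#' @return The matrix with filled cells (provenance `"regressed"`) and
#'   attribute `fit_report` (list `n`, `r_squared`, `slope`,
#'   `fraction_filled`).
#' @export
gap_fill_regression <- function(x, target, predictor, min_n = 8) {
  both <- !is.na(x[, target]) & !is.na(x[, predictor])
  if (sum(both) < min_n) {
    stop("only ", sum(both), " species with both '", target, "' and '",
         predictor, "' (need ", min_n, ")")
  }
  if (stats::sd(x[both, predictor]) < .Machine$double.eps^0.5) {
    stop("degenerate predictor '", predictor, "': no variance")
  }
  fit <- stats::lm(y ~ p, data = data.frame(y = x[both, target],
                                            p = x[both, predictor]))
  fill <- is.na(x[, target]) & !is.na(x[, predictor])
  prov <- attr(x, "provenance")
  if (any(fill)) {
    x[fill, target] <- stats::predict(fit,
      newdata = data.frame(p = x[fill, predictor]))
    prov[fill, target] <- "regressed"
  }
  attr(x, "provenance") <- prov
  attr(x, "fit_report") <- list(
    n = sum(both), r_squared = summary(fit)$r.squared,
    slope = unname(stats::coef(fit)[2]),
    fraction_filled = mean(fill)
  )
  x
}

#' Hierarchical clade-mean fill for a trait
#'
#' Remaining gaps are filled by the genus mean, then the family mean,
#' then the spermaphyte-class mean of the observed values.
#'
#' @param x Trait matrix.
#' @param trait Column to fill.
#' @param lineage Data frame `species`, `genus`, `family`, `class`
#'   covering the rows of `x`.
#' @return The matrix with filled cells (provenance `"clade_mean"`).
#' @export
clade_mean_fill <- function(x, trait, lineage) {
  rownames(lineage) <- lineage$species
  prov <- attr(x, "provenance")
  v <- x[, trait]
  obs <- x[, trait] # clade means always come from measured values
  for (rank in c("genus", "family", "class")) {
    if (!anyNA(v)) break
    grp <- lineage[rownames(x), rank]
    means <- tapply(obs, grp, mean, na.rm = TRUE)
    fill <- is.na(v) & !is.na(grp) & is.finite(means[grp])
    v[fill] <- means[grp[fill]]
    prov[fill, trait] <- "clade_mean"
  }
  x[, trait] <- v
  attr(x, "provenance") <- prov
  x
}

#' Iterative low-rank PCA imputation of a numeric matrix
#'
#' EM-style imputation: columns are standardised on their observed
#' cells, missing cells initialised at the column mean, and the matrix
#' repeatedly replaced by its rank-`rank` SVD reconstruction at the
#' missing positions until the imputed values stabilise. Observed
#' cells are never altered.
#'
#' @param x Numeric matrix with `NA`s.
#' @param rank Reconstruction rank (>= 1, < min(dim)).
#' @param max_iter,tol Convergence controls.
#' @return Completed matrix on the original scale; attributes `rank`
#'   and `iterations`.
#' @export
impute_pca <- function(x, rank = 2, max_iter = 3000, tol = 1e-7) {
  stopifnot(rank >= 1, rank <= min(dim(x)) - 1)
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sd, "/")
  miss <- is.na(z)
  z[miss] <- 0
  if (any(miss)) {
    obj_prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      s <- svd(z, nu = rank, nv = rank)
      zhat <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
      delta <- max(abs(z[miss] - zhat[miss]))
      z[miss] <- zhat[miss]
      # EM monotonically decreases the observed-cell reconstruction
      # error; a plateau there means convergence even when imputed
      # cells still rotate within a degenerate principal subspace
      obj <- sum((z[!miss] - zhat[!miss])^2)
      if (delta < tol ||
          (it > 10 && abs(obj_prev - obj) < 1e-10 * (1 + obj))) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    if (!converged) {
      stop("PCA imputation did not converge after ", max_iter,
           " iterations (last change ", signif(delta, 3), ")")
    }
  } else {
    it <- 0L
  }
  out <- sweep(sweep(z, 2, sd, "*"), 2, mu, "+")
  dimnames(out) <- dimnames(x)
  attr(out, "rank") <- rank
  attr(out, "iterations") <- if (any(miss)) it else 0L
  out
}

#' Choose the imputation rank by cell-holdout cross-validation
#'
#' Repeatedly masks a fraction of the observed cells, imputes at each
#' candidate rank, and picks the rank minimising the mean squared
#' reconstruction error of the held-out (standardised) cells.
#'
#' @param x Numeric matrix with `NA`s.
#' @param ranks Candidate ranks (default 1 to min(dim)-1, capped at 5).
#' @param holdout Fraction of observed cells masked per repeat (0.05).
#' @param repeats Number of repeats (10).
#' @param seed RNG seed for the masking (fixed for reproducibility).
#' @return The selected rank; attribute `cv_mse` gives the per-rank
#'   mean errors.
#' @export
choose_rank <- function(x, ranks = NULL, holdout = 0.05, repeats = 10,
                        seed = 1L) {
  if (is.null(ranks)) ranks <- seq_len(min(min(dim(x)) - 1, 5))
  obs <- which(!is.na(x))
  n_hold <- max(1, round(holdout * length(obs)))
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- 1
  err <- matrix(NA_real_, repeats, length(ranks))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (r in seq_len(repeats)) {
    hold <- sample(obs, n_hold)
    xm <- x
    xm[hold] <- NA
    # a held-out cell may empty a column; skip such draws
    if (any(colSums(!is.na(xm)) < 2)) next
    for (k in seq_along(ranks)) {
      comp <- try(impute_pca(xm, rank = ranks[k], max_iter = 300, tol = 1e-6),
                  silent = TRUE)
      if (inherits(comp, "try-error")) next
      zs <- (comp[hold] - x[hold]) / sd[col(x)[hold]]
      err[r, k] <- mean(zs^2)
    }
  }
  mse <- colMeans(err, na.rm = TRUE)
  best <- ranks[which.min(mse)]
  attr(best, "cv_mse") <- stats::setNames(mse, ranks)
  best
}

#' Integrative trait index as the first axis of an imputation PCA
#'
#' Missing cells are filled by [impute_pca()] (rank chosen by
#' [choose_rank()] unless given), a PCA is run on the standardised
#' completed matrix, and each species' score on the first axis is
#' returned. The axis sign is fixed so the anchor trait loads
#' positively (for a plant-economics-spectrum index anchored on Amax,
#' positive scores mean acquisitive species).
#'
#' @param x Species-by-trait numeric matrix (>= 5 species, >= 3
#'   traits, overall missingness < 60%). All-missing columns are
#'   dropped with a warning.
#' @param traits Optional subset of columns to use.
#' @param anchor Trait whose loading is forced positive.
#' @param rank Imputation rank; `NULL` (default) = cross-validated.
#' @return List of class `trait_index`: `scores` (named vector),
#'   `variance_explained_axis1`, `loadings` (axis-1 loadings), `rank`,
#'   `completed` (the imputed matrix).
#' @export
build_index <- function(x, traits = colnames(x), anchor, rank = NULL) {
  x <- x[, traits, drop = FALSE]
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) {
    warning("dropping all-missing trait column(s): ",
            paste(colnames(x)[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  if (nrow(x) < 5 || ncol(x) < 3) stop("need >= 5 species and >= 3 traits")
  if (mean(is.na(x)) >= 0.6) stop("overall missingness must be < 60%")
  if (!anchor %in% colnames(x)) stop("anchor trait '", anchor, "' not in table")
  if (anyNA(x)) {
    if (is.null(rank)) rank <- choose_rank(x)
    comp <- impute_pca(x, rank = rank)
  } else {
    comp <- x
    rank <- NA_integer_
  }
  pca <- stats::prcomp(comp, center = TRUE, scale. = TRUE)
  scores <- pca$x[, 1]
  load1 <- pca$rotation[, 1]
  if (load1[anchor] < 0) {
    scores <- -scores
    load1 <- -load1
  }
  structure(
    list(
      scores = scores,
      variance_explained_axis1 = pca$sdev[1]^2 / sum(pca$sdev^2),
      loadings = load1, rank = rank, completed = comp
    ),
    class = "trait_index"
  )
}
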
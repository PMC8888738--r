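#' Build a clade-age tree from a crown-age table and a lineage map
#'
#' The tree is defined by (i) a lineage map placing every species in a
#' genus, family, order and spermaphyte class, and (ii) crown ages (Myr)
#' for named clades. The root age is the angiosperm-gymnosperm split
#' (350 Myr by convention here), so the distance between any angiosperm
#' and any gymnosperm is 350 Myr. Distances are most-recent-common-
#' ancestor (MRCA) crown ages, not path lengths (i.e. the split age,
#' not twice the split age).
#'
#' @param ages Data frame with columns `clade` and `crown_age_myr`
#'   (one row per named clade; clades absent from the table have
#'   unresolved ages and fall back to the half-crown rule in
#'   [pairwise_distance()]). Must contain a row for `root_clade`.
#' @param lineage Data frame with columns `species`, `genus`, `family`,
#'   `order`, `class` (`NA` allowed above genus, except `class`).
#' @param root_clade Name of the root clade in `ages` (default
#'   `"Spermatophyta"`).
#' @return Object of class `clade_tree`.
#' @export
clade_tree <- function(ages, lineage, root_clade = "Spermatophyta") {
  stopifnot(all(c("clade", "crown_age_myr") %in% names(ages)),
            all(c("species", "genus", "family", "order", "class") %in% names(lineage)))
  if (anyDuplicated(ages$clade)) stop("duplicated clade in age table")
  if (anyDuplicated(lineage$species)) stop("duplicated species in lineage map")
  if (anyNA(lineage$class)) stop("every species must resolve at least to class")
  age <- stats::setNames(ages$crown_age_myr, ages$clade)
  if (!root_clade %in% names(age)) stop("root clade '", root_clade, "' has no age")
  ranks <- c("genus", "family", "order", "class")
  # ultrametric consistency: ages must increase up every lineage chain
  for (i in seq_len(nrow(lineage))) {
    chain <- c(unlist(lineage[i, ranks], use.names = FALSE), root_clade)
    a <- age[chain]
    known <- which(!is.na(a))
    if (length(known) > 1 && any(diff(a[known]) <= 0)) {
      j <- known[which(diff(a[known]) <= 0)[1] + c(0, 1)]
      stop("age inversion: clade '", chain[j[1]], "' (", a[j[1]],
           " Myr) is not younger than its ancestor '", chain[j[2]],
           "' (", a[j[2]], " Myr)")
    }
  }
  rownames(lineage) <- lineage$species
  structure(
    list(age = age, lineage = lineage, ranks = ranks, root = root_clade),
    class = "clade_tree"
  )
}

#' Load the clade-age tree shipped with the package
#'
#' Ages come from `inst/extdata/clade_ages.csv`, an editable
#' configuration file: the angiosperm-gymnosperm split (350 Myr) and
#' the Cupressales-Pinales split (273 Myr) are fixed reference values;
#' the remaining ages are plausible placeholders to be refined from the
#' systematics literature.
#'
#' @return A [clade_tree()].
#' @export
default_clade_tree <- function() {
  ages <- utils::read.csv(system.file("extdata", "clade_ages.csv",
                                      package = "soctraits"))
  lineage <- utils::read.csv(system.file("extdata", "lineage.csv",
                                         package = "soctraits"))
  clade_tree(ages, lineage)
}

# lowest shared clade of two species + the chain of containing clades
.mrca_chain <- function(tree, a, b) {
  la <- tree$lineage[a, ]
  lb <- tree$lineage[b, ]
  if (anyNA(c(la$species, lb$species))) {
    stop("species not in lineage map: ",
         paste(setdiff(c(a, b), tree$lineage$species), collapse = ", "))
  }
  chain <- tree$root
  for (i in rev(seq_along(tree$ranks))) {
    ca <- la[[tree$ranks[i]]]
    cb <- lb[[tree$ranks[i]]]
    if (is.na(ca) && is.na(cb)) next # unranked level: skip, not a split
    if (is.na(ca) || is.na(cb) || !identical(ca, cb)) break
    chain <- c(ca, chain)
  }
  chain
}

#' Phylogenetic distance between two species
#'
#' Distance = crown age of the MRCA clade (Myr). When the MRCA clade's
#' age is unresolved, the fallback is half the crown age of the
#' smallest containing clade with a resolved age.
#'
#' @param tree A [clade_tree()].
#' @param a,b Species names.
#' @return List with `distance` (Myr) and `provenance` (`"mrca"` or
#'   `"half_crown_fallback"`).
#' @export
pairwise_distance <- function(tree, a, b) {
  if (identical(a, b)) return(list(distance = 0, provenance = "mrca"))
  chain <- .mrca_chain(tree, a, b)
  ages <- tree$age[chain]
  known <- which(!is.na(ages))
  if (known[1] == 1) {
    list(distance = unname(ages[1]), provenance = "mrca")
  } else {
    list(distance = unname(ages[known[1]]) / 2,
         provenance = "half_crown_fallback")
  }
}

#' Full pairwise distance matrix
#'
#' @param tree A [clade_tree()].
#' @param species Species to include (default: all in the lineage map).
#' @return Symmetric matrix (Myr) with zero diagonal; attribute
#'   `provenance` is a matching character matrix.
#' @export
phylo_distance_matrix <- function(tree, species = tree$lineage$species) {
  n <- length(species)
  d <- matrix(0, n, n, dimnames = list(species, species))
  p <- matrix("mrca", n, n, dimnames = list(species, species))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        r <- pairwise_distance(tree, species[i], species[j])
        d[i, j] <- d[j, i] <- r$distance
        p[i, j] <- p[j, i] <- r$provenance
      }
    }
  }
  attr(d, "provenance") <- p
  d
}

#' Export the clade-age tree as a newick string
#'
#' Builds an ultrametric newick representation (branch lengths in Myr)
#' for the species of the lineage map. Clades with unresolved ages are
#' collapsed into their parent (soft polytomy), so only MRCA-resolvable
#' structure is exported. The result parses with [ape::read.tree()].
#'
#' @param tree A [clade_tree()].
#' @param species Species to include (default all).
#' @return A newick string (single tree, terminated by `;`).
#' @export
as_newick <- function(tree, species = tree$lineage$species) {
  lin <- tree$lineage[tree$lineage$species %in% species, , drop = FALSE]
  build <- function(rows, rank_i, parent_age) {
    if (rank_i > length(tree$ranks)) {
      # species tips hang from their genus (or nearest resolved clade)
      return(list(
        parts = paste0(gsub(" ", "_", rows$species), ":", parent_age)
      ))
    }
    rank <- rev(tree$ranks)[rank_i] # class, order, family, genus
    parts <- character(0)
    for (cl in unique(rows[[rank]])) {
      sub <- rows[is.na(rows[[rank]]) == is.na(cl) &
                    (is.na(cl) | rows[[rank]] %in% cl), , drop = FALSE]
      cl_age <- if (!is.na(cl)) unname(tree$age[cl]) else NA_real_
      if (is.na(cl) || is.na(cl_age)) {
        parts <- c(parts, build(sub, rank_i + 1, parent_age)$parts)
      } else {
        inner <- build(sub, rank_i + 1, cl_age)$parts
        parts <- c(parts, if (length(inner) == 1) {
          # single child: splice out this node, extending the branch
          old <- as.numeric(sub("^.*:", "", inner))
          paste0(sub(":[0-9.eE+-]+$", "", inner), ":",
                 old + parent_age - cl_age)
        } else {
          paste0("(", paste(inner, collapse = ","), ")", cl, ":",
                 parent_age - cl_age)
        })
      }
    }
    list(parts = parts)
  }
  root_age <- unname(tree$age[tree$root])
  parts <- build(lin, 1, root_age)$parts
  paste0("(", paste(parts, collapse = ","), ")", tree$root, ";")
}

#' Census of within-site species pairs
#'
#' Enumerates unordered species pairs co-occurring at a site, reporting
#' the total number of (site, pair) combinations, the number of
#' distinct pairs across sites, and the fraction of pairs whose
#' distance required the half-crown fallback.
#'
#' @param stands Data frame with `site_id` and `species`.
#' @param tree Optional [clade_tree()] for distances/provenance.
#' @return List: `pairs` (data frame `site_id`, `species_a`,
#'   `species_b`, `distance_myr`, `provenance`), `n_total`,
#'   `n_distinct`, `fallback_fraction`.
#' @export
site_pair_census <- function(stands, tree = NULL) {
  rows <- lapply(split(stands, stands$site_id), function(d) {
    sp <- sort(unique(d$species))
    if (length(sp) < 2) return(NULL)
    idx <- utils::combn(length(sp), 2)
    data.frame(site_id = d$site_id[1], species_a = sp[idx[1, ]],
               species_b = sp[idx[2, ]])
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) {
    return(list(pairs = NULL, n_total = 0L, n_distinct = 0L,
                fallback_fraction = NA_real_))
  }
  rownames(pairs) <- NULL
  pairs$distance_myr <- NA_real_
  pairs$provenance <- NA_character_
  if (!is.null(tree)) {
    for (i in seq_len(nrow(pairs))) {
      r <- pairwise_distance(tree, pairs$species_a[i], pairs$species_b[i])
      pairs$distance_myr[i] <- r$distance
      pairs$provenance[i] <- r$provenance
    }
  }
  key <- paste(pairs$species_a, pairs$species_b, sep = "|")
  list(
    pairs = pairs,
    n_total = nrow(pairs),
    n_distinct = length(unique(key)),
    fallback_fraction = if (is.null(tree)) NA_real_ else
      mean(pairs$provenance == "half_crown_fallback")
  )
}
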
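#' Write a simulated dataset to CSV fixtures
#'
#' Writes `sites.csv`, `stands.csv`, `soil_layers.csv`, `traits.csv`,
#' `mixtures.csv` and `truth.csv` (plus `species_truth.csv` and the
#' configuration as `config.yaml`) under `path`. Output is plain CSV
#' with full floating-point precision, so a fixed seed gives
#' byte-identical files.
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param path Directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(dataset, path) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", path)
  }
  tabs <- c(sites = "sites", stands = "stands", soil_layers = "soil_layers",
            traits = "traits", mixtures = "mixtures", truth = "truth",
            species = "species_truth")
  for (nm in names(tabs)) {
    f <- file.path(path, paste0(tabs[[nm]], ".csv"))
    utils::write.csv(format(dataset[[nm]], digits = 15, trim = TRUE,
                            scientific = FALSE),
                     f, row.names = FALSE, quote = TRUE)
  }
  cfg <- unclass(dataset$config)
  cfg$trait_loading_vector <- as.list(cfg$trait_loading_vector)
  yaml::write_yaml(cfg, file.path(path, "config.yaml"))
  invisible(path)
}

#' Read a CSV fixture directory back into tables
#'
#' @param path Directory written by [write_fixture()].
#' @return List with the same tables (and `config`, if present) as
#'   [simulate_dataset()] produces.
#' @export
read_fixture <- function(path) {
  rd <- function(f) {
    d <- utils::read.csv(file.path(path, f), stringsAsFactors = FALSE)
    # all-missing columns parse as logical; they are numeric by schema
    for (nm in names(d)) {
      if (is.logical(d[[nm]]) && all(is.na(d[[nm]]))) {
        d[[nm]] <- as.numeric(d[[nm]])
      }
    }
    d
  }
  out <- list(
    sites = rd("sites.csv"), stands = rd("stands.csv"),
    soil_layers = rd("soil_layers.csv"), traits = rd("traits.csv"),
    mixtures = rd("mixtures.csv"), truth = rd("truth.csv"),
    species = rd("species_truth.csv")
  )
  cf <- file.path(path, "config.yaml")
  if (file.exists(cf)) {
    cfg <- yaml::read_yaml(cf)
    cfg$trait_loading_vector <- unlist(cfg$trait_loading_vector)
    cfg$stands_per_site <- as.numeric(cfg$stands_per_site)
    out$config <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
  }
  class(out) <- "sim_dataset"
  out
}
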
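# End-to-end pipeline: simulate (optional) -> synchrony -> covariates ->
# attributes -> inference, with a run manifest for reproducibility and
# per-stage row accounting.

#' Default pipeline configuration
#'
#' @param simulate either a [study_config()] (the pipeline generates its
#'   inputs) or `NULL`, in which case `inputs` must name existing CSVs.
#' @param inputs named list of CSV paths (abundance, sites, climate,
#'   habitat, attributes) when not simulating.
#' @param max_distance_km,max_pairs,min_shared,window_years synchrony
#'   stage parameters.
#' @param alpha selection / significance level.
#' @param b_select,b_attr permutation counts for climate-variable selection
#'   and attribute models.
#' @param attributes attribute columns to model.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = study_config(), inputs = NULL,
                            max_distance_km = 100, max_pairs = 10000,
                            min_shared = 7, window_years = 10,
                            alpha = 0.05, b_select = 1000, b_attr = 1000,
                            attributes = c("specialism", "mobility",
                                           "mean_abundance",
                                           "change_class_all")) {
  if (is.null(simulate) && is.null(inputs)) {
    stop("config must contain either a simulate block or input paths")
  }
  if (is.null(simulate)) {
    need <- c("abundance", "sites", "climate", "habitat", "attributes")
    miss <- setdiff(need, names(inputs))
    if (length(miss) > 0L) {
      stop("inputs missing: ", paste(miss, collapse = ", "))
    }
    absent <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
    if (length(absent) > 0L) {
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
    }
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synchrony analysis pipeline
#'
#' Executes every stage in order, writes all intermediate and final tables
#' as CSV into `out_dir`, and records a JSON manifest (config snapshot,
#' per-stage seeds, row counts in/out, dropped-record tallies by reason,
#' package version). Re-running with the same config and seed reproduces
#' every output byte-identically; [rerun_from_manifest()] does so from the
#' manifest alone.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed.
#' @return invisibly, a list with the main in-memory results (`synchrony`,
#'   `climate_synchrony`, `model_table`, `selection`, `attribute_results`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(packageVersion("synchroscope")),
    seed = seed,
    seeds = list(climate = substream_seed(seed, "climate"),
                 gaps = substream_seed(seed, "gaps"),
                 pairs = substream_seed(seed, "pairs"),
                 permutations = substream_seed(seed, "perm:base")),
    config = serialise_config(config),
    stages = list()
  )

  # ---- stage: inputs -----------------------------------------------------
  if (!is.null(config$simulate)) {
    fx <- make_study_fixture(config$simulate, seed = seed)
    abundance <- fx$abundance; sites <- fx$sites
    climate <- fx$climate; habitat <- fx$habitat
    attributes <- fx$attributes
  } else {
    abundance <- read_table(config$inputs$abundance, "abundance")
    sites <- read_table(config$inputs$sites, "sites")
    climate <- read_table(config$inputs$climate, "climate")
    habitat <- read_table(config$inputs$habitat, "habitat")
    attributes <- read_table(config$inputs$attributes, "attributes")
  }
  write_table(abundance, file.path(out_dir, "abundance.csv"))
  write_table(sites, file.path(out_dir, "sites.csv"))
  write_table(climate, file.path(out_dir, "climate.csv"))
  write_table(habitat, file.path(out_dir, "habitat.csv"))
  write_table(attributes, file.path(out_dir, "attributes.csv"))
  manifest$stages$inputs <- list(abundance_rows = nrow(abundance),
                                 sites = nrow(sites))

  # ---- stage: synchrony --------------------------------------------------
  pairs <- eligible_pairs(sites, max_distance_km = config$max_distance_km,
                          max_pairs = config$max_pairs, seed = seed)
  sync <- moving_window_synchrony(abundance, sites, pairs = pairs,
                                  window_years = config$window_years,
                                  min_shared = config$min_shared)
  clim <- climate_synchrony(climate, sites, pairs,
                            window_years = config$window_years)
  write_table(sync$records, file.path(out_dir, "synchrony.csv"))
  write_table(sync$dropped, file.path(out_dir, "dropped.csv"))
  write_table(clim$records, file.path(out_dir, "climate_synchrony.csv"))
  manifest$stages$synchrony <- list(
    pairs = nrow(pairs),
    records = nrow(sync$records),
    dropped_by_reason = as.list(table(sync$dropped$reason)),
    climate_records = nrow(clim$records),
    climate_dropped = clim$n_dropped
  )

  # ---- stage: covariates -------------------------------------------------
  cov <- pair_covariates(pairs, sites, habitat, mode = "proportions")
  write_table(cov, file.path(out_dir, "pair_covariates.csv"))
  manifest$stages$covariates <- list(pairs = nrow(cov))

  # ---- stage: model table + inference ------------------------------------
  tab <- build_model_table(sync$records, cov, clim$records, attributes)
  manifest$stages$model_table <- list(
    rows = nrow(tab),
    dropped_incomplete = attr(tab, "n_dropped_incomplete")
  )
  sel <- select_climate_covariates(tab, alpha = config$alpha,
                                   B = config$b_select, seed = seed)
  write_table(sel$results, file.path(out_dir, "climate_selection.csv"))
  attr_res <- attribute_models(tab, attributes = config$attributes,
                               climate_vars = sel$kept,
                               B = config$b_attr, seed = seed)
  write_table(attr_res, file.path(out_dir, "model_results.csv"))
  manifest$stages$inference <- list(
    climate_kept = sel$kept,
    attribute_rows = nrow(attr_res)
  )

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(synchrony = sync, climate_synchrony = clim,
                 model_table = tab, selection = sel,
                 attribute_results = attr_res, manifest = manifest))
}

# Config as plain lists for the manifest (drops function elements, which a
# YAML/JSON round trip cannot carry).
serialise_config <- function(config) {
  clean <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, clean)
      x[!vapply(x, is.null, logical(1))]
    } else if (is.function(x)) NULL else x
  }
  clean(unclass(config))
}

#' Re-run a pipeline from its manifest
#'
#' Reads the manifest written by [run_pipeline()] and re-executes the
#' pipeline with the recorded config and seed. With an unchanged package
#' version, outputs are byte-identical to the original run.
#'
#' @param manifest_path path to a `manifest.json`.
#' @param out_dir output directory for the re-run.
#' @return as [run_pipeline()].
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg_raw <- man$config
  sim <- if (!is.null(cfg_raw$simulate)) {
    do.call(study_config, cfg_raw$simulate[names(cfg_raw$simulate) %in%
                                             names(formals(study_config))])
  } else NULL
  keep <- setdiff(names(formals(pipeline_config)), c("simulate", "inputs"))
  args <- cfg_raw[names(cfg_raw) %in% keep]
  cfg <- do.call(pipeline_config,
                 c(list(simulate = sim, inputs = cfg_raw$inputs), args))
  run_pipeline(cfg, out_dir, seed = man$seed)
}

#' Load a pipeline configuration from a YAML file
#'
#' The file may contain a `simulate:` block (arguments of
#' [study_config()]) and any top-level arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(study_config, y$simulate) else NULL
  keep <- setdiff(names(formals(pipeline_config)), c("simulate", "inputs"))
  args <- y[names(y) %in% keep]
  do.call(pipeline_config, c(list(simulate = sim, inputs = y$inputs), args))
}
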
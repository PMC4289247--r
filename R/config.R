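#' Default run configuration
#'
#' Defaults follow the worm/fly-scale analysis conventions: q = 250 labels,
#' R = 32 annealing runs, cooling factor 0.9, stop flip rate 1%,
#' co-appearance threshold 0.95, minimum module size 5, neighbor count
#' d = 5 (or `"auto"` for the smallest connecting d).
#'
#' @return Nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    inputs = list(species = list(), orthologs = NULL),
    coexpression = list(d = "auto", d_max = 30L, log2 = FALSE,
                        signed = FALSE),
    cost = list(kappa = 3, lambda = 1, signed = FALSE,
                kappa_triplet = NULL, normalize_layers = FALSE,
                weight_scheme = "mean_recip"),
    annealing = list(q = 250L, R = 32L, cooling = 0.9, stop_fliprate = 0.01,
                     sweeps = 20L, max_temperatures = 1000L, seed = 1L),
    consensus = list(threshold = 0.95, min_size = 5L),
    evaluation = list(metagenes = NULL, gaf = NULL, regulators = NULL)
  ), class = "run_config")
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (sec in names(raw)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (key in names(raw[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, ".", key)
      cfg[[sec]][[key]] <- raw[[sec]][[key]]
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  a <- cfg$annealing
  stopifnot(a$q >= 2, a$R >= 1, a$cooling > 0, a$cooling < 1,
            a$stop_fliprate > 0, a$stop_fliprate < 1, a$sweeps >= 1)
  stopifnot(cfg$cost$kappa >= 0, cfg$cost$lambda > 0,
            cfg$consensus$threshold > 0, cfg$consensus$threshold <= 1,
            cfg$consensus$min_size >= 1)
  cfg
}

config_params <- function(cfg) {
  ct <- cfg$cost
  cost_params(kappa = ct$kappa, lambda = ct$lambda, signed = ct$signed,
              kappa_triplet = if (is.null(ct$kappa_triplet)) ct$kappa
                              else ct$kappa_triplet,
              normalize_layers = ct$normalize_layers)
}

config_schedule <- function(cfg) {
  a <- cfg$annealing
  anneal_schedule(cooling_factor = a$cooling, stop_fliprate = a$stop_fliprate,
                  sweeps_per_temperature = a$sweeps,
                  max_temperatures = a$max_temperatures, seed = a$seed)
}

#' Run the full clustering pipeline on an assembled multi-layer network
#'
#' Ensemble annealing, co-appearance aggregation, consensus module
#' extraction and conserved/specific classification in one call.
#'
#' @param mln A `multilayer_network`.
#' @param params A [cost_params()].
#' @param q,schedule,R Annealing settings; see [run_ensemble()].
#' @param threshold,min_size Consensus settings; see [extract_modules()].
#' @param parallel Passed to [run_ensemble()].
#' @return List `ensemble`, `coappearance`, `modules`, `tags`.
#' @export
run_pipeline <- function(mln, params = cost_params(), q = 50L,
                         schedule = anneal_schedule(), R = 16L,
                         threshold = 0.95, min_size = 5L, parallel = FALSE) {
  ens <- run_ensemble(mln, params, q, schedule, R, parallel = parallel)
  coap <- coappearance(ens, mln)
  mods <- extract_modules(coap, threshold, min_size)
  tags <- classify_modules(mods, mln)
  list(ensemble = ens, coappearance = coap, modules = mods, tags = tags)
}

#' Write pipeline outputs with provenance
#'
#' Writes modules (TSV + GMT), the co-appearance matrix (MTX + node index),
#' per-run temperature traces, the resolved configuration, and a JSON
#' summary (versions, seeds, counts) into `dir`.
#'
#' @param result Output of [run_pipeline()].
#' @param mln The clustered `multilayer_network`.
#' @param dir Output directory.
#' @param config Optional `run_config` to serialize alongside.
#' @return `dir`, invisibly.
#' @export
write_pipeline_output <- function(result, mln, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_modules(result$modules, mln, file.path(dir, "modules.tsv"),
                tags = result$tags)
  sets <- lapply(result$modules$modules, function(idx)
    mln$node_index$gene[idx])
  if (length(sets)) write_gmt(sets, file.path(dir, "modules.gmt"))
  write_coappearance(result$coappearance, file.path(dir, "coappearance.mtx"),
                     file.path(dir, "node_index.tsv"))
  traces <- do.call(rbind, lapply(result$ensemble, function(r)
    cbind(seed = r$seed, r$temperature_trace)))
  utils::write.table(traces, file.path(dir, "annealing_trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config))
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  summary <- list(
    package_version = as.character(utils::packageVersion("crossclust")),
    n_runs = length(result$ensemble),
    seeds = vapply(result$ensemble, `[[`, 0L, "seed"),
    n_modules = length(result$modules$modules),
    n_unassigned = length(result$modules$unassigned),
    module_sizes = as.integer(lengths(result$modules$modules)),
    tags = as.list(result$tags))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
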
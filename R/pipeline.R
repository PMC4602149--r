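# Orchestration and file-format plumbing: one seeded, manifest-backed run of
# simulate -> extract -> cluster -> report, plus round-trip readers/writers
# for every tabular artifact.

#' Pipeline run configuration
#'
#' Collects every tunable of a full run with validated defaults. All
#' thresholds of the individual stages keep their own function defaults
#' unless overridden here.
#'
#' @param seed Root seed; per-stage sub-seeds are spawned from it.
#' @param n_per_archetype Cells per archetype.
#' @param archetypes Archetype table.
#' @param mode `"noiseless"` extracts from exact expected responses;
#'   `"poisson"` simulates spike trains first and extracts from them.
#' @param k_range,restarts Clustering sweep settings.
#' @param margin Placement margin for [sample_population()] (um).
#' @param out_dir Optional directory; when set, all artifacts are written
#'   there.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 0, n_per_archetype = 40,
                            archetypes = rgc_archetypes(),
                            mode = c("noiseless", "poisson"),
                            k_range = 4:25, restarts = 200,
                            margin = 0, out_dir = NULL) {
  mode <- match.arg(mode)
  check_number(seed, "seed")
  check_number(n_per_archetype, "n_per_archetype", lower = 1)
  check_number(restarts, "restarts", lower = 1)
  if (!is.numeric(k_range) || length(k_range) < 1 || any(k_range < 2)) {
    stop("`k_range` must be numeric with all values >= 2", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_per_archetype = as.integer(n_per_archetype),
                 archetypes = archetypes, mode = mode,
                 k_range = as.integer(k_range),
                 restarts = as.integer(restarts),
                 margin = margin, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The archetype table is stored as a list of rows; everything else is
#' scalar.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst$archetypes <- purrr::transpose(as.list(tibble::as_tibble(lst$archetypes)))
  yaml::write_yaml(lst, path)
  invisible(config)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  arch <- dplyr::bind_rows(lapply(lst$archetypes, tibble::as_tibble))
  pipeline_config(seed = lst$seed, n_per_archetype = lst$n_per_archetype,
                  archetypes = arch, mode = lst$mode, k_range = lst$k_range,
                  restarts = lst$restarts, margin = lst$margin %||% 0,
                  out_dir = lst$out_dir)
}

#' Run the full typing pipeline
#'
#' Executes simulate (population, protocols, optionally Poisson spike
#' trains) -> extract (seven parameters, responsiveness filter) -> cluster
#' (normalize, silhouette-selected k-means) -> report (group
#' characteristics, separation matrix), recording a manifest with content
#' checksums so a completed run is reproducible bit-identically from its
#' seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_run` list: `config`, `population`, `protocols`,
#'   `spikes` (Poisson mode), `params`, `responsive`, `model`, `groups`,
#'   `separation`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sub_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max - 1L, 4))
  timing <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timing[[stage]] <<- proc.time()[["elapsed"]] - t0
    val
  }

  protocols <- clock("stimuli", stimulus_protocols(seed = sub_seeds[1]))
  population <- clock("population", sample_population(
    config$archetypes, config$n_per_archetype, seed = sub_seeds[2],
    margin = config$margin))

  spikes <- NULL
  params <- clock("extract", {
    if (config$mode == "poisson") {
      spikes <- simulate_retina(population, protocols, seed = sub_seeds[3])
      extract_parameters(spikes, protocols)
    } else {
      expected_parameters(population, protocols)
    }
  })
  responsive <- responsiveness_filter(params)
  if (nrow(responsive) <= max(config$k_range)) {
    stop(sprintf("only %d responsive cells for k up to %d",
                 nrow(responsive), max(config$k_range)), call. = FALSE)
  }

  model <- clock("cluster", {
    cluster_cells(responsive, k_range = config$k_range,
                  restarts = config$restarts, seed = sub_seeds[4])
  })
  groups <- group_characteristics(responsive, model$labels)
  separation <- separation_matrix(model$data, model$labels)

  manifest <- list(
    package_version = as.character(utils::packageVersion("rgctyper")),
    seed = config$seed, mode = config$mode,
    n_cells = nrow(population), n_responsive = nrow(responsive),
    selected_k = model$k, mean_silhouette = model$mean_silhouette,
    checksums = list(
      population = rlang::hash(population),
      params = rlang::hash(params),
      labels = rlang::hash(model$labels),
      separation = rlang::hash(separation)
    ),
    timing_s = as.list(timing)
  )

  run <- list(config = config, population = population, protocols = protocols,
              spikes = spikes, params = params, responsive = responsive,
              model = model, groups = groups, separation = separation,
              manifest = manifest)
  class(run) <- "pipeline_run"
  if (!is.null(config$out_dir)) write_pipeline_outputs(run, config$out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d cells (%d responsive), selected k = %d, mean silhouette %.3f\n",
              x$manifest$n_cells, x$manifest$n_responsive,
              x$manifest$selected_k, x$manifest$mean_silhouette))
  invisible(x)
}

write_pipeline_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pn in names(run$protocols)) {
    write_event_log(run$protocols[[pn]], file.path(dir, paste0(pn, ".tsv")))
  }
  if (!is.null(run$spikes)) {
    write_spikes(run$spikes, file.path(dir, "spikes.csv"))
  }
  write_parameters(run$params, file.path(dir, "parameters.csv"))
  readr::write_csv(
    tibble::tibble(cell_id = run$model$cell_id, cluster = run$model$labels),
    file.path(dir, "clusters.csv"))
  readr::write_csv(run$groups, file.path(dir, "group_characteristics.csv"))
  readr::write_csv(run$model$per_k, file.path(dir, "silhouette_by_k.csv"))
  utils::write.csv(run$separation, file.path(dir, "separation_matrix.csv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write / read spike tables
#'
#' CSV with columns `cell_id`, `protocol`, `time_s`; floats round-trip at
#' full precision.
#'
#' @param spikes Spike tibble.
#' @param path File path.
#' @return The tibble (invisibly for the writer).
#' @export
write_spikes <- function(spikes, path) {
  readr::write_csv(spikes[, c("cell_id", "protocol", "time_s")], path)
  invisible(spikes)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  out <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_integer(), protocol = readr::col_character(),
    time_s = readr::col_double()), progress = FALSE))
  pr <- readr::problems(out)
  if (nrow(pr) > 0) {
    stop(sprintf("malformed spike table '%s': %s at line %d", path,
                 pr$expected[1], pr$row[1]), call. = FALSE)
  }
  out
}

#' Write / read parameter tables
#'
#' @param params Parameter tibble.
#' @param path File path.
#' @return The tibble (invisibly for the writer).
#' @export
write_parameters <- function(params, path) {
  readr::write_csv(params, path)
  invisible(params)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  out <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_integer(),
    archetype = readr::col_character(),
    polarity_call = readr::col_character(),
    .default = readr::col_guess()), progress = FALSE))
  pr <- readr::problems(out)
  if (nrow(pr) > 0) {
    stop(sprintf("malformed parameter table '%s': %s at line %d", path,
                 pr$expected[1], pr$row[1]), call. = FALSE)
  }
  out
}
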
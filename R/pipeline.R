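pipeline_stages <- c("simulate", "mask", "fit", "project", "metrics",
                     "partition", "report")

#' Configure a full uncertainty experiment
#'
#' One configuration object drives the whole pipeline; every downstream
#' seed is derived deterministically from `seed`, so two runs of the same
#' config are identical.
#'
#' @param n_rows,n_cols,cell_size_km Grid specification.
#' @param corr_length Spatial correlation length of baseline climate noise
#'   (cells).
#' @param design A [scenario_design()]; default
#'   [default_scenario_design()] (5 GCMs x 4 RCPs, 14 combos, 2 periods).
#' @param effects A [scenario_effects()] perturbation configuration.
#' @param n_species Number of virtual species.
#' @param taxon_mix,prevalence_range,breadth_frac_range Passed to
#'   [simulate_species()].
#' @param taxon_buffer_km Taxon to buffer/dispersal distance mapping (km).
#' @param algorithms,n_repetitions,n_absences SDM settings.
#' @param tss_thresholds TSS retention policies compared by the threshold
#'   sensitivity analysis; metrics and partitions are computed per policy.
#' @param n_regions Number of synthetic sub-regions.
#' @param n_range_bins Number of log-range-size bins.
#' @param pixel_metrics,region_metrics,per_pixel_partition Stage switches.
#' @param delta_beta_semantics `"whittaker"` or `"literal"`.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @seealso [demo_config()] for the shipped desk-scale configuration,
#'   [run_experiment()].
#' @export
experiment_config <- function(n_rows = 15, n_cols = 20, cell_size_km = 100,
                              corr_length = 3,
                              design = default_scenario_design(),
                              effects = scenario_effects(),
                              n_species = 20,
                              taxon_mix = c(amphibian = 1 / 3, bird = 1 / 3, mammal = 1 / 3),
                              prevalence_range = c(0.05, 0.30),
                              breadth_frac_range = c(0.25, 0.6),
                              taxon_buffer_km = default_taxon_buffer_km(),
                              algorithms = sdm_algorithms,
                              n_repetitions = 4,
                              n_absences = NULL,
                              tss_thresholds = c(0.4, 0.6, 0.7),
                              n_regions = 4,
                              n_range_bins = 3,
                              pixel_metrics = TRUE,
                              region_metrics = TRUE,
                              per_pixel_partition = TRUE,
                              delta_beta_semantics = "whittaker",
                              seed = 1) {
  stopifnot(inherits(design, "scenario_design"), inherits(effects, "scenario_effects"))
  if (!all(tss_thresholds >= -1 & tss_thresholds <= 1)) {
    stop_invalid("`tss_thresholds` must lie in [-1, 1]")
  }
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols, cell_size_km = cell_size_km,
      corr_length = corr_length, design = design, effects = effects,
      n_species = n_species, taxon_mix = taxon_mix,
      prevalence_range = prevalence_range,
      breadth_frac_range = breadth_frac_range,
      taxon_buffer_km = taxon_buffer_km,
      algorithms = algorithms, n_repetitions = n_repetitions,
      n_absences = n_absences, tss_thresholds = sort(tss_thresholds),
      n_regions = n_regions, n_range_bins = n_range_bins,
      pixel_metrics = pixel_metrics, region_metrics = region_metrics,
      per_pixel_partition = per_pixel_partition,
      delta_beta_semantics = delta_beta_semantics,
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Desk-scale demonstration configuration
#'
#' A complete experiment small enough to run end-to-end in minutes:
#' 20 species on a 15 x 20 grid with a 2-GCM x 2-RCP x 1-period ensemble.
#'
#' @param seed Master seed.
#' @return An `experiment_config`.
#' @export
demo_config <- function(seed = 1) {
  experiment_config(
    n_rows = 15, n_cols = 20, n_species = 20,
    design = scenario_design(
      gcm_ids = c("GCM-A", "GCM-B"),
      rcp_ids = c("RCP2.6", "RCP8.5"),
      periods = "2041-2060"
    ),
    tss_thresholds = c(0.4, 0.6, 0.7),
    seed = seed
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    paste0("<experiment_config> %d x %d grid, %d species, ",
           "%d combos x %d periods, seed %d\n"),
    x$n_rows, x$n_cols, x$n_species, nrow(x$design$combos),
    length(x$design$periods), x$seed
  ))
  invisible(x)
}

#' Closed-form projection counts for a design
#'
#' Per-species future projections = algorithms x repetitions x
#' (GCM, RCP) combinations x periods, assuming no dropped models; the
#' total multiplies by the species count.
#'
#' @param n_algorithms,n_repetitions,n_combos,n_periods,n_species Design
#'   dimensions, or supply `config`.
#' @param config Optionally an [experiment_config()] from which all
#'   dimensions are taken.
#' @return List with `per_species` and `total`.
#' @export
#' @examples
#' expected_projection_count(4, 4, 14, 2, 11495)
expected_projection_count <- function(n_algorithms = NULL, n_repetitions = NULL,
                                      n_combos = NULL, n_periods = NULL,
                                      n_species = 1, config = NULL) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "experiment_config"))
    n_algorithms <- length(config$algorithms)
    n_repetitions <- config$n_repetitions
    n_combos <- nrow(config$design$combos)
    n_periods <- length(config$design$periods)
    n_species <- config$n_species
  }
  per_species <- n_algorithms * n_repetitions * n_combos * n_periods
  list(per_species = per_species, total = per_species * n_species)
}

stage_requires <- list(
  simulate = character(),
  mask = "simulate",
  fit = "simulate",
  project = c("fit", "mask"),
  metrics = "project",
  partition = "metrics",
  report = "partition"
)

stage_provides <- list(
  simulate = c("grid", "current", "cube", "species", "regions"),
  mask = "domains",
  fit = "fits",
  project = "cubes",
  metrics = c("species_records", "pixel_records", "region_records"),
  partition = c("partitions", "bin_partitions", "threshold_comparison",
                "pixel_partition"),
  report = "manifest"
)

#' Run one pipeline stage
#'
#' Stages (`simulate`, `mask`, `fit`, `project`, `metrics`, `partition`,
#' `report`) are re-runnable individually: each takes the accumulated
#' `state`, checks its upstream artifacts, and returns the state with its
#' own outputs added. All randomness derives from `config$seed`, so
#' re-running a stage with unchanged inputs reproduces its outputs
#' exactly.
#'
#' @param stage Stage name.
#' @param config An [experiment_config()].
#' @param state Named list of artifacts from earlier stages.
#' @param outdir Output directory (used by `report`; `NULL` skips writing).
#' @return The updated state list.
#' @export
run_stage <- function(stage, config, state = list(), outdir = NULL) {
  stage <- match.arg(stage, pipeline_stages)
  stopifnot(inherits(config, "experiment_config"))
  missing_stage <- stage_requires[[stage]][!vapply(
    stage_requires[[stage]],
    function(s) all(stage_provides[[s]] %in% names(state)), logical(1)
  )]
  if (length(missing_stage)) {
    abort(sprintf(
      "stage '%s' needs outputs of stage '%s'; run that stage first",
      stage, missing_stage[1]
    ), class = "bioscen_missing_stage")
  }
  switch(stage,
    simulate = {
      state$grid <- make_grid(config$n_rows, config$n_cols, config$cell_size_km)
      state$current <- simulate_current_climate(
        state$grid, corr_length = config$corr_length,
        seed = derive_seed(config$seed, "climate")
      )
      state$cube <- simulate_scenario_climate(
        state$current, config$design, config$effects,
        seed = derive_seed(config$seed, "scenarios")
      )
      state$species <- simulate_species(
        state$current, config$n_species,
        taxon_mix = config$taxon_mix,
        prevalence_range = config$prevalence_range,
        breadth_frac_range = config$breadth_frac_range,
        seed = derive_seed(config$seed, "species")
      )
      state$regions <- assign_regions(state$grid, config$n_regions)
      state
    },
    mask = {
      state$domains <- tibble::tibble(
        species_id = state$species$species_id,
        no_dispersal = purrr::map(state$species$true_range,
                                  function(r) no_dispersal_mask(r)$cells),
        domain = purrr::map2(
          state$species$true_range, state$species$taxon,
          function(rng, tx) {
            limited_dispersal_mask(
              rng, state$grid, config$taxon_buffer_km[[tx]]
            )$cells
          }
        )
      )
      state
    },
    fit = {
      state$fits <- fit_ensemble(
        state$species, state$current,
        taxon_buffer_km = config$taxon_buffer_km,
        algorithms = config$algorithms,
        n_repetitions = config$n_repetitions,
        n_absences = config$n_absences,
        seed = derive_seed(config$seed, "sdm")
      )
      state
    },
    project = {
      base <- project_ensemble(
        state$fits, state$cube,
        threshold = min(config$tss_thresholds),
        domains = state$domains[c("species_id", "domain")]
      )
      state$cubes <- setNames(
        purrr::map(config$tss_thresholds, function(th) {
          filter_projection_cube(base, th)
        }),
        as.character(config$tss_thresholds)
      )
      state
    },
    metrics = {
      state$species_records <- purrr::map(state$cubes, species_sensitivity)
      state$pixel_records <- if (config$pixel_metrics) {
        purrr::map(state$cubes, pixel_sensitivity)
      }
      state$region_records <- if (config$region_metrics) {
        purrr::map(state$cubes, function(pc) {
          dplyr::bind_rows(
            region_delta_beta_s(pc, state$regions, "limited_dispersal",
                                semantics = config$delta_beta_semantics),
            region_delta_beta_s(pc, state$regions, "no_dispersal",
                                semantics = config$delta_beta_semantics)
          )
        })
      }
      state
    },
    partition = {
      main_th <- as.character(max(config$tss_thresholds))
      recs <- state$species_records[[main_th]]
      state$partitions <- dplyr::bind_rows(purrr::imap(
        list(ccs = "ccs", lcs = "lcs"),
        function(metric, nm) {
          fit <- safe_partition(recs, metric, "nested")
          if (is.null(fit)) return(NULL)
          dplyr::mutate(partition_to_rows(fit), metric = nm, .before = 1)
        }
      ))
      bins <- bin_by_range_size(state$species, config$n_range_bins)
      state$bin_partitions <- dplyr::bind_rows(
        partition_by_range_bin(recs, bins, "ccs"),
        partition_by_range_bin(recs, bins, "lcs")
      )
      state$threshold_comparison <- dplyr::bind_rows(
        threshold_sensitivity(state$species_records, "ccs"),
        threshold_sensitivity(state$species_records, "lcs")
      )
      state$pixel_partition <- if (config$per_pixel_partition &&
                                     !is.null(state$pixel_records)) {
        partition_per_pixel(state$pixel_records[[main_th]], "delta_alpha")
      }
      state
    },
    report = {
      state$manifest <- build_manifest(config, state)
      if (!is.null(outdir)) write_outputs(config, state, outdir)
      state
    }
  )
}

#' Run the whole experiment
#'
#' Executes all stages in order. With `outdir` set, the report stage writes
#' every table as CSV plus a JSON run manifest and a YAML echo of the
#' configuration.
#'
#' @param config An [experiment_config()].
#' @param outdir Optional output directory.
#' @return The final state list (see [run_stage()] for its artifacts).
#' @export
run_experiment <- function(config, outdir = NULL) {
  state <- list()
  for (stage in pipeline_stages) {
    state <- run_stage(stage, config, state, outdir = outdir)
  }
  state
}

build_manifest <- function(config, state) {
  main_th <- as.character(max(config$tss_thresholds))
  base_th <- as.character(min(config$tss_thresholds))
  counts <- expected_projection_count(config = config)
  retained <- vapply(state$cubes, function(pc) sum(pc$models$retained), numeric(1))
  list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    tool_version = as.character(utils::packageVersion("bioscen")),
    counts = list(
      species_requested = config$n_species,
      species_retained = nrow(state$species),
      models_attempted = nrow(state$fits$models),
      models_converged = sum(state$fits$models$status == "ok"),
      models_retained_per_threshold = as.list(retained),
      projections_produced = nrow(state$cubes[[base_th]]$projections),
      future_projections_produced = sum(
        state$cubes[[base_th]]$projections$layer == "future"
      ),
      expected_future_per_species_no_drops = counts$per_species,
      expected_future_total_no_drops = counts$total,
      species_records_excluded = attr(state$species_records[[main_th]],
                                      "n_excluded") %||% 0L
    )
  )
}

write_outputs <- function(config, state, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  main_th <- as.character(max(config$tss_thresholds))
  w <- function(x, name) {
    if (!is.null(x) && nrow(x)) {
      utils::write.csv(x, file.path(outdir, name), row.names = FALSE)
    }
  }
  w(dplyr::select(state$fits$models, -"fit"), "model_scores.csv")
  w(dplyr::bind_rows(purrr::imap(
    state$species_records,
    function(r, th) dplyr::mutate(r, threshold = as.numeric(th), .before = 1)
  )), "species_metrics.csv")
  if (!is.null(state$pixel_records)) {
    w(state$pixel_records[[main_th]], "pixel_metrics.csv")
  }
  if (!is.null(state$region_records)) {
    w(state$region_records[[main_th]], "region_metrics.csv")
  }
  w(state$partitions, "partitions.csv")
  w(state$bin_partitions, "range_bin_partitions.csv")
  w(state$threshold_comparison, "threshold_comparison.csv")
  if (!is.null(state$pixel_partition)) {
    w(state$pixel_partition, "pixel_partition.csv")
  }
  w(dplyr::select(state$species, -"optimum", -"breadth", -"true_range"),
    "species.csv")
  w(state$regions, "regions.csv")
  jsonlite::write_json(state$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- unclass(config)
  cfg$design <- list(
    gcm_ids = config$design$gcm_ids, rcp_ids = config$design$rcp_ids,
    combos = as.data.frame(config$design$combos),
    periods = config$design$periods
  )
  cfg$effects <- lapply(unclass(config$effects), unname)
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  invisible(NULL)
}
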
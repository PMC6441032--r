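#' Fit the SDM ensemble for a set of species
#'
#' For every species: samples pseudo-absences within its taxon's buffer and
#' fits every algorithm under `n_repetitions` random 70/30 split-sample
#' repetitions (the split is shared across algorithms within a repetition),
#' scoring each fit with the true skill statistic on the hold-out.
#' Non-converging or single-class fits are dropped (never imputed) and
#' logged with `status = "failed"`, so the downstream design may be
#' unbalanced.
#'
#' @param species A [simulate_species()] tibble.
#' @param current Baseline `climate_layers`.
#' @param taxon_buffer_km Named taxon to buffer-distance (km) mapping used
#'   for absence sampling.
#' @param algorithms Subset of `c("GLM", "GAM", "BRT", "RF")`.
#' @param n_repetitions Number of split-sample repetitions (default 4).
#' @param n_absences Pseudo-absence count (`NULL` = `min(10 x presences,
#'   buffer cells)`).
#' @param seed Master seed; per-species and per-repetition seeds derive
#'   from it.
#' @return An `sdm_fits` object: `models` tibble (one row per attempted
#'   fit: `species_id`, `taxon`, `algorithm`, `repetition`, `tss_score`,
#'   `cutoff`, `status`, list-column `fit`) and the `species` table.
#' @export
fit_ensemble <- function(species, current,
                         taxon_buffer_km = default_taxon_buffer_km(),
                         algorithms = sdm_algorithms,
                         n_repetitions = 4,
                         n_absences = NULL,
                         seed = 1) {
  stopifnot(inherits(current, "climate_layers"), is.data.frame(species))
  if (nrow(species) == 0) stop_invalid("no species supplied")
  if (any(species$range_size < 20)) stop_invalid("all species must have >= 20 presence cells")
  algorithms <- match.arg(algorithms, sdm_algorithms, several.ok = TRUE)

  models <- purrr::map(seq_len(nrow(species)), function(i) {
    sp <- species[i, ]
    buffer_km <- taxon_buffer_km[[sp$taxon]]
    if (is.null(buffer_km) || is.na(buffer_km)) {
      stop_invalid(sprintf("no buffer distance configured for taxon '%s'", sp$taxon))
    }
    training <- build_training_set(
      sp, current, buffer_km,
      n_absences = n_absences,
      seed = derive_seed(seed, paste0("absence:", sp$species_id))
    )
    purrr::map(seq_len(n_repetitions), function(rep) {
      rep_seed <- derive_seed(seed, sprintf("rep:%s:%d", sp$species_id, rep))
      purrr::map(algorithms, function(alg) {
        fit <- tryCatch(
          fit_sdm(training, alg, repetition_seed = rep_seed),
          error = function(e) e
        )
        if (inherits(fit, "error")) {
          warn(sprintf(
            "%s %s rep %d failed and is excluded: %s",
            sp$species_id, alg, rep, conditionMessage(fit)
          ))
          tibble::tibble(
            species_id = sp$species_id, taxon = sp$taxon, algorithm = alg,
            repetition = rep, tss_score = NA_real_, cutoff = NA_real_,
            status = "failed", fit = list(NULL)
          )
        } else {
          tibble::tibble(
            species_id = sp$species_id, taxon = sp$taxon, algorithm = alg,
            repetition = rep, tss_score = fit$tss_score, cutoff = fit$cutoff,
            status = "ok", fit = list(fit)
          )
        }
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  structure(
    list(models = models, species = species,
         grid = attr(current, "grid"), seed = seed),
    class = "sdm_fits"
  )
}

#' @export
print.sdm_fits <- function(x, ...) {
  cat(sprintf(
    "<sdm_fits> %d species, %d/%d fits converged, mean TSS = %.3f\n",
    nrow(x$species), sum(x$models$status == "ok"), nrow(x$models),
    mean(x$models$tss_score, na.rm = TRUE)
  ))
  invisible(x)
}

#' Project a fitted ensemble onto a climate cube
#'
#' Filters fitted models by the TSS retention threshold and projects every
#' retained model onto the current layers and every (GCM, RCP, period)
#' layer, restricted to each species' limited-dispersal domain. Species
#' with zero retained models are excluded with a warning.
#'
#' @param fits An [fit_ensemble()] object.
#' @param cube A [simulate_scenario_climate()] climate cube.
#' @param threshold TSS retention threshold; models with
#'   `tss_score < threshold` are dropped.
#' @param domains Optional tibble `species_id`, `domain` (list of cell
#'   indices). By default limited-dispersal masks are computed from
#'   `taxon_buffer_km`.
#' @param taxon_buffer_km Named taxon to dispersal-distance mapping used
#'   when `domains` is `NULL`.
#' @return A `projection_cube`: list with
#'   * `projections`: tibble keyed by `species_id`, `algorithm`,
#'     `repetition`, `layer` (`"current"`/`"future"`), `gcm`, `rcp`,
#'     `period`, with list-column `suitable` (cells predicted suitable
#'     within the domain);
#'   * `models`: registry with `retained` flags;
#'   * `species`: per-species `range_size`, `true_range`, `domain`,
#'     `n_retained`;
#'   * `design`, `grid`, `threshold`.
#' @export
project_ensemble <- function(fits, cube, threshold = 0.4, domains = NULL,
                             taxon_buffer_km = default_taxon_buffer_km()) {
  stopifnot(inherits(fits, "sdm_fits"), inherits(cube, "climate_cube"))
  grid <- attr(cube$current, "grid")
  if (!identical(grid, fits$grid)) stop_invalid("fits and cube are on different grids")
  if (is.null(domains)) {
    domains <- tibble::tibble(
      species_id = fits$species$species_id,
      domain = purrr::map2(fits$species$true_range, fits$species$taxon, function(rng, tx) {
        limited_dispersal_mask(rng, grid, taxon_buffer_km[[tx]])$cells
      })
    )
  }

  models <- dplyr::mutate(
    fits$models,
    retained = .data$status == "ok" & !is.na(.data$tss_score) & .data$tss_score >= threshold
  )

  per_species <- purrr::map(seq_len(nrow(fits$species)), function(i) {
    sp <- fits$species[i, ]
    domain <- domains$domain[[match(sp$species_id, domains$species_id)]]
    sp_models <- dplyr::filter(models, .data$species_id == sp$species_id)
    kept <- dplyr::filter(sp_models, .data$retained)
    if (nrow(kept) == 0) {
      warn(sprintf(
        "species %s: no model reached TSS >= %g; excluded from projections",
        sp$species_id, threshold
      ))
    }

    # one stacked frame over current + all scenario layers restricted to
    # the domain: a single predict() call per retained model
    dom_current <- cube$current[match(domain, cube$current$cell), c("cell", climate_vars)]
    stack <- dplyr::bind_rows(
      dplyr::bind_cols(
        tibble::tibble(layer = "current", gcm = NA_character_,
                       rcp = NA_character_, period = NA_character_),
        dom_current
      ),
      dplyr::bind_cols(
        tibble::tibble(layer = "future"),
        cube$future[cube$future$cell %in% domain,
                    c("gcm", "rcp", "period", "cell", climate_vars)]
      )
    )

    projections <- purrr::map(seq_len(nrow(kept)), function(j) {
      fit <- kept$fit[[j]]
      score <- predict_suitability(fit$model, fit$algorithm, stack)
      suit <- score >= fit$cutoff
      tibble::tibble(
        layer = stack$layer, gcm = stack$gcm, rcp = stack$rcp,
        period = stack$period, cell = stack$cell, suitable = suit
      ) |>
        dplyr::group_by(.data$layer, .data$gcm, .data$rcp, .data$period) |>
        dplyr::summarise(suitable = list(.data$cell[.data$suitable]), .groups = "drop") |>
        dplyr::mutate(
          species_id = sp$species_id, taxon = sp$taxon,
          algorithm = kept$algorithm[[j]], repetition = kept$repetition[[j]],
          .before = 1
        )
    }) |> dplyr::bind_rows()

    list(
      projections = projections,
      species = tibble::tibble(
        species_id = sp$species_id, taxon = sp$taxon,
        range_size = sp$range_size, true_range = sp$true_range,
        domain = list(domain), n_retained = nrow(kept)
      )
    )
  })

  structure(
    list(
      projections = dplyr::bind_rows(purrr::map(per_species, "projections")),
      models = dplyr::select(models, -"fit"),
      species = dplyr::bind_rows(purrr::map(per_species, "species")),
      design = cube$design,
      grid = grid,
      threshold = threshold
    ),
    class = "projection_cube"
  )
}

#' Fit, filter and project the full SDM ensemble in one call
#'
#' Convenience wrapper around [fit_ensemble()] and [project_ensemble()].
#'
#' @inheritParams fit_ensemble
#' @inheritParams project_ensemble
#' @param cube A [simulate_scenario_climate()] climate cube; its current
#'   layers are the calibration climate.
#' @return A `projection_cube` (see [project_ensemble()]).
#' @export
#' @examples
#' \donttest{
#' g <- make_grid(12, 12)
#' cur <- simulate_current_climate(g, seed = 1)
#' cube <- simulate_scenario_climate(
#'   cur, scenario_design(c("G1", "G2"), c("RCP2.6", "RCP8.5"),
#'                        periods = "2041-2060"),
#'   seed = 2
#' )
#' sp <- simulate_species(cur, 2, seed = 3)
#' pc <- run_ensemble(sp, cube, threshold = -1, n_repetitions = 2,
#'                    algorithms = "GLM", seed = 4)
#' glance(pc)
#' }
run_ensemble <- function(species, cube,
                         taxon_buffer_km = default_taxon_buffer_km(),
                         threshold = 0.4,
                         algorithms = sdm_algorithms,
                         n_repetitions = 4,
                         n_absences = NULL,
                         seed = 1) {
  fits <- fit_ensemble(
    species, cube$current,
    taxon_buffer_km = taxon_buffer_km, algorithms = algorithms,
    n_repetitions = n_repetitions, n_absences = n_absences, seed = seed
  )
  project_ensemble(fits, cube, threshold = threshold,
                   taxon_buffer_km = taxon_buffer_km)
}

#' @export
print.projection_cube <- function(x, ...) {
  cat(sprintf(
    "<projection_cube> %d species, %d retained models, %d projections (TSS >= %g)\n",
    nrow(x$species), sum(x$models$retained), nrow(x$projections), x$threshold
  ))
  invisible(x)
}

#' Re-filter a projection cube at a stricter TSS threshold
#'
#' Raising the threshold never adds models, so record sets for several
#' thresholds can be derived from one fitted ensemble projected at the most
#' permissive threshold.
#'
#' @param cube A `projection_cube`.
#' @param threshold New TSS threshold, `>=` the cube's own.
#' @return A `projection_cube` containing only models with
#'   `tss_score >= threshold`.
#' @export
filter_projection_cube <- function(cube, threshold) {
  stopifnot(inherits(cube, "projection_cube"))
  if (threshold < cube$threshold) {
    stop_invalid("cannot lower the threshold below the projected cube's threshold")
  }
  models <- dplyr::mutate(
    cube$models,
    retained = .data$retained & !is.na(.data$tss_score) & .data$tss_score >= threshold
  )
  keep <- dplyr::select(
    dplyr::filter(models, .data$retained),
    "species_id", "algorithm", "repetition"
  )
  projections <- dplyr::semi_join(
    cube$projections, keep, by = c("species_id", "algorithm", "repetition")
  )
  species <- dplyr::mutate(
    cube$species,
    n_retained = vapply(.data$species_id, function(id) {
      sum(keep$species_id == id)
    }, numeric(1))
  )
  structure(
    list(
      projections = projections, models = models, species = species,
      design = cube$design, grid = cube$grid, threshold = threshold
    ),
    class = "projection_cube"
  )
}
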
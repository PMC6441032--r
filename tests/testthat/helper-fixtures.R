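# shared in-code fixtures; everything is generated at test time

toy_grid <- function(n = 20) make_grid(n, n)

toy_climate <- function(n = 20, seed = 1, corr_length = 2) {
  simulate_current_climate(toy_grid(n), corr_length = corr_length, seed = seed)
}

# training table with disjoint climate supports: every algorithm should
# separate it perfectly
separable_training <- function(n_pres = 40, n_abs = 80, seed = 1, id = "toy") {
  withr::with_seed(seed, {
    pres <- tibble::tibble(
      mean_temp = rnorm(n_pres, 22, 0.8), temp_range = rnorm(n_pres, 9, 0.6),
      precip_sum = rnorm(n_pres, 1500, 40), precip_cv = rnorm(n_pres, 25, 1.2)
    )
    abs <- tibble::tibble(
      mean_temp = rnorm(n_abs, 5, 0.8), temp_range = rnorm(n_abs, 20, 0.6),
      precip_sum = rnorm(n_abs, 500, 40), precip_cv = rnorm(n_abs, 60, 1.2)
    )
    out <- dplyr::bind_cols(
      tibble::tibble(
        cell = seq_len(n_pres + n_abs),
        label = rep(c(1L, 0L), c(n_pres, n_abs))
      ),
      dplyr::bind_rows(pres, abs)
    )
    attr(out, "species_id") <- id
    attr(out, "buffer_km") <- 2000
    out
  })
}

# hand-built projection cube: one species list and explicit suitable sets
# per (species, algorithm, repetition, scenario); exercises the metric layer
# without fitting any model
toy_projection_cube <- function(species, projections, grid,
                                design = scenario_design("G1", "R1", periods = "p1")) {
  structure(
    list(
      projections = projections,
      models = dplyr::distinct(projections, species_id, algorithm, repetition) |>
        dplyr::mutate(tss_score = 1, cutoff = 0.5, status = "ok", retained = TRUE),
      species = species,
      design = design,
      grid = grid,
      threshold = 0.4
    ),
    class = "projection_cube"
  )
}

# one projection row
proj_row <- function(species_id, taxon, algorithm, repetition, layer,
                     suitable, gcm = NA_character_, rcp = NA_character_,
                     period = NA_character_) {
  tibble::tibble(
    species_id = species_id, taxon = taxon, algorithm = algorithm,
    repetition = repetition, layer = layer, gcm = gcm, rcp = rcp,
    period = period, suitable = list(as.integer(suitable))
  )
}

toy_species_row <- function(species_id, taxon, true_range, domain) {
  tibble::tibble(
    species_id = species_id, taxon = taxon,
    range_size = length(true_range),
    true_range = list(as.integer(true_range)),
    domain = list(as.integer(domain)),
    n_retained = 1
  )
}

# brute-force sequential nested SS via group means; valid on designs that
# are balanced within each SDM block (gcm x rcp complete), the shape used
# by the oracle-equivalence checks
oracle_nested_ss <- function(tab) {
  y <- tab$value
  tot <- sum((y - mean(y))^2)
  ss_sdm <- sum(tapply(y, tab$sdm, function(v) length(v) * (mean(v) - mean(y))^2))
  ss_gcm <- 0
  ss_rcp <- 0
  for (s in unique(tab$sdm)) {
    ys <- y[tab$sdm == s]
    gs <- tab$gcm[tab$sdm == s]
    rs <- tab$rcp[tab$sdm == s]
    ss_gcm <- ss_gcm + sum(tapply(ys, gs, function(v) length(v) * (mean(v) - mean(ys))^2))
    ss_rcp <- ss_rcp + sum(tapply(ys, rs, function(v) length(v) * (mean(v) - mean(ys))^2))
  }
  c(sdm = ss_sdm, gcm = ss_gcm, rcp = ss_rcp,
    residual = tot - ss_sdm - ss_gcm - ss_rcp)
}

# brute-force classical main-effect SS on balanced crossed designs
oracle_factorial_ss <- function(tab) {
  y <- tab$value
  tot <- sum((y - mean(y))^2)
  main <- function(f) sum(tapply(y, f, function(v) length(v) * (mean(v) - mean(y))^2))
  ss <- c(sdm = main(tab$sdm), gcm = main(tab$gcm), rcp = main(tab$rcp))
  c(ss, residual = tot - sum(ss))
}
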
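climate_vars <- c("mean_temp", "temp_range", "precip_sum", "precip_cv")

# variables that perturb multiplicatively under scenarios (precipitation-like);
# temperature-like variables perturb additively
multiplicative_vars <- c("precip_sum", "precip_cv")

new_climate_layers <- function(values, grid) {
  out <- dplyr::bind_cols(cell_coords(grid), tibble::as_tibble(values))
  attr(out, "grid") <- grid
  class(out) <- c("climate_layers", class(out))
  out
}

#' @export
print.climate_layers <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<climate_layers> on a %d x %d grid\n", g$n_rows, g$n_cols))
  NextMethod()
}

# Gaussian random field on the grid: white noise smoothed with a separable
# Gaussian kernel of scale `corr_length` (in cells), rescaled to sd = 1.
# corr_length = 0 returns plain white noise.
gaussian_field <- function(n_rows, n_cols, corr_length) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (corr_length > 0) {
    k <- function(n) {
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      w <- exp(-d^2 / (2 * corr_length^2))
      sweep(w, 1L, rowSums(w), "/")
    }
    z <- k(n_rows) %*% z %*% t(k(n_cols))
  }
  s <- sd(as.vector(z))
  if (s > 0) z <- z / s
  z - mean(z)
}

default_noise_sd <- c(mean_temp = 1.5, temp_range = 1.5, precip_sum = 150, precip_cv = 8)

#' Simulate baseline (current-period) climate layers
#'
#' Generates the four bioclimatic variables used throughout the pipeline --
#' annual mean temperature (degC), annual temperature range (degC), annual
#' precipitation sum (mm) and precipitation seasonality (CV, %) -- as smooth
#' planar gradients plus spatially autocorrelated Gaussian noise. The
#' gradients mimic a latitudinal temperature decline and longitudinal
#' moisture/seasonality contrasts; they carry no claim of matching real-world
#' marginal distributions.
#'
#' @param grid A [make_grid()] object.
#' @param corr_length Correlation length of the noise field, in cells
#'   (0 = white noise).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param noise_sd Named numeric vector of per-variable noise standard
#'   deviations (variable units).
#' @return A `climate_layers` tibble: one row per cell with columns `cell`,
#'   `row`, `col`, `x_km`, `y_km` and the four climate variables.
#'   `precip_sum` and `precip_cv` are clipped at 0.
#' @export
#' @examples
#' cl <- simulate_current_climate(make_grid(10, 10), corr_length = 2, seed = 1)
#' dplyr::glimpse(cl)
simulate_current_climate <- function(grid, corr_length = 3, seed = 1,
                                     noise_sd = default_noise_sd) {
  stopifnot(inherits(grid, "bioscen_grid"))
  if (corr_length < 0) stop_invalid("`corr_length` must be >= 0")
  noise_sd <- noise_sd[climate_vars]
  if (anyNA(noise_sd)) stop_invalid("`noise_sd` must name all four climate variables")
  nr <- grid$n_rows
  nc <- grid$n_cols
  rfrac <- if (nr > 1) (rep(seq_len(nr), each = nc) - 1) / (nr - 1) else rep(0, nc)
  cfrac <- if (nc > 1) (rep(seq_len(nc), times = nr) - 1) / (nc - 1) else rep(0, nr)

  base <- list(
    mean_temp = 25 - 30 * rfrac + 2 * cfrac,     # warm "equatorial" edge at row 1
    temp_range = 8 + 18 * rfrac + 4 * cfrac,     # more continental toward high rows/cols
    precip_sum = 1800 - 1400 * rfrac - 300 * cfrac,
    precip_cv = 20 + 60 * cfrac + 10 * rfrac
  )

  vals <- with_seed(seed, {
    lapply(setNames(climate_vars, climate_vars), function(v) {
      noise <- if (noise_sd[[v]] > 0) {
        noise_sd[[v]] * as.vector(t(gaussian_field(nr, nc, corr_length)))
      } else {
        0
      }
      x <- base[[v]] + noise
      if (v %in% multiplicative_vars) x <- pmax(x, 0)
      x
    })
  })
  new_climate_layers(vals, grid)
}

#' Describe the scenario factorial design
#'
#' A scenario design names the GCM ensemble members, the RCP forcing
#' pathways ordered by emission severity, the (GCM, RCP) combinations that
#' were actually run (CMIP5-style ensembles are rarely the full factorial),
#' and the future time horizons.
#'
#' @param gcm_ids Character vector of GCM labels.
#' @param rcp_ids Character vector of RCP labels, ordered from least to most
#'   severe.
#' @param combos A data frame with columns `gcm`, `rcp` listing the runs
#'   available; defaults to the full factorial.
#' @param periods Character vector of future period labels, in time order.
#' @return A `scenario_design` object.
#' @seealso [default_scenario_design()] for the 5-GCM, 4-RCP, 14-combination
#'   ensemble layout used as the package default.
#' @export
scenario_design <- function(gcm_ids, rcp_ids,
                            combos = NULL,
                            periods = c("2041-2060", "2061-2080")) {
  gcm_ids <- as.character(gcm_ids)
  rcp_ids <- as.character(rcp_ids)
  if (length(gcm_ids) < 1 || length(rcp_ids) < 1 || length(periods) < 1) {
    stop_invalid("need at least one GCM, one RCP and one period")
  }
  if (anyDuplicated(gcm_ids) || anyDuplicated(rcp_ids) || anyDuplicated(periods)) {
    stop_invalid("GCM, RCP and period labels must be unique")
  }
  if (is.null(combos)) {
    combos <- tidyr::expand_grid(gcm = gcm_ids, rcp = rcp_ids)
  }
  combos <- tibble::as_tibble(combos)[c("gcm", "rcp")]
  if (nrow(combos) == 0) stop_invalid("`combos` must contain at least one (gcm, rcp) pair")
  if (!all(combos$gcm %in% gcm_ids) || !all(combos$rcp %in% rcp_ids)) {
    stop_invalid("`combos` must be a subset of gcm_ids x rcp_ids")
  }
  if (anyDuplicated(combos)) stop_invalid("duplicate (gcm, rcp) combinations")
  structure(
    list(
      gcm_ids = gcm_ids,
      rcp_ids = rcp_ids,
      combos = combos,
      periods = as.character(periods)
    ),
    class = "scenario_design"
  )
}

#' @export
print.scenario_design <- function(x, ...) {
  cat(sprintf(
    "<scenario_design> %d GCMs x %d RCPs (%d combos) x %d periods\n",
    length(x$gcm_ids), length(x$rcp_ids), nrow(x$combos), length(x$periods)
  ))
  invisible(x)
}

#' Default 14-combination CMIP5-style scenario design
#'
#' Five GCMs and four RCPs restricted to 14 of the 20 possible pairs,
#' mirroring the unbalanced structure of real CMIP5 ensembles in which not
#' every model ran every pathway: all five GCMs ran RCP4.5 and RCP8.5, while
#' RCP2.6 and RCP6.0 are each available for two models only.
#'
#' @return A [scenario_design()] with 14 combinations and two periods.
#' @export
#' @examples
#' d <- default_scenario_design()
#' nrow(d$combos) # 14
default_scenario_design <- function() {
  gcms <- c("GCM-A", "GCM-B", "GCM-C", "GCM-D", "GCM-E")
  rcps <- c("RCP2.6", "RCP4.5", "RCP6.0", "RCP8.5")
  combos <- dplyr::bind_rows(
    tidyr::expand_grid(gcm = gcms, rcp = c("RCP4.5", "RCP8.5")),
    tidyr::expand_grid(gcm = c("GCM-A", "GCM-B"), rcp = "RCP2.6"),
    tidyr::expand_grid(gcm = c("GCM-C", "GCM-D"), rcp = "RCP6.0")
  )
  scenario_design(gcms, rcps, combos)
}

#' Configure scenario perturbation magnitudes
#'
#' Controls the ground-truth variance structure of the synthetic climate
#' ensemble. RCPs shift each variable by `rank * rcp_severity_step *
#' period_scaling` (additive in degC for temperature variables, fractional
#' for precipitation variables, per the delta-change convention); each GCM
#' contributes one smooth spatial deviation field drawn once and reused
#' across RCPs and periods, whose spatial mean has standard deviation
#' `gcm_sd`; `noise_sd` adds independent per-layer noise.
#'
#' @param rcp_severity_step Named per-variable shift per RCP severity rank
#'   (degC for temperature variables; fractional change for precipitation
#'   variables).
#' @param gcm_sd Named per-variable sd of the GCM-specific deviation
#'   (same units/convention as `rcp_severity_step`); must be >= 0.
#' @param period_scaling Numeric multiplier per period (> 0), recycled to
#'   the design's periods; later horizons usually scale harder.
#' @param spatial_corr_length Correlation length (cells) of GCM deviation
#'   patterns.
#' @param noise_sd Named per-variable sd of independent layer noise; >= 0.
#' @return A `scenario_effects` list.
#' @export
scenario_effects <- function(rcp_severity_step = c(mean_temp = 1.1, temp_range = 0.25,
                                                   precip_sum = -0.04, precip_cv = 0.02),
                             gcm_sd = c(mean_temp = 0.45, temp_range = 0.25,
                                        precip_sum = 0.03, precip_cv = 0.015),
                             period_scaling = c(1, 1.3),
                             spatial_corr_length = 5,
                             noise_sd = c(mean_temp = 0, temp_range = 0,
                                          precip_sum = 0, precip_cv = 0)) {
  rcp_severity_step <- rcp_severity_step[climate_vars]
  gcm_sd <- gcm_sd[climate_vars]
  noise_sd <- noise_sd[climate_vars]
  if (anyNA(rcp_severity_step) || anyNA(gcm_sd) || anyNA(noise_sd)) {
    stop_invalid("effect vectors must name all four climate variables")
  }
  if (any(gcm_sd < 0) || any(noise_sd < 0)) stop_invalid("`gcm_sd` and `noise_sd` must be >= 0")
  if (any(period_scaling <= 0)) stop_invalid("`period_scaling` must be > 0")
  structure(
    list(
      rcp_severity_step = rcp_severity_step,
      gcm_sd = gcm_sd,
      period_scaling = as.numeric(period_scaling),
      spatial_corr_length = spatial_corr_length,
      noise_sd = noise_sd
    ),
    class = "scenario_effects"
  )
}

#' Simulate the factorial future-climate ensemble
#'
#' Builds one future [climate layer set][simulate_current_climate] per
#' (GCM, RCP, period) combination of the design. Temperature-like variables
#' receive additive deltas, precipitation-like variables multiplicative
#' ones: `future = current + rcp_rank * step * period_scaling + gcm_dev`
#' (additive case) with the multiplicative analogue
#' `current * (1 + rank * step * scaling) * (1 + gcm_dev)`. The GCM deviation
#' field is drawn once per GCM (zero-mean smooth pattern plus a scalar
#' offset with sd `gcm_sd`) and reused across RCPs and periods, so "GCM" is
#' a coherent factor level. RCP severity rank is the 1-based position of the
#' RCP in the design's ordered `rcp_ids`.
#'
#' @param current A `climate_layers` object (the baseline).
#' @param design A [scenario_design()].
#' @param effects A [scenario_effects()] configuration.
#' @param seed Integer seed.
#' @return A `climate_cube`: list with `current` (the input) and `future`,
#'   a long tibble of per-cell climate keyed by `gcm`, `rcp`, `period`.
#' @export
#' @examples
#' g <- make_grid(8, 8)
#' cur <- simulate_current_climate(g, corr_length = 0, seed = 1)
#' cube <- simulate_scenario_climate(cur, default_scenario_design(),
#'                                   scenario_effects(), seed = 2)
#' dplyr::count(cube$future, gcm, rcp, period)
simulate_scenario_climate <- function(current, design, effects = scenario_effects(),
                                      seed = 1) {
  stopifnot(inherits(current, "climate_layers"), inherits(design, "scenario_design"))
  grid <- attr(current, "grid")
  if (nrow(design$combos) == 0) stop_invalid("scenario design has no combinations")
  nr <- grid$n_rows
  nc <- grid$n_cols
  n_per <- length(design$periods)
  scaling <- rep_len(effects$period_scaling, n_per)

  layers <- with_seed(seed, {
    # one deviation field per (gcm, variable): scalar offset + centred pattern
    gcm_dev <- lapply(setNames(design$gcm_ids, design$gcm_ids), function(g) {
      lapply(setNames(climate_vars, climate_vars), function(v) {
        s <- effects$gcm_sd[[v]]
        if (s == 0) return(rep(0, nr * nc))
        offset <- rnorm(1, 0, s)
        pattern <- s * as.vector(t(gaussian_field(nr, nc, effects$spatial_corr_length)))
        offset + pattern
      })
    })
    purrr::pmap(
      tidyr::expand_grid(design$combos, period = design$periods),
      function(gcm, rcp, period) {
        rank <- match(rcp, design$rcp_ids)
        scal <- scaling[match(period, design$periods)]
        vals <- lapply(setNames(climate_vars, climate_vars), function(v) {
          step <- effects$rcp_severity_step[[v]]
          dev <- gcm_dev[[gcm]][[v]]
          eps <- if (effects$noise_sd[[v]] > 0) {
            rnorm(nr * nc, 0, effects$noise_sd[[v]])
          } else {
            0
          }
          x <- current[[v]]
          if (v %in% multiplicative_vars) {
            pmax(x * (1 + rank * step * scal) * (1 + dev) * (1 + eps), 0)
          } else {
            x + rank * step * scal + dev + eps
          }
        })
        dplyr::bind_cols(
          tibble::tibble(gcm = gcm, rcp = rcp, period = period),
          cell_coords(grid),
          tibble::as_tibble(vals)
        )
      }
    )
  })

  structure(
    list(current = current, future = dplyr::bind_rows(layers), design = design),
    class = "climate_cube"
  )
}

#' @export
print.climate_cube <- function(x, ...) {
  g <- attr(x$current, "grid")
  cat(sprintf(
    "<climate_cube> %d x %d grid; %d future layers (%d combos x %d periods)\n",
    g$n_rows, g$n_cols,
    nrow(dplyr::distinct(x$future, .data$gcm, .data$rcp, .data$period)),
    nrow(x$design$combos), length(x$design$periods)
  ))
  invisible(x)
}

# extract one future layer as a climate_layers tibble
future_layer <- function(cube, gcm, rcp, period) {
  grid <- attr(cube$current, "grid")
  sub <- cube$future[cube$future$gcm == gcm & cube$future$rcp == rcp &
                       cube$future$period == period, , drop = FALSE]
  out <- sub[c("cell", "row", "col", "x_km", "y_km", climate_vars)]
  attr(out, "grid") <- grid
  class(out) <- c("climate_layers", class(out))
  out
}
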
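# count, per cell, how many of the supplied cell sets contain it
count_per_cell <- function(cell_sets, n_cells) {
  cells <- unlist(cell_sets, use.names = FALSE)
  if (length(cells) == 0) return(integer(n_cells))
  tabulate(cells, nbins = n_cells)
}

#' Per-cell species richness from a stack of binary maps
#'
#' @param suitable_sets List (one element per species) of integer cell
#'   indices predicted suitable.
#' @param n_cells Total number of grid cells.
#' @param domain_sets Optional list of per-species domain cells; cells
#'   covered by no species' domain are returned as `NA` (outside every
#'   modelled area the richness is undefined, not zero).
#' @return Numeric vector of length `n_cells`.
#' @export
#' @examples
#' pixel_richness(list(1:3, 2:4), n_cells = 6)
pixel_richness <- function(suitable_sets, n_cells, domain_sets = NULL) {
  if (length(suitable_sets) == 0) stop_invalid("empty species set")
  rich <- as.numeric(count_per_cell(suitable_sets, n_cells))
  if (!is.null(domain_sets)) {
    covered <- count_per_cell(domain_sets, n_cells) > 0
    rich[!covered] <- NA_real_
  }
  rich
}

#' Per-cell relative change in species richness (percent)
#'
#' `100 * (future - current) / current`, missing where current richness is
#' 0 or undefined.
#'
#' @param current_richness,future_richness Numeric richness vectors on the
#'   same grid.
#' @return Numeric percent vector.
#' @export
pixel_delta_alpha <- function(current_richness, future_richness) {
  if (length(current_richness) != length(future_richness)) {
    stop_invalid("richness maps must share the grid")
  }
  ifelse(!is.na(current_richness) & current_richness > 0,
         100 * (future_richness - current_richness) / current_richness,
         NA_real_)
}

#' Per-cell percent of species lost
#'
#' `100 * |present now, absent in future| / current richness`, evaluated
#' per species pair of current/future maps (no-dispersal view), missing
#' where current richness is 0.
#'
#' @param current_sets,future_sets Paired per-species lists of suitable
#'   cells.
#' @param n_cells Total number of grid cells.
#' @return Numeric percent vector in `[0, 100]` where defined.
#' @export
pixel_percent_loss <- function(current_sets, future_sets, n_cells) {
  if (length(current_sets) != length(future_sets)) {
    stop_invalid("current and future stacks must pair one map per species")
  }
  lost_sets <- purrr::map2(current_sets, future_sets, setdiff)
  cur <- count_per_cell(current_sets, n_cells)
  lost <- count_per_cell(lost_sets, n_cells)
  ifelse(cur > 0, 100 * lost / cur, NA_real_)
}

#' Per-cell temporal turnover
#'
#' `beta_t = (lost + gained) / (current richness + gained)`, in `[0, 1]`:
#' 0 when the community is unchanged, 1 when no currently present species
#' persists. Missing where the denominator is 0.
#'
#' @param lost,gained,current_richness Numeric per-cell count vectors.
#' @return Numeric vector in `[0, 1]` where defined.
#' @export
#' @examples
#' pixel_beta_t(2, 3, 10) # 5/13
pixel_beta_t <- function(lost, gained, current_richness) {
  if (length(lost) != length(gained) || length(lost) != length(current_richness)) {
    stop_invalid("maps must share the grid")
  }
  denom <- current_richness + gained
  ifelse(!is.na(denom) & denom > 0, (lost + gained) / denom, NA_real_)
}

# per-species presence sets for one (algorithm, repetition) under each
# dispersal assumption, current and one future design cell
presence_sets <- function(cur_rows, fut_rows, ranges) {
  cur_lim <- cur_rows$suitable
  fut_lim <- fut_rows$suitable
  cur_nd <- purrr::map2(cur_lim, ranges, intersect)
  fut_nd <- purrr::map2(fut_lim, cur_nd, intersect)
  list(cur_lim = cur_lim, fut_lim = fut_lim, cur_nd = cur_nd, fut_nd = fut_nd)
}

#' Pixel-level sensitivity table
#'
#' Stacks per-species binary projections into community metrics per grid
#' cell, taxon and design cell (algorithm x repetition x GCM x RCP x
#' period): relative richness change (`delta_alpha`, limited dispersal),
#' percent of species lost (`percent_loss`, no dispersal) and temporal
#' turnover (`beta_t`, limited dispersal). Cells where a metric's
#' denominator is 0 carry `NA`.
#'
#' @param cube A [run_ensemble()] projection cube.
#' @return A long tibble: `cell`, `taxon`, `algorithm`, `repetition`,
#'   `gcm`, `rcp`, `period`, `delta_alpha`, `percent_loss`, `beta_t`.
#'   Cells outside every species' domain are omitted.
#' @export
pixel_sensitivity <- function(cube) {
  stopifnot(inherits(cube, "projection_cube"))
  n_cell <- n_cells(cube$grid)
  ranges <- setNames(cube$species$true_range, cube$species$species_id)

  fut <- dplyr::filter(cube$projections, .data$layer == "future")
  cur <- dplyr::filter(cube$projections, .data$layer == "current")
  if (nrow(fut) == 0) stop_invalid("projection cube contains no future projections")

  fut |>
    dplyr::group_by(
      .data$taxon, .data$algorithm, .data$repetition,
      .data$gcm, .data$rcp, .data$period
    ) |>
    dplyr::group_map(function(rows, key) {
      cur_rows <- dplyr::semi_join(
        cur, dplyr::mutate(rows, algorithm = key$algorithm, repetition = key$repetition),
        by = c("species_id", "algorithm", "repetition")
      )
      cur_rows <- cur_rows[match(rows$species_id, cur_rows$species_id), ]
      sets <- presence_sets(cur_rows, rows, ranges[rows$species_id])
      domains <- cube$species$domain[match(rows$species_id, cube$species$species_id)]

      rich_cur <- pixel_richness(sets$cur_lim, n_cell, domains)
      rich_fut <- pixel_richness(sets$fut_lim, n_cell, domains)
      lost_lim <- count_per_cell(purrr::map2(sets$cur_lim, sets$fut_lim, setdiff), n_cell)
      gained_lim <- count_per_cell(purrr::map2(sets$fut_lim, sets$cur_lim, setdiff), n_cell)

      covered <- !is.na(rich_cur)
      tibble::tibble(
        cell = which(covered),
        taxon = key$taxon, algorithm = key$algorithm, repetition = key$repetition,
        gcm = key$gcm, rcp = key$rcp, period = key$period,
        delta_alpha = pixel_delta_alpha(rich_cur, rich_fut)[covered],
        percent_loss = pixel_percent_loss(sets$cur_nd, sets$fut_nd, n_cell)[covered],
        beta_t = pixel_beta_t(lost_lim, gained_lim, rich_cur)[covered]
      )
    }) |>
    dplyr::bind_rows()
}
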
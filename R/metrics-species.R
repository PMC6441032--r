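#' Species-level sensitivity: change in climatic suitability (CCS)
#'
#' Relative change in suitable-cell count between a future projection under
#' limited dispersal and the current projection: `(future - current) /
#' current`. On an equal-area grid cell counts are proportional to area.
#'
#' @param current_suitable,future_suitable_limited Suitable-cell counts
#'   (current projection, and future projection within the
#'   limited-dispersal domain).
#' @return CCS, a unitless relative change `>= -1` when the future domain
#'   contains the current suitable area; `NA` (flagged by callers) when the
#'   current count is 0.
#' @export
#' @examples
#' species_ccs(100, 100) # 0
#' species_ccs(80, 120)  # 0.5
species_ccs <- function(current_suitable, future_suitable_limited) {
  ifelse(current_suitable > 0,
         (future_suitable_limited - current_suitable) / current_suitable,
         NA_real_)
}

#' Species-level sensitivity: loss in climatic suitability (LCS)
#'
#' Fraction of the cells suitable now (within the no-dispersal domain) that
#' become unsuitable in the future; the species' risk of habitat loss within
#' its current area of occupancy, in `[0, 1]`.
#'
#' @param current_suitable_cells Integer cells suitable under current
#'   climate within the no-dispersal domain.
#' @param future_suitable_cells Integer cells suitable in the future
#'   projection.
#' @return LCS in `[0, 1]`, or `NA` if the current suitable set is empty.
#' @export
#' @examples
#' species_lcs(1:100, 1:35) # 0.65
species_lcs <- function(current_suitable_cells, future_suitable_cells) {
  n <- length(current_suitable_cells)
  if (n == 0) return(NA_real_)
  sum(!(current_suitable_cells %in% future_suitable_cells)) / n
}

#' Species-level sensitivity table
#'
#' Converts a projection cube into one CCS/LCS record per retained model
#' and scenario: `species x algorithm x repetition x GCM x RCP x period`.
#' CCS contrasts future vs current suitable area on the limited-dispersal
#' domain; LCS counts losses within the no-dispersal domain (currently
#' suitable cells inside the current range). Records with empty
#' denominators are `NA` with `flag` set, and the exclusion count is
#' reported as an attribute.
#'
#' @param cube A [run_ensemble()] projection cube.
#' @return A tibble with columns `species_id`, `taxon`, `range_size`,
#'   `algorithm`, `repetition`, `gcm`, `rcp`, `period`, `ccs`, `lcs`,
#'   `flag`; attribute `n_excluded`.
#' @export
species_sensitivity <- function(cube) {
  stopifnot(inherits(cube, "projection_cube"))
  cur <- dplyr::filter(cube$projections, .data$layer == "current")
  fut <- dplyr::filter(cube$projections, .data$layer == "future")
  if (nrow(fut) == 0) stop_invalid("projection cube contains no future projections")
  cur <- dplyr::select(cur, "species_id", "algorithm", "repetition",
                       current_suitable = "suitable")
  sp <- dplyr::select(cube$species, "species_id", "range_size", "true_range")
  out <- fut |>
    dplyr::left_join(cur, by = c("species_id", "algorithm", "repetition")) |>
    dplyr::left_join(sp, by = "species_id") |>
    dplyr::mutate(
      ccs = species_ccs(
        lengths(.data$current_suitable), lengths(.data$suitable)
      ),
      lcs = purrr::pmap_dbl(
        list(.data$current_suitable, .data$suitable, .data$true_range),
        function(cur_cells, fut_cells, range) {
          species_lcs(intersect(cur_cells, range), fut_cells)
        }
      ),
      flag = is.na(.data$ccs) | is.na(.data$lcs)
    ) |>
    dplyr::select(
      "species_id", "taxon", "range_size", "algorithm", "repetition",
      "gcm", "rcp", "period", "ccs", "lcs", "flag"
    )
  attr(out, "n_excluded") <- sum(out$flag)
  out
}
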
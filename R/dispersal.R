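#' Dispersal assumption masks
#'
#' Two dispersal assumptions bound where a species can occur in the future:
#' `no_dispersal` keeps only the current range, while `limited_dispersal`
#' admits every cell whose centre lies within a taxon-specific Euclidean
#' distance of any current-range cell centre (inclusive boundary). The
#' limited mask always contains the range, and masks grow monotonically with
#' distance.
#'
#' @param range_cells Integer vector of current-range cell indices
#'   (non-empty).
#' @param grid A [make_grid()] object.
#' @param distance_km Maximal dispersal distance in km (>= 0).
#' @return A `dispersal_mask`: list with `assumption`, sorted integer
#'   `cells`, and `distance_km` (limited only).
#' @export
#' @examples
#' g <- make_grid(10, 10)
#' m <- limited_dispersal_mask(55, g, 250)
#' length(m$cells) # 13-cell discretised disc
limited_dispersal_mask <- function(range_cells, grid, distance_km) {
  stopifnot(inherits(grid, "bioscen_grid"))
  range_cells <- as.integer(range_cells)
  if (length(range_cells) == 0) stop_invalid("`range_cells` must be non-empty")
  if (any(range_cells < 1 | range_cells > n_cells(grid))) {
    stop_invalid("`range_cells` outside the grid")
  }
  if (distance_km < 0) stop_invalid("`distance_km` must be >= 0")
  d <- distance_to_cells(grid, range_cells)
  cells <- which(d <= distance_km + 1e-9)
  structure(
    list(
      assumption = "limited_dispersal",
      cells = sort(unique(as.integer(cells))),
      distance_km = as.numeric(distance_km)
    ),
    class = "dispersal_mask"
  )
}

#' @rdname limited_dispersal_mask
#' @export
no_dispersal_mask <- function(range_cells) {
  range_cells <- as.integer(range_cells)
  if (length(range_cells) == 0) stop_invalid("`range_cells` must be non-empty")
  structure(
    list(
      assumption = "no_dispersal",
      cells = sort(unique(range_cells)),
      distance_km = NA_real_
    ),
    class = "dispersal_mask"
  )
}

#' @export
print.dispersal_mask <- function(x, ...) {
  cat(sprintf(
    "<dispersal_mask> %s: %d cells%s\n", x$assumption, length(x$cells),
    if (is.na(x$distance_km)) "" else sprintf(" (distance %g km)", x$distance_km)
  ))
  invisible(x)
}

#' Default taxon-specific dispersal / absence-buffer distances
#'
#' Maximal-dispersal buffer distances per taxon (km), used both for
#' pseudo-absence sampling and for the limited-dispersal domain. The mapping
#' is configurable wherever it is consumed.
#'
#' @return Named numeric vector (km).
#' @export
default_taxon_buffer_km <- function() {
  c(amphibian = 2000, mammal = 3000, bird = 4000)
}
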
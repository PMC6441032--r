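#' Define a planar equal-area grid
#'
#' The study world is a flat rectangular lattice of square cells, the
#' synthetic analogue of a 100 km equal-area projection grid. Cells are
#' indexed row-major (`cell = (row - 1) * n_cols + col`) and all distances
#' are Euclidean between cell centres, in kilometres.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size_km Side length of each square cell in km (default 100).
#' @return A `bioscen_grid` object.
#' @export
#' @examples
#' g <- make_grid(10, 10)
#' n_cells(g)
make_grid <- function(n_rows, n_cols, cell_size_km = 100) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop_invalid("`n_rows` and `n_cols` must be positive integers")
  }
  if (!is.numeric(cell_size_km) || cell_size_km <= 0) {
    stop_invalid("`cell_size_km` must be > 0")
  }
  structure(
    list(
      n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols),
      cell_size_km = as.numeric(cell_size_km)
    ),
    class = "bioscen_grid"
  )
}

#' @export
print.bioscen_grid <- function(x, ...) {
  cat(sprintf(
    "<bioscen_grid> %d x %d cells of %g km (%d cells)\n",
    x$n_rows, x$n_cols, x$cell_size_km, n_cells(x)
  ))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A [make_grid()] object.
#' @return Integer cell count.
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "bioscen_grid"))
  grid$n_rows * grid$n_cols
}

#' Cell centre coordinates
#'
#' @param grid A [make_grid()] object.
#' @return A tibble with one row per cell: `cell`, `row`, `col`, and centre
#'   coordinates `x_km`, `y_km`.
#' @export
cell_coords <- function(grid) {
  stopifnot(inherits(grid, "bioscen_grid"))
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  tibble::tibble(
    cell = seq_len(n_cells(grid)),
    row = row,
    col = col,
    x_km = (col - 0.5) * grid$cell_size_km,
    y_km = (row - 0.5) * grid$cell_size_km
  )
}

# Euclidean distance (km) from every grid cell to the nearest cell in `cells`
distance_to_cells <- function(grid, cells) {
  coords <- cell_coords(grid)
  src <- coords[match(cells, coords$cell), , drop = FALSE]
  # small worlds: a dense |grid| x |cells| distance computation is exact and fast
  dx <- outer(coords$x_km, src$x_km, "-")
  dy <- outer(coords$y_km, src$y_km, "-")
  sqrt(dx^2 + dy^2) |> apply(1L, min)
}
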
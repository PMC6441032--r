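#' Bin species by range size on the log scale
#'
#' Equal-width bins on `log10(range_size)` spanning the observed range,
#' right-closed with the lowest edge included, so every modelled species is
#' assigned to exactly one bin.
#'
#' @param records A data frame with columns `species_id` and `range_size`
#'   (cells, `>= 20`).
#' @param n_bins Number of bins.
#' @return List of class `range_size_bins` with `edges` (length
#'   `n_bins + 1`, on the range-size scale) and `bins`, a tibble
#'   `species_id`, `range_size`, `bin` (integer), `bin_label`.
#' @export
#' @examples
#' rec <- tibble::tibble(species_id = c("a", "b", "c"),
#'                       range_size = c(100, 1000, 10000))
#' bin_by_range_size(rec, 2)$bins$bin # 1 1 2
bin_by_range_size <- function(records, n_bins) {
  stopifnot(is.data.frame(records), all(c("species_id", "range_size") %in% names(records)))
  if (n_bins < 1) stop_invalid("`n_bins` must be >= 1")
  sizes <- dplyr::distinct(
    tibble::as_tibble(records[c("species_id", "range_size")])
  )
  lg <- log10(sizes$range_size)
  if (max(lg) == min(lg)) {
    if (n_bins > 1) warn("all species share one range size: returning a single bin")
    edges_log <- c(min(lg) - 0.5, min(lg) + 0.5)
    bin <- rep(1L, nrow(sizes))
  } else {
    edges_log <- seq(min(lg), max(lg), length.out = n_bins + 1)
    bin <- as.integer(cut(lg, breaks = edges_log, include.lowest = TRUE, right = TRUE))
  }
  structure(
    list(
      edges = 10^edges_log,
      bins = dplyr::mutate(
        sizes,
        bin = bin,
        bin_label = sprintf("bin%02d", bin)
      )
    ),
    class = "range_size_bins"
  )
}

#' @export
print.range_size_bins <- function(x, ...) {
  cat(sprintf(
    "<range_size_bins> %d bins over range sizes [%g, %g]\n",
    length(x$edges) - 1, min(x$edges), max(x$edges)
  ))
  invisible(x)
}
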
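#' Change in spatial turnover per sub-region
#'
#' For each region and design cell, spatial turnover is summarised as
#' Whittaker's multiplicative beta diversity, `beta = gamma / mean(alpha)`:
#' regional species richness over mean per-cell richness across the
#' region's cells. The reported quantity is the relative change
#' `delta_beta_s = 100 * (beta_future - beta_current) / beta_current`.
#' An alternative literal reading -- the percent change in regional gamma
#' diversity divided by the current mean alpha -- is available via
#' `semantics = "literal"`.
#'
#' @param cube A [run_ensemble()] projection cube.
#' @param regions An [assign_regions()] tibble covering the cube's grid.
#' @param assumption `"limited_dispersal"` (default) or `"no_dispersal"`;
#'   under no dispersal both periods are restricted to currently suitable
#'   cells inside the current range.
#' @param semantics `"whittaker"` (default) or `"literal"` (see above).
#' @return A tibble: `region_id`, `taxon`, `algorithm`, `repetition`,
#'   `gcm`, `rcp`, `period`, `assumption`, `delta_beta_s`, `flag` (`TRUE`
#'   where current gamma or mean alpha is 0 and the metric is undefined).
#' @export
region_delta_beta_s <- function(cube, regions,
                                assumption = c("limited_dispersal", "no_dispersal"),
                                semantics = c("whittaker", "literal")) {
  stopifnot(inherits(cube, "projection_cube"), is.data.frame(regions))
  assumption <- match.arg(assumption)
  semantics <- match.arg(semantics)
  n_cell <- n_cells(cube$grid)
  if (!setequal(regions$cell, seq_len(n_cell))) {
    stop_invalid("`regions` must cover every cell of the cube's grid exactly once")
  }
  region_of <- regions$region_id[match(seq_len(n_cell), regions$cell)]
  region_ids <- sort(unique(region_of))
  region_sizes <- as.numeric(table(region_of)[region_ids])
  ranges <- setNames(cube$species$true_range, cube$species$species_id)

  fut <- dplyr::filter(cube$projections, .data$layer == "future")
  cur <- dplyr::filter(cube$projections, .data$layer == "current")

  # per-region gamma and mean alpha for a list of per-species cell sets;
  # mean alpha averages over all region cells (richness 0 where no species)
  region_stats <- function(sets) {
    rich <- count_per_cell(sets, n_cell)
    alpha_sum <- tapply(rich, region_of, sum)[region_ids]
    gamma <- vapply(region_ids, function(r) {
      sum(vapply(sets, function(s) any(region_of[s] == r), logical(1)))
    }, numeric(1))
    list(gamma = gamma, mean_alpha = as.numeric(alpha_sum) / region_sizes)
  }

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
      if (assumption == "limited_dispersal") {
        s_cur <- sets$cur_lim
        s_fut <- sets$fut_lim
      } else {
        s_cur <- sets$cur_nd
        s_fut <- sets$fut_nd
      }
      st_cur <- region_stats(s_cur)
      st_fut <- region_stats(s_fut)
      defined <- st_cur$gamma > 0 & st_cur$mean_alpha > 0
      dbs <- rep(NA_real_, length(region_ids))
      if (semantics == "whittaker") {
        b_cur <- st_cur$gamma / st_cur$mean_alpha
        b_fut <- ifelse(st_fut$mean_alpha > 0, st_fut$gamma / st_fut$mean_alpha, NA_real_)
        dbs[defined] <- 100 * (b_fut[defined] - b_cur[defined]) / b_cur[defined]
      } else {
        dbs[defined] <- (100 * (st_fut$gamma[defined] - st_cur$gamma[defined]) /
                           st_cur$gamma[defined]) / st_cur$mean_alpha[defined]
      }
      tibble::tibble(
        region_id = region_ids,
        taxon = key$taxon, algorithm = key$algorithm, repetition = key$repetition,
        gcm = key$gcm, rcp = key$rcp, period = key$period,
        assumption = assumption,
        delta_beta_s = dbs,
        flag = !defined | is.na(dbs)
      )
    }) |>
    dplyr::bind_rows()
}
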
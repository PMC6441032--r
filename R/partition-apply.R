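partition_to_rows <- function(part) {
  dplyr::mutate(
    part$table,
    total_deviance = part$total_deviance,
    n = part$n,
    engine = part$engine
  )
}

# quietly run one grouped partition, returning NULL where degenerate
safe_partition <- function(data, metric, engine, include_interaction = FALSE) {
  fit <- withCallingHandlers(
    tryCatch({
      if (engine == "nested") {
        nested_partition(data, response = metric,
                         include_interaction = include_interaction)
      } else {
        full_factorial_partition(data, response = metric)
      }
    }, error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(fit) || fit$flag) NULL else fit
}

#' Per-pixel deviance partitioning
#'
#' Runs the nested (or full-factorial) partition independently for every
#' grid cell of a pixel-level sensitivity table, producing the per-cell
#' relative influence of SDM, GCM and RCP plus the total deviance --
#' the tabular form of the spatial uncertainty maps. Cells whose table is
#' degenerate (constant or insufficient response) are omitted.
#'
#' @param pixel_records A [pixel_sensitivity()] table (optionally
#'   pre-filtered to one taxon and period).
#' @param metric Which metric column to partition (`"delta_alpha"`,
#'   `"percent_loss"` or `"beta_t"`).
#' @param by Extra grouping columns kept alongside `cell`
#'   (default `c("taxon", "period")`).
#' @param engine `"nested"` or `"full_factorial"`.
#' @return A long tibble: grouping columns, `component`, `df`, `deviance`,
#'   `share_explained`, `share_total`, `total_deviance`, `n`.
#' @export
partition_per_pixel <- function(pixel_records,
                                metric = c("delta_alpha", "percent_loss", "beta_t"),
                                by = c("taxon", "period"),
                                engine = c("nested", "full_factorial")) {
  metric <- match.arg(metric)
  engine <- match.arg(engine)
  by <- intersect(by, names(pixel_records))
  pixel_records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "cell")))) |>
    dplyr::group_map(function(rows, key) {
      fit <- safe_partition(rows, metric, engine)
      if (is.null(fit)) return(NULL)
      dplyr::bind_cols(key, partition_to_rows(fit))
    }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(metric = metric, .before = 1)
}

#' Deviance partitioning stratified by species range size
#'
#' Pools the species-level sensitivity records of each log-range-size bin
#' and partitions each pooled table, tracing how the relative influence of
#' SDM, GCM and RCP shifts from rare to widespread species.
#'
#' @param species_records A [species_sensitivity()] table.
#' @param bins A [bin_by_range_size()] object covering the records'
#'   species.
#' @param metric `"ccs"` or `"lcs"`.
#' @param engine `"nested"` or `"full_factorial"`.
#' @return A long tibble: `metric`, `bin`, `bin_label`, `n_species`,
#'   component rows as in [partition_per_pixel()]. Empty or degenerate
#'   bins are skipped with a warning.
#' @export
partition_by_range_bin <- function(species_records, bins,
                                   metric = c("ccs", "lcs"),
                                   engine = c("nested", "full_factorial")) {
  metric <- match.arg(metric)
  engine <- match.arg(engine)
  stopifnot(inherits(bins, "range_size_bins"))
  joined <- dplyr::inner_join(
    species_records, bins$bins[c("species_id", "bin", "bin_label")],
    by = "species_id"
  )
  all_bins <- sort(unique(bins$bins$bin))
  out <- purrr::map(all_bins, function(b) {
    rows <- dplyr::filter(joined, .data$bin == b)
    fit <- if (nrow(rows)) safe_partition(rows, metric, engine) else NULL
    if (is.null(fit)) {
      warn(sprintf("range-size bin %d skipped (empty or degenerate)", b))
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(
        bin = b, bin_label = sprintf("bin%02d", b),
        n_species = dplyr::n_distinct(rows$species_id)
      ),
      partition_to_rows(fit)
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(metric = metric, .before = 1)
}

#' Compare deviance partitions across TSS retention thresholds
#'
#' Re-derives record sets from the same fitted ensemble under each TSS
#' threshold policy and partitions each, side by side, to show whether the
#' SDM-driven share of uncertainty is an artefact of low-quality models.
#'
#' @param records_by_threshold Named list of species-level record tables,
#'   one per threshold (names are the thresholds), all computed from the
#'   same fitted models.
#' @param metric `"ccs"` or `"lcs"`.
#' @param engine `"nested"` or `"full_factorial"`.
#' @return A long tibble with a `threshold` column; thresholds retaining
#'   zero models yield no rows and a warning.
#' @export
threshold_sensitivity <- function(records_by_threshold,
                                  metric = c("ccs", "lcs"),
                                  engine = c("nested", "full_factorial")) {
  metric <- match.arg(metric)
  engine <- match.arg(engine)
  stopifnot(is.list(records_by_threshold), !is.null(names(records_by_threshold)))
  out <- purrr::imap(records_by_threshold, function(rows, th) {
    fit <- if (!is.null(rows) && nrow(rows)) safe_partition(rows, metric, engine) else NULL
    if (is.null(fit)) {
      warn(sprintf("threshold %s retains no usable records; column left empty", th))
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(threshold = as.numeric(th), n_rows = nrow(rows)),
      partition_to_rows(fit)
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(metric = metric, .before = 1)
}

#' Simulate a balanced factorial design table with planted effects
#'
#' Generates `y = a(SDM) + b(GCM) + c(RCP) + noise` on a balanced crossed
#' design, with factor level effects drawn from centred normals and, by
#' default, rescaled so each factor's planted effect standard deviation is
#' exact -- the ground truth for variance-recovery checks of the partition
#' engines.
#'
#' @param n_sdm,n_gcm,n_rcp,n_rep Level and replicate counts.
#' @param effect_sd Length-3 numeric: planted sd of the SDM, GCM and RCP
#'   effects.
#' @param noise_sd Residual noise sd.
#' @param seed Integer seed.
#' @param exact_variance Rescale drawn effects to the exact planted sd
#'   (default `TRUE`).
#' @return A tibble `sdm`, `gcm`, `rcp`, `rep`, `value`.
#' @export
simulate_design_table <- function(n_sdm = 4, n_gcm = 5, n_rcp = 4, n_rep = 4,
                                  effect_sd = c(3, 2, 1), noise_sd = 0.1,
                                  seed = 1, exact_variance = TRUE) {
  stopifnot(length(effect_sd) == 3)
  draw <- function(k, s) {
    if (k < 2 || s == 0) return(rep(0, k))
    e <- rnorm(k)
    e <- e - mean(e)
    if (exact_variance && sd(e) > 0) e * s / sd(e) else e * s
  }
  with_seed(seed, {
    a <- draw(n_sdm, effect_sd[1])
    b <- draw(n_gcm, effect_sd[2])
    c_ <- draw(n_rcp, effect_sd[3])
    tab <- tidyr::expand_grid(
      sdm = sprintf("S%d", seq_len(n_sdm)),
      gcm = sprintf("G%d", seq_len(n_gcm)),
      rcp = sprintf("R%d", seq_len(n_rcp)),
      rep = seq_len(n_rep)
    )
    tab$value <- a[match(tab$sdm, sprintf("S%d", seq_len(n_sdm)))] +
      b[match(tab$gcm, sprintf("G%d", seq_len(n_gcm)))] +
      c_[match(tab$rcp, sprintf("R%d", seq_len(n_rcp)))] +
      rnorm(nrow(tab), 0, noise_sd)
    tab
  })
}
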
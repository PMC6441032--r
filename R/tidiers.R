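#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a deviance partition
#'
#' @param x A `deviance_partition`.
#' @param ... Unused.
#' @return A tibble with one row per component (`sdm`, `gcm`, `rcp`,
#'   optional `gcm_rcp`, `residual`): `component`, `df`, `deviance`,
#'   `share_explained`, `share_total`.
#' @exportS3Method generics::tidy
tidy.deviance_partition <- function(x, ...) {
  x$table
}

#' One-row summary of a deviance partition
#'
#' @param x A `deviance_partition`.
#' @param ... Unused.
#' @return A one-row tibble: `engine`, `n`, `n_dropped`, `total_deviance`,
#'   `explained_deviance`, `explained_fraction`, `flag`.
#' @exportS3Method generics::glance
glance.deviance_partition <- function(x, ...) {
  tibble::tibble(
    engine = x$engine,
    n = x$n,
    n_dropped = x$n_dropped,
    total_deviance = x$total_deviance,
    explained_deviance = x$explained_deviance,
    explained_fraction = if (isTRUE(x$total_deviance > 0)) {
      x$explained_deviance / x$total_deviance
    } else {
      NA_real_
    },
    flag = x$flag
  )
}

#' Tidy a fitted SDM
#'
#' @param x A [fit_sdm()] object.
#' @param ... Unused.
#' @return A one-row tibble: `species_id`, `algorithm`, `tss_score`,
#'   `cutoff`, `n_train`, `n_eval`.
#' @exportS3Method generics::tidy
tidy.fitted_sdm <- function(x, ...) {
  tibble::tibble(
    species_id = x$species_id %||% NA_character_,
    algorithm = x$algorithm,
    tss_score = x$tss_score,
    cutoff = x$cutoff,
    n_train = x$n_train,
    n_eval = x$n_eval
  )
}

#' Summarise a projection cube
#'
#' @param x A [run_ensemble()] projection cube.
#' @param ... Unused.
#' @return A one-row tibble with species, model and projection counts and
#'   the mean TSS of converged fits.
#' @exportS3Method generics::glance
glance.projection_cube <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$species),
    n_models_fit = sum(x$models$status == "ok"),
    n_models_retained = sum(x$models$retained),
    n_projections = nrow(x$projections),
    mean_tss = mean(x$models$tss_score, na.rm = TRUE),
    threshold = x$threshold
  )
}
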
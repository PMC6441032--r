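resolve_col <- function(data, supplied, candidates, what) {
  nm <- supplied %||% candidates[candidates %in% names(data)][1]
  if (is.na(nm) || is.null(nm) || !nm %in% names(data)) {
    stop_invalid(sprintf(
      "no %s column found (looked for %s)", what,
      paste(sprintf("'%s'", candidates), collapse = ", ")
    ))
  }
  nm
}

# Sequential (order-dependent) sums of squares over a list of categorical
# terms. Each term's deviance is the drop in residual SS when its indicator
# columns join the cumulative design; ranks come from pivoted QR, so
# unbalanced and incomplete designs (missing GCM x RCP combos, dropped
# models) are handled by least squares on the observed rows, no imputation.
sequential_partition <- function(y, term_factors, engine) {
  keep <- !is.na(y)
  for (f in term_factors) keep <- keep & !is.na(f)
  n_dropped <- sum(!keep)
  y <- y[keep]
  term_factors <- lapply(term_factors, function(f) droplevels(factor(f[keep])))
  n <- length(y)
  if (n < 2 || length(unique(y)) < 2) {
    if (n >= 2) warn("constant response: total deviance is 0, shares undefined")
    tab <- tibble::tibble(
      component = c(names(term_factors), "residual"),
      df = NA_integer_, deviance = if (n >= 2) 0 else NA_real_,
      share_explained = NA_real_, share_total = NA_real_
    )
    return(new_deviance_partition(tab, total = if (n >= 2) 0 else NA_real_,
                                  n = n, n_dropped = n_dropped,
                                  engine = engine, flag = TRUE))
  }
  total <- sum((y - mean(y))^2)
  X <- matrix(1, n, 1)
  rank_prev <- 1L
  rss_prev <- total
  rows <- purrr::imap(term_factors, function(f, nm) {
    if (nlevels(f) < 2) {
      warn(sprintf("term '%s' has a single level; its component is 0", nm))
    }
    X <<- cbind(X, stats::model.matrix(~ f - 1))
    q <- qr(X)
    rss <- sum((y - qr.fitted(q, y))^2)
    row <- tibble::tibble(
      component = nm,
      df = q$rank - rank_prev,
      deviance = max(rss_prev - rss, 0)
    )
    rank_prev <<- q$rank
    rss_prev <<- rss
    row
  })
  tab <- dplyr::bind_rows(rows)
  explained <- sum(tab$deviance)
  tab <- dplyr::bind_rows(
    tab,
    tibble::tibble(component = "residual", df = n - rank_prev, deviance = rss_prev)
  )
  tab$share_total <- 100 * tab$deviance / total
  tab$share_explained <- ifelse(
    tab$component == "residual", NA_real_,
    if (explained > 0) 100 * tab$deviance / explained else NA_real_
  )
  new_deviance_partition(tab[c("component", "df", "deviance",
                               "share_explained", "share_total")],
                         total = total, n = n, n_dropped = n_dropped,
                         engine = engine, flag = FALSE)
}

new_deviance_partition <- function(table, total, n, n_dropped, engine, flag) {
  structure(
    list(table = table, total_deviance = total,
         explained_deviance = sum(table$deviance[table$component != "residual"]),
         n = n, n_dropped = n_dropped, engine = engine, flag = flag),
    class = "deviance_partition"
  )
}

#' @export
print.deviance_partition <- function(x, ...) {
  cat(sprintf("<deviance_partition> engine: %s, n = %d, total deviance = %.4g\n",
              x$engine, x$n, x$total_deviance))
  print(x$table)
  invisible(x)
}

#' Nested deviance partitioning of ensemble uncertainty
#'
#' Attributes the deviance (Gaussian deviance, i.e. sums of squares) of a
#' sensitivity metric to the choices of SDM algorithm, GCM and RCP with a
#' nested sequential ANOVA: SDM enters first, then GCM within SDM, then RCP
#' within SDM (the crossed-within-nested scheme `SDM/GCM:RCP`). SDMs are
#' fitted irrespective of climate forcing, while GCM and RCP effects are
#' only meaningful within each algorithm's projections -- hence the
#' nesting. Sequential sums of squares are order-dependent on unbalanced
#' designs; the term order here is part of the method. The within-SDM
#' GCM:RCP interaction is pooled into the residual by default.
#'
#' @param data A long design table: one row per response value with
#'   categorical columns for SDM, GCM and RCP. Cross-validation repetitions
#'   stay as replicate rows, not a factor.
#' @param response Response column name; defaults to `"value"` or the first
#'   of `ccs`, `lcs`, `delta_alpha`, `percent_loss`, `beta_t`,
#'   `delta_beta_s` present.
#' @param sdm,gcm,rcp Factor column names (defaults: `sdm`/`algorithm`,
#'   `gcm`, `rcp`).
#' @param include_interaction If `TRUE`, a fourth term (GCM:RCP within SDM)
#'   is extracted from the residual.
#' @return A `deviance_partition`: component table (`component`, `df`,
#'   `deviance`, `share_explained`, `share_total`) plus totals. Shares of
#'   explained deviance sum to 100; component plus residual deviance equals
#'   the total.
#' @seealso [full_factorial_partition()] for the crossed-main-effects
#'   alternative, [tidy.deviance_partition()].
#' @export
#' @examples
#' tab <- tidyr::expand_grid(sdm = letters[1:4], gcm = LETTERS[1:3],
#'                           rcp = c("2.6", "8.5"), rep = 1:2)
#' tab$value <- as.integer(factor(tab$sdm)) + rnorm(nrow(tab), 0, 0.1)
#' nested_partition(tab)
nested_partition <- function(data, response = NULL, sdm = NULL, gcm = NULL,
                             rcp = NULL, include_interaction = FALSE) {
  response <- resolve_col(data, response, c("value", "ccs", "lcs", "delta_alpha",
                                            "percent_loss", "beta_t", "delta_beta_s"),
                          "response")
  sdm <- resolve_col(data, sdm, c("sdm", "algorithm"), "SDM")
  gcm <- resolve_col(data, gcm, c("gcm"), "GCM")
  rcp <- resolve_col(data, rcp, c("rcp"), "RCP")
  f_sdm <- factor(data[[sdm]])
  f_gcm <- factor(data[[gcm]])
  f_rcp <- factor(data[[rcp]])
  for (nm in c("gcm", "rcp")) {
    f <- if (nm == "gcm") f_gcm else f_rcp
    if (nlevels(droplevels(f)) < 2) {
      warn(sprintf("factor '%s' has a single level; its component is 0", nm))
    }
  }
  terms <- list(
    sdm = f_sdm,
    gcm = interaction(f_sdm, f_gcm, drop = TRUE),
    rcp = interaction(f_sdm, f_rcp, drop = TRUE)
  )
  if (include_interaction) {
    terms$gcm_rcp <- interaction(f_sdm, f_gcm, f_rcp, drop = TRUE)
  }
  sequential_partition(data[[response]], terms, engine = "nested")
}

#' Full-factorial sequential deviance partitioning
#'
#' The crossed-main-effects alternative to [nested_partition()]: sequential
#' terms SDM, GCM, RCP as plain main effects, interactions pooled into the
#' residual. On balanced complete designs the sequential sums of squares
#' coincide with classical main-effect ANOVA regardless of order; on
#' unbalanced designs the two engines differ while both conserve total
#' deviance.
#'
#' @inheritParams nested_partition
#' @return A `deviance_partition`.
#' @export
full_factorial_partition <- function(data, response = NULL, sdm = NULL,
                                     gcm = NULL, rcp = NULL) {
  response <- resolve_col(data, response, c("value", "ccs", "lcs", "delta_alpha",
                                            "percent_loss", "beta_t", "delta_beta_s"),
                          "response")
  sdm <- resolve_col(data, sdm, c("sdm", "algorithm"), "SDM")
  gcm <- resolve_col(data, gcm, c("gcm"), "GCM")
  rcp <- resolve_col(data, rcp, c("rcp"), "RCP")
  terms <- list(
    sdm = factor(data[[sdm]]),
    gcm = factor(data[[gcm]]),
    rcp = factor(data[[rcp]])
  )
  sequential_partition(data[[response]], terms, engine = "full_factorial")
}
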
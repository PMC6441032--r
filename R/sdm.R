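sdm_algorithms <- c("GLM", "GAM", "BRT", "RF")

#' Assemble a presence/absence training table
#'
#' All true-range cells enter as presences; pseudo-absences are sampled
#' uniformly without replacement from the cells within `buffer_km`
#' (Euclidean, cell centres) of the range but outside it. Sampling absences
#' from a geographic buffer rather than the whole world avoids
#' over-optimistic accuracy from trivially distinct far-away climates.
#'
#' @param species One row of a [simulate_species()] tibble (or a list with
#'   `species_id` and `true_range`).
#' @param climate Baseline `climate_layers`.
#' @param buffer_km Buffer distance in km (> 0).
#' @param n_absences Number of absences to draw; `NULL` uses
#'   `min(10 * n_presences, all buffer cells)`.
#' @param seed Integer seed.
#' @return A tibble with columns `cell`, `label` (1 presence / 0 absence)
#'   and the four climate variables; attributes `species_id` and
#'   `buffer_km`.
#' @export
build_training_set <- function(species, climate, buffer_km,
                               n_absences = NULL, seed = 1) {
  stopifnot(inherits(climate, "climate_layers"))
  if (buffer_km <= 0) stop_invalid("`buffer_km` must be > 0")
  grid <- attr(climate, "grid")
  range_cells <- if (is.data.frame(species)) species$true_range[[1]] else species$true_range
  species_id <- if (is.data.frame(species)) species$species_id[[1]] else species$species_id
  range_cells <- as.integer(range_cells)
  if (length(range_cells) < 20) stop_invalid("species must have >= 20 presence cells")

  buffer <- limited_dispersal_mask(range_cells, grid, buffer_km)
  candidates <- setdiff(buffer$cells, range_cells)
  if (length(candidates) == 0) {
    stop_invalid(sprintf(
      "species %s: no absence candidates within %g km of the range", species_id, buffer_km
    ))
  }
  if (is.null(n_absences)) n_absences <- min(10L * length(range_cells), length(candidates))
  if (n_absences > length(candidates)) {
    warn(sprintf(
      "species %s: only %d absence candidates within the buffer (requested %d)",
      species_id, length(candidates), n_absences
    ))
    n_absences <- length(candidates)
  }
  absences <- with_seed(seed, sort(sample(candidates, n_absences)))

  rows <- climate[match(c(range_cells, absences), climate$cell), c("cell", climate_vars)]
  out <- dplyr::bind_cols(
    tibble::tibble(label = rep(c(1L, 0L), c(length(range_cells), length(absences)))),
    rows
  )[c("cell", "label", climate_vars)]
  attr(out, "species_id") <- species_id
  attr(out, "buffer_km") <- as.numeric(buffer_km)
  out
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1`, a prevalence-insensitive accuracy
#' score for binary predictions in `[-1, 1]`.
#'
#' @param predicted,observed Binary (0/1 or logical) vectors of equal length.
#' @return A single numeric TSS value.
#' @export
#' @examples
#' evaluate_tss(c(1, 1, 0, 0), c(1, 1, 0, 0)) # 1
#' evaluate_tss(rep(1, 10), rep(c(1, 0), 5))  # 0
evaluate_tss <- function(predicted, observed) {
  predicted <- as.integer(as.logical(predicted))
  observed <- as.integer(as.logical(observed))
  if (length(predicted) != length(observed)) stop_invalid("inputs must have equal length")
  if (all(observed == 1)) stop_invalid("`observed` contains no absences; specificity undefined")
  if (all(observed == 0)) stop_invalid("`observed` contains no presences; sensitivity undefined")
  tp <- sum(predicted == 1 & observed == 1)
  fn <- sum(predicted == 0 & observed == 1)
  tn <- sum(predicted == 0 & observed == 0)
  fp <- sum(predicted == 1 & observed == 0)
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' TSS-maximising binarisation cutoff
#'
#' Evaluates TSS over a candidate grid made of the unique scores and the
#' midpoints between consecutive unique scores (prediction rule
#' `score >= cutoff`), returning the smallest cutoff achieving the maximum.
#'
#' @param scores Continuous suitability scores in `[0, 1]`.
#' @param observed Binary labels.
#' @return List with `cutoff` and the achieved `tss`.
#' @export
select_cutoff <- function(scores, observed) {
  observed <- as.integer(as.logical(observed))
  if (length(scores) != length(observed)) stop_invalid("inputs must have equal length")
  u <- sort(unique(scores))
  if (length(u) == 1) {
    warn("constant scores: returning cutoff 0.5")
    return(list(cutoff = 0.5, tss = 0))
  }
  candidates <- sort(unique(c(u, (u[-1] + u[-length(u)]) / 2)))
  tss <- vapply(candidates, function(ct) {
    evaluate_tss(scores >= ct, observed)
  }, numeric(1))
  best <- which.max(tss) # which.max returns the first (smallest) maximiser
  if (tss[best] <= 0) {
    warn(sprintf("best achievable TSS is %.3f (model no better than chance)", tss[best]))
  }
  list(cutoff = candidates[best], tss = tss[best])
}

fit_algorithm <- function(algorithm, train) {
  x <- as.matrix(train[climate_vars])
  y <- train$label
  switch(algorithm,
    GLM = {
      df <- as.data.frame(train[c("label", climate_vars)])
      form <- stats::as.formula(paste(
        "label ~",
        paste(sprintf("%s + I(%s^2)", climate_vars, climate_vars), collapse = " + ")
      ))
      glm(form, family = binomial(), data = df)
    },
    GAM = {
      df <- as.data.frame(train[c("label", climate_vars)])
      k <- max(3L, min(5L, min(vapply(climate_vars, function(v) {
        length(unique(df[[v]]))
      }, integer(1))) - 1L))
      form <- stats::as.formula(paste(
        "label ~", paste(sprintf("s(%s, k = %d)", climate_vars, k), collapse = " + ")
      ))
      mgcv::gam(form, family = binomial(), data = df, method = "GCV.Cp")
    },
    BRT = {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1, max_depth = 3,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = 80, verbose = 0
      )
    },
    RF = {
      randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)), ntree = 150)
    },
    stop_invalid(sprintf("unknown algorithm '%s'", algorithm))
  )
}

predict_suitability <- function(model, algorithm, newdata) {
  x <- newdata[climate_vars]
  switch(algorithm,
    GLM = as.numeric(predict(model, newdata = as.data.frame(x), type = "response")),
    GAM = as.numeric(predict(model, newdata = as.data.frame(x), type = "response")),
    BRT = as.numeric(predict(model, newdata = xgboost::xgb.DMatrix(
      as.matrix(x), nthread = 1
    ))),
    RF = as.numeric(predict(model, newdata = as.matrix(x), type = "prob")[, "1"])
  )
}

#' Fit one species distribution model with split-sample validation
#'
#' Calibrates the chosen algorithm on a random 70% of the training table and
#' evaluates it on the held-out 30% with the true skill statistic at the
#' TSS-maximising cutoff, which is stored as the model's binarisation rule.
#' Repeating the call with different `repetition_seed`s yields the
#' split-sample cross-validation repetitions of the ensemble.
#'
#' @param training A [build_training_set()] table.
#' @param algorithm One of `"GLM"`, `"GAM"`, `"BRT"`, `"RF"`.
#' @param split_fraction Calibration fraction (default 0.7).
#' @param repetition_seed Integer seed controlling the split and any
#'   stochastic fitting.
#' @return A `fitted_sdm` object: algorithm, model handle, `tss_score`,
#'   `cutoff`, and the evaluation indices.
#' @export
fit_sdm <- function(training, algorithm, split_fraction = 0.7, repetition_seed = 1) {
  algorithm <- match.arg(algorithm, sdm_algorithms)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_invalid("`split_fraction` must be in (0, 1)")
  }
  n <- nrow(training)
  with_seed(repetition_seed, {
    idx <- sample.int(n, floor(split_fraction * n))
    train <- training[idx, , drop = FALSE]
    eval <- training[-idx, , drop = FALSE]
    if (length(unique(train$label)) < 2) {
      abort(paste(
        "calibration split contains a single class;",
        "re-split with a different `repetition_seed`"
      ), class = "bioscen_single_class_split")
    }
    if (length(unique(eval$label)) < 2) {
      abort(paste(
        "evaluation split contains a single class;",
        "re-split with a different `repetition_seed`"
      ), class = "bioscen_single_class_split")
    }
    # separable virtual species routinely trigger perfect-separation /
    # step-failure warnings that do not harm prediction; hard failures
    # still error and are excluded by the ensemble driver
    model <- suppressWarnings(fit_algorithm(algorithm, train))
    scores <- predict_suitability(model, algorithm, eval)
    sel <- suppressWarnings(select_cutoff(scores, eval$label))
    structure(
      list(
        species_id = attr(training, "species_id"),
        algorithm = algorithm,
        model = model,
        tss_score = sel$tss,
        cutoff = sel$cutoff,
        repetition_seed = repetition_seed,
        n_train = nrow(train),
        n_eval = nrow(eval)
      ),
      class = "fitted_sdm"
    )
  })
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat(sprintf(
    "<fitted_sdm> %s %s: TSS = %.3f, cutoff = %.3f\n",
    x$species_id %||% "?", x$algorithm, x$tss_score, x$cutoff
  ))
  invisible(x)
}

#' Project a fitted SDM onto climate layers
#'
#' Predicts continuous suitability for every in-domain cell and binarises at
#' the model's stored cutoff; cells outside the domain are absent from the
#' output.
#'
#' @param model A [fit_sdm()] object.
#' @param layers `climate_layers` on the model's grid.
#' @param domain Integer cell indices defining the projection domain
#'   (default: all cells).
#' @return A tibble `cell`, `score`, `suitable` (0/1) for in-domain cells.
#' @export
project <- function(model, layers, domain = NULL) {
  stopifnot(inherits(model, "fitted_sdm"), inherits(layers, "climate_layers"))
  if (is.null(domain)) domain <- layers$cell
  sub <- layers[match(domain, layers$cell), , drop = FALSE]
  if (anyNA(sub$cell)) stop_invalid("`domain` contains cells outside the layers' grid")
  if (nrow(sub) == 0) {
    return(tibble::tibble(cell = integer(), score = numeric(), suitable = integer()))
  }
  score <- predict_suitability(model$model, model$algorithm, sub)
  tibble::tibble(
    cell = sub$cell,
    score = score,
    suitable = as.integer(score >= model$cutoff)
  )
}
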
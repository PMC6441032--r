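#' Gaussian-niche suitability of every grid cell for one species
#'
#' Suitability is the product over the four climate variables of independent
#' Gaussian responses `exp(-(x - optimum)^2 / (2 * breadth^2))`, so the true
#' environmental response of every virtual species is known in closed form.
#'
#' @param climate A `climate_layers` tibble.
#' @param optimum,breadth Named numeric 4-vectors in variable units
#'   (`breadth` strictly positive).
#' @return Numeric vector of suitabilities in `[0, 1]`, one per cell.
#' @export
niche_suitability <- function(climate, optimum, breadth) {
  optimum <- optimum[climate_vars]
  breadth <- breadth[climate_vars]
  if (anyNA(optimum) || anyNA(breadth)) {
    stop_invalid("`optimum` and `breadth` must name all four climate variables")
  }
  if (any(breadth <= 0)) stop_invalid("`breadth` must be strictly positive")
  s <- rep(1, nrow(climate))
  for (v in climate_vars) {
    s <- s * exp(-(climate[[v]] - optimum[[v]])^2 / (2 * breadth[[v]]^2))
  }
  s
}

#' Simulate virtual species with known niches
#'
#' Each species gets a 4-D Gaussian niche (independent variables): the
#' optimum is the climate of a randomly chosen cell, jittered, and the
#' breadth per variable is drawn as a fraction of that variable's spatial
#' standard deviation. The true range is the set of cells whose suitability
#' exceeds the quantile cutoff that realises the species' drawn target
#' prevalence. Species whose range ends up below 20 cells -- the minimum
#' for fitting response curves to four predictors -- are re-drawn a limited
#' number of times and otherwise dropped with a warning.
#'
#' @param climate Baseline `climate_layers`.
#' @param n_species Number of species to generate.
#' @param taxon_mix Named proportions over `c("amphibian", "bird", "mammal")`.
#' @param prevalence_range Interval in (0, 1) from which each species' target
#'   prevalence (fraction of grid cells occupied) is drawn uniformly.
#' @param breadth_frac_range Interval of niche breadth as a fraction of each
#'   variable's spatial sd.
#' @param seed Integer seed.
#' @return A tibble with one row per retained species: `species_id`, `taxon`,
#'   `prevalence_target`, list-columns `optimum`, `breadth`, `true_range`
#'   (integer cell indices), and `range_size`.
#' @export
#' @examples
#' cl <- simulate_current_climate(make_grid(20, 20), seed = 1)
#' sp <- simulate_species(cl, n_species = 5, seed = 2)
#' sp$range_size
simulate_species <- function(climate, n_species,
                             taxon_mix = c(amphibian = 1 / 3, bird = 1 / 3, mammal = 1 / 3),
                             prevalence_range = c(0.05, 0.30),
                             breadth_frac_range = c(0.25, 0.6),
                             seed = 1) {
  stopifnot(inherits(climate, "climate_layers"))
  if (n_species < 1) stop_invalid("`n_species` must be >= 1")
  if (prevalence_range[1] <= 0 || prevalence_range[2] >= 1 ||
      prevalence_range[1] > prevalence_range[2]) {
    stop_invalid("`prevalence_range` must be an interval inside (0, 1)")
  }
  taxa <- c("amphibian", "bird", "mammal")
  taxon_mix <- taxon_mix[taxa]
  taxon_mix[is.na(taxon_mix)] <- 0
  if (sum(taxon_mix) <= 0) stop_invalid("`taxon_mix` must have positive total mass")
  nc <- nrow(climate)
  sds <- vapply(climate_vars, function(v) sd(climate[[v]]), numeric(1))
  sds[sds == 0] <- 1

  draw_one <- function(id, taxon) {
    for (attempt in 1:50) {
      prevalence <- runif(1, prevalence_range[1], prevalence_range[2])
      if (prevalence * nc < 1) {
        stop_invalid(sprintf(
          "species %s: target prevalence %.3f is unattainable on a %d-cell grid",
          id, prevalence, nc
        ))
      }
      anchor <- sample.int(nc, 1)
      optimum <- vapply(climate_vars, function(v) {
        climate[[v]][anchor] + rnorm(1, 0, 0.25 * sds[[v]])
      }, numeric(1))
      breadth <- vapply(climate_vars, function(v) {
        runif(1, breadth_frac_range[1], breadth_frac_range[2]) * sds[[v]]
      }, numeric(1))
      suit <- niche_suitability(climate, optimum, breadth)
      cutoff <- quantile(suit, 1 - prevalence, names = FALSE)
      range_cells <- which(suit >= cutoff)
      if (length(range_cells) >= 20) {
        return(tibble::tibble(
          species_id = id, taxon = taxon, prevalence_target = prevalence,
          optimum = list(optimum), breadth = list(breadth),
          true_range = list(as.integer(range_cells)),
          range_size = length(range_cells)
        ))
      }
    }
    warn(sprintf("species %s dropped: <20 presence cells after 50 attempts", id))
    NULL
  }

  with_seed(seed, {
    taxon <- sample(taxa, n_species, replace = TRUE, prob = taxon_mix)
    rows <- purrr::imap(taxon, function(tx, i) {
      draw_one(sprintf("sp%03d", i), tx)
    })
    dplyr::bind_rows(rows)
  })
}

#' Partition the grid into contiguous rectangular regions
#'
#' A synthetic stand-in for policy-reporting sub-regions (IPBES-style): the
#' grid is tiled by `r x c` rectangular blocks (the factorisation of
#' `n_regions` closest to square), with row/column band sizes differing by
#' at most one cell.
#'
#' @param grid A [make_grid()] object.
#' @param n_regions Number of regions (between 1 and the cell count).
#' @param seed Unused placeholder for API symmetry; tiling is deterministic.
#' @return A tibble `cell`, `row`, `col`, `region_id` covering every cell
#'   exactly once.
#' @export
#' @examples
#' table(assign_regions(make_grid(10, 10), 4)$region_id)
assign_regions <- function(grid, n_regions, seed = NULL) {
  stopifnot(inherits(grid, "bioscen_grid"))
  if (n_regions < 1 || n_regions > n_cells(grid)) {
    stop_invalid("`n_regions` must be between 1 and the number of cells")
  }
  n_regions <- as.integer(n_regions)
  # factor pair r*c = n_regions closest to square, r along rows
  divs <- which(n_regions %% seq_len(n_regions) == 0)
  r <- divs[which.min(abs(sqrt(n_regions) - divs))]
  c <- n_regions %/% r
  if (r > grid$n_rows || c > grid$n_cols) {
    # fall back to whichever orientation fits
    if (c <= grid$n_rows && r <= grid$n_cols) {
      tmp <- r; r <- c; c <- tmp
    } else {
      stop_invalid("`n_regions` cannot be tiled as contiguous blocks on this grid")
    }
  }
  band <- function(n, k) rep(seq_len(k), times = diff(floor(seq(0, n, length.out = k + 1))))
  row_band <- band(grid$n_rows, r)
  col_band <- band(grid$n_cols, c)
  coords <- cell_coords(grid)
  coords$region_id <- sprintf(
    "R%02d", (row_band[coords$row] - 1L) * c + col_band[coords$col]
  )
  coords[c("cell", "row", "col", "region_id")]
}
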
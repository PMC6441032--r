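test_that("CCS and LCS match hand arithmetic", {
  expect_equal(species_ccs(100, 100), 0)
  expect_equal(species_ccs(100, 0), -1)
  expect_equal(species_ccs(80, 120), 0.5)
  expect_true(is.na(species_ccs(0, 10)))
  expect_equal(species_lcs(1:100, 1:100), 0)
  expect_equal(species_lcs(1:100, integer()), 1)
  expect_equal(species_lcs(1:100, 36:200), 0.35)
  expect_true(is.na(species_lcs(integer(), 1:5)))
})

test_that("CCS equals -LCS when the future map is confined to current suitable cells", {
  withr::with_seed(21, {
    for (i in 1:25) {
      cur <- sort(sample(1:400, sample(20:120, 1)))
      fut <- intersect(sort(sample(1:400, sample(10:200, 1))), cur)
      ccs <- species_ccs(length(cur), length(fut))
      lcs <- species_lcs(cur, fut)
      expect_equal(ccs, -lcs)
      expect_gte(ccs, -1)
      expect_true(lcs >= 0 && lcs <= 1)
    }
  })
})

test_that("the species sensitivity table carries one record per future projection", {
  g <- toy_grid(10)
  species <- dplyr::bind_rows(
    toy_species_row("a", "bird", 1:30, 1:100),
    toy_species_row("b", "bird", 40:80, 1:100)
  )
  projections <- dplyr::bind_rows(
    proj_row("a", "bird", "GLM", 1, "current", 1:25),
    proj_row("a", "bird", "GLM", 1, "future", 1:10, "G1", "R1", "p1"),
    proj_row("b", "bird", "GLM", 1, "current", 40:69),
    proj_row("b", "bird", "GLM", 1, "future", 55:84, "G1", "R1", "p1")
  )
  pc <- toy_projection_cube(species, projections, g)
  ss <- species_sensitivity(pc)
  expect_equal(nrow(ss), 2)
  a <- ss[ss$species_id == "a", ]
  expect_equal(a$ccs, (10 - 25) / 25)
  expect_equal(a$lcs, 15 / 25) # all 25 current cells are inside the range
  b <- ss[ss$species_id == "b", ]
  expect_equal(b$ccs, 0) # 30 -> 30 cells
  expect_equal(b$lcs, 15 / 30)
})

test_that("pixel richness stacks maps and respects domain missingness", {
  r <- pixel_richness(list(1:3, 2:4, 4L), n_cells = 6)
  expect_equal(r, c(1, 2, 2, 2, 0, 0))
  # double-counting identity
  sets <- list(1:3, 2:4, 4L)
  expect_equal(sum(r), sum(lengths(sets)))
  rd <- pixel_richness(list(1:2, 2:3), n_cells = 5, domain_sets = list(1:3, 2:4))
  expect_true(is.na(rd[5]))
  expect_equal(rd[1:4], c(1, 2, 1, 0))
  expect_error(pixel_richness(list(), 5), class = "bioscen_invalid_input")
})

test_that("pixel metrics match arithmetic examples and stay in bounds", {
  expect_equal(pixel_delta_alpha(10, 5), -50)
  expect_true(is.na(pixel_delta_alpha(0, 5)))
  expect_equal(pixel_beta_t(0, 0, 10), 0)
  expect_equal(pixel_beta_t(10, 5, 10), 1)
  expect_equal(pixel_beta_t(2, 3, 10), 5 / 13)
  cur <- list(1:10, 1:5)
  fut <- list(6:10, integer())
  pl <- pixel_percent_loss(cur, fut, 10)
  expect_equal(pl[1], 100) # species 1 keeps cell? no: cells 1:5 lose both
  expect_equal(pl[6], 0)
})

test_that("pixel metrics equal per-cell brute-force recounts", {
  n_cell <- 400
  withr::with_seed(31, {
    for (trial in 1:5) {
      n_sp <- sample(3:10, 1)
      cur <- purrr::map(1:n_sp, ~ sort(sample(1:n_cell, sample(20:150, 1))))
      fut <- purrr::map(1:n_sp, ~ sort(sample(1:n_cell, sample(20:150, 1))))
      rich_c <- pixel_richness(cur, n_cell)
      rich_f <- pixel_richness(fut, n_cell)
      lost <- bioscen:::count_per_cell(purrr::map2(cur, fut, setdiff), n_cell)
      gained <- bioscen:::count_per_cell(purrr::map2(fut, cur, setdiff), n_cell)
      da <- pixel_delta_alpha(rich_c, rich_f)
      pl <- pixel_percent_loss(cur, fut, n_cell)
      bt <- pixel_beta_t(lost, gained, rich_c)
      for (cell in sample(1:n_cell, 40)) {
        present_c <- vapply(cur, function(s) cell %in% s, logical(1))
        present_f <- vapply(fut, function(s) cell %in% s, logical(1))
        rc <- sum(present_c); rf <- sum(present_f)
        lo <- sum(present_c & !present_f); ga <- sum(!present_c & present_f)
        expect_equal(rich_c[cell], rc)
        if (rc > 0) {
          expect_equal(da[cell], 100 * (rf - rc) / rc)
          expect_equal(pl[cell], 100 * lo / rc)
        } else {
          expect_true(is.na(da[cell]) && is.na(pl[cell]))
        }
        if (rc + ga > 0) {
          expect_equal(bt[cell], (lo + ga) / (rc + ga))
          expect_true(bt[cell] >= 0 && bt[cell] <= 1)
        } else {
          expect_true(is.na(bt[cell]))
        }
      }
    }
  })
})

test_that("beta_t is 0 iff nothing turns over and 1 iff nothing persists", {
  withr::with_seed(41, {
    for (i in 1:30) {
      rc <- sample(0:8, 1); ga <- sample(0:5, 1)
      lo <- if (rc > 0) sample(0:rc, 1) else 0
      bt <- pixel_beta_t(lo, ga, rc)
      if (rc + ga == 0) {
        expect_true(is.na(bt))
      } else if (lo == 0 && ga == 0) {
        expect_equal(bt, 0)
      } else if (lo == rc) {
        expect_equal(bt, 1)
      } else {
        expect_true(bt > 0 && bt < 1)
      }
    }
  })
})

test_that("regional turnover change follows the Whittaker definition", {
  g <- make_grid(4, 4) # one region
  regions <- assign_regions(g, 1)
  # 10 species: currently every species everywhere in cells 1:4 -> alpha=10 at
  # those cells; future halves per-cell occupancy while keeping gamma at 10
  species <- dplyr::bind_rows(purrr::map(1:10, function(i) {
    toy_species_row(sprintf("s%02d", i), "bird", 1:16, 1:16)
  }))
  cur_sets <- purrr::map(1:10, ~ 1:16)                     # alpha = 10, gamma = 10
  fut_sets <- purrr::map(1:10, ~ if (.x <= 5) 1:16 else integer()) # alpha 5, gamma...
  # gamma_future would drop to 5; instead keep every species present somewhere:
  fut_sets <- purrr::map(1:10, ~ if (.x <= 5) 1:16 else .x) # alpha 5.3..., gamma 10
  projections <- dplyr::bind_rows(purrr::map(1:10, function(i) {
    dplyr::bind_rows(
      proj_row(sprintf("s%02d", i), "bird", "GLM", 1, "current", cur_sets[[i]]),
      proj_row(sprintf("s%02d", i), "bird", "GLM", 1, "future", fut_sets[[i]],
               "G1", "R1", "p1")
    )
  }))
  pc <- toy_projection_cube(species, projections, g)
  out <- region_delta_beta_s(pc, regions, "limited_dispersal")
  mean_alpha_fut <- (5 * 16 + 5) / 16
  expected <- 100 * ((10 / mean_alpha_fut) - 1) / 1 # beta_current = 10/10 = 1
  expect_equal(out$delta_beta_s, expected)

  # identical future -> zero change in every region
  proj_same <- dplyr::bind_rows(purrr::map(1:10, function(i) {
    dplyr::bind_rows(
      proj_row(sprintf("s%02d", i), "bird", "GLM", 1, "current", cur_sets[[i]]),
      proj_row(sprintf("s%02d", i), "bird", "GLM", 1, "future", cur_sets[[i]],
               "G1", "R1", "p1")
    )
  }))
  pc2 <- toy_projection_cube(species, proj_same, g)
  expect_equal(region_delta_beta_s(pc2, regions)$delta_beta_s, 0)
  # literal semantics: percent change in gamma over current mean alpha
  lit <- region_delta_beta_s(pc, regions, semantics = "literal")
  expect_equal(lit$delta_beta_s, 0) # gamma stays 10
})

test_that("range-size bins are equal-width on the log scale and exhaustive", {
  rec <- tibble::tibble(species_id = c("a", "b", "c"),
                        range_size = c(100, 1000, 10000))
  b <- bin_by_range_size(rec, 2)
  expect_equal(b$bins$bin, c(1L, 1L, 2L))
  expect_equal(b$edges, c(100, 1000, 10000))
  one <- bin_by_range_size(rec, 1)
  expect_equal(unique(one$bins$bin), 1L)
  withr::with_seed(5, {
    rec2 <- tibble::tibble(species_id = sprintf("s%d", 1:40),
                           range_size = sample(20:5000, 40))
    b2 <- bin_by_range_size(rec2, 4)
    expect_equal(sum(table(b2$bins$bin)), 40)
    expect_true(all(diff(b2$edges) > 0))
  })
  expect_warning(
    bin_by_range_size(tibble::tibble(species_id = c("a", "b"),
                                     range_size = c(50, 50)), 3),
    "single bin"
  )
})
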
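test_that("a pure SDM signal is attributed entirely to the SDM component", {
  tab <- simulate_design_table(effect_sd = c(3, 0, 0), noise_sd = 0, seed = 1)
  for (engine in list(nested_partition, full_factorial_partition)) {
    p <- engine(tab)
    shares <- setNames(p$table$share_explained, p$table$component)
    expect_equal(unname(shares["sdm"]), 100)
    expect_equal(unname(shares["gcm"]), 0)
    expect_equal(unname(shares["rcp"]), 0)
  }
})

test_that("component and residual deviance conserve the total", {
  withr::with_seed(2, {
    for (i in 1:10) {
      tab <- simulate_design_table(
        n_sdm = sample(2:4, 1), n_gcm = sample(2:5, 1), n_rcp = sample(2:4, 1),
        n_rep = sample(1:4, 1), effect_sd = runif(3, 0, 3), noise_sd = runif(1, 0.1, 2),
        seed = 100 + i
      )
      for (fit in list(nested_partition(tab), full_factorial_partition(tab))) {
        expect_equal(sum(fit$table$deviance), fit$total_deviance,
                     tolerance = 1e-8)
        keep <- fit$table$component != "residual"
        expect_equal(sum(fit$table$share_explained[keep]), 100, tolerance = 1e-6)
        expect_equal(sum(fit$table$share_total), 100, tolerance = 1e-6)
      }
    }
  })
})

test_that("sequential SS match the brute-force group-means oracle on small tables", {
  # all balanced shapes up to 4 x 3 x 2 levels with up to 5 replicates
  shapes <- tidyr::expand_grid(a = 2:4, b = 2:3, c = 2, r = c(1, 3, 5))
  for (i in seq_len(nrow(shapes))) {
    tab <- simulate_design_table(
      n_sdm = shapes$a[i], n_gcm = shapes$b[i], n_rcp = shapes$c[i],
      n_rep = shapes$r[i], effect_sd = c(2, 1.5, 1), noise_sd = 0.5,
      seed = 200 + i
    )
    nest <- nested_partition(tab)
    oracle <- oracle_nested_ss(tab)
    expect_equal(setNames(nest$table$deviance, nest$table$component),
                 oracle, tolerance = 1e-10)
    fact <- full_factorial_partition(tab)
    oracle_f <- oracle_factorial_ss(tab)
    expect_equal(setNames(fact$table$deviance, fact$table$component),
                 oracle_f, tolerance = 1e-10)
  }
})

test_that("engines agree with stats::anova sequential sums of squares", {
  tab <- simulate_design_table(n_sdm = 3, n_gcm = 4, n_rcp = 3, n_rep = 2,
                               effect_sd = c(2, 1, 0.5), noise_sd = 1, seed = 9)
  # drop rows to make the design unbalanced
  tab <- tab[-c(3, 17, 40, 41, 55), ]
  ref <- anova(lm(value ~ sdm + sdm:gcm + sdm:rcp, data = tab))
  nest <- nested_partition(tab)
  expect_equal(nest$table$deviance[1:3], ref$`Sum Sq`[1:3], tolerance = 1e-8)
  expect_equal(nest$table$deviance[4], ref$`Sum Sq`[4], tolerance = 1e-8)
  ref_f <- anova(lm(value ~ sdm + gcm + rcp, data = tab))
  fact <- full_factorial_partition(tab)
  expect_equal(fact$table$deviance[1:3], ref_f$`Sum Sq`[1:3], tolerance = 1e-8)
})

test_that("on balanced designs sequential main effects are order-invariant", {
  tab <- simulate_design_table(seed = 10, noise_sd = 1)
  fwd <- full_factorial_partition(tab)
  swapped <- dplyr::rename(tab, sdm = gcm, gcm = sdm)
  rev <- full_factorial_partition(swapped)
  fwd_ss <- setNames(fwd$table$deviance, fwd$table$component)
  rev_ss <- setNames(rev$table$deviance, rev$table$component)
  expect_equal(unname(fwd_ss["sdm"]), unname(rev_ss["gcm"]), tolerance = 1e-9)
  expect_equal(unname(fwd_ss["gcm"]), unname(rev_ss["sdm"]), tolerance = 1e-9)
  # the nested GCM/RCP terms absorb their within-SDM interaction, so they can
  # only exceed the factorial main effects; the SDM term coincides
  nest <- nested_partition(tab)
  expect_equal(nest$table$deviance[1], fwd$table$deviance[1], tolerance = 1e-9)
  expect_gte(nest$table$deviance[2], fwd_ss[["gcm"]] - 1e-9)
  expect_gte(nest$table$deviance[3], fwd_ss[["rcp"]] - 1e-9)
})

test_that("unbalanced 14-combo designs split engines but keep the sum identities", {
  des <- default_scenario_design()
  tab <- tidyr::expand_grid(
    sdm = sprintf("S%d", 1:4), des$combos, rep = 1:4
  )
  withr::with_seed(11, {
    tab$value <- as.integer(factor(tab$sdm)) * 1.5 +
      as.integer(factor(tab$gcm)) * 0.8 +
      as.integer(factor(tab$rcp)) * 0.4 + rnorm(nrow(tab), 0, 0.5)
  })
  nest <- nested_partition(tab)
  fact <- full_factorial_partition(tab)
  expect_false(isTRUE(all.equal(nest$table$deviance[2], fact$table$deviance[2])))
  for (fit in list(nest, fact)) {
    expect_equal(sum(fit$table$deviance), fit$total_deviance, tolerance = 1e-8)
  }
})

test_that("planted 9:4:1 effect variances are recovered within 5 points", {
  shares <- purrr::map(1:30, function(s) {
    tab <- simulate_design_table(n_sdm = 4, n_gcm = 5, n_rcp = 4, n_rep = 4,
                                 effect_sd = c(3, 2, 1), noise_sd = 0.1, seed = s)
    p <- nested_partition(tab)
    setNames(p$table$share_explained, p$table$component)[c("sdm", "gcm", "rcp")]
  })
  avg <- colMeans(do.call(rbind, shares))
  expect_equal(unname(avg["sdm"]), 100 * 9 / 14, tolerance = 5 / (100 * 9 / 14))
  expect_lt(abs(avg["sdm"] - 100 * 9 / 14), 5)
  expect_lt(abs(avg["gcm"] - 100 * 4 / 14), 5)
  expect_lt(abs(avg["rcp"] - 100 * 1 / 14), 5)
})

test_that("with no signal each component's share matches its df fraction", {
  res <- purrr::map(1:150, function(s) {
    tab <- simulate_design_table(effect_sd = c(0, 0, 0), noise_sd = 1, seed = 3000 + s)
    p <- nested_partition(tab)
    c(
      explained = p$explained_deviance / p$total_deviance,
      sdm = p$table$deviance[1] / p$total_deviance,
      df_model = sum(p$table$df[1:3]),
      df_total = p$n - 1
    )
  })
  m <- colMeans(do.call(rbind, res))
  expect_equal(unname(m["explained"]), m[["df_model"]] / m[["df_total"]],
               tolerance = 0.05)
  expect_equal(unname(m["sdm"]), 3 / m[["df_total"]], tolerance = 0.15)
})

test_that("exchangeable replicates explain almost nothing", {
  # mirrors treating cross-validation runs as replicates rather than a factor
  withr::with_seed(13, {
    under_1pc <- vapply(1:10, function(i) {
      tab <- simulate_design_table(effect_sd = c(3, 2, 1), noise_sd = 0.3,
                                   seed = 400 + i)
      y <- tab$value
      rss_full <- sum(lm(value ~ sdm + sdm:gcm + sdm:rcp, data = tab)$residuals^2)
      rss_rep <- sum(lm(value ~ sdm + sdm:gcm + sdm:rcp + factor(rep),
                        data = tab)$residuals^2)
      total <- sum((y - mean(y))^2)
      (rss_full - rss_rep) / total < 0.01
    }, logical(1))
    expect_true(all(under_1pc))
  })
})

test_that("degenerate tables are flagged rather than partitioned", {
  tab <- simulate_design_table(n_rep = 2, seed = 5)
  tab$value <- 1
  expect_warning(p <- nested_partition(tab), "constant response")
  expect_true(p$flag)
  expect_true(all(is.na(p$table$share_explained)))
  one_level <- simulate_design_table(n_gcm = 1, seed = 6)
  expect_warning(p2 <- nested_partition(one_level), "single level")
  expect_equal(p2$table$deviance[p2$table$component == "gcm"], 0, tolerance = 1e-9)
})

test_that("tidy and glance expose the partition in broom shape", {
  tab <- simulate_design_table(seed = 7)
  p <- nested_partition(tab)
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$component, c("sdm", "gcm", "rcp", "residual"))
  gl <- glance(p)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, nrow(tab))
  expect_false(gl$flag)
  p_int <- nested_partition(tab, include_interaction = TRUE)
  expect_equal(tidy(p_int)$component[4], "gcm_rcp")
  expect_lte(tidy(p_int)$deviance[5], tidy(p)$deviance[4] + 1e-9)
})

test_that("per-pixel partitioning localises a spatially confined RCP effect", {
  n_cell <- 50
  design <- tidyr::expand_grid(
    algorithm = sprintf("S%d", 1:3), gcm = sprintf("G%d", 1:2),
    rcp = sprintf("R%d", 1:3), repetition = 1:2
  )
  withr::with_seed(15, {
    recs <- purrr::map(1:n_cell, function(cell) {
      southern <- cell > 25
      v <- as.integer(factor(design$algorithm)) * 0.5 +
        rnorm(nrow(design), 0, 0.3) +
        if (southern) as.integer(factor(design$rcp)) * 2 else 0
      dplyr::mutate(design, cell = cell, taxon = "bird", period = "p1",
                    delta_alpha = v)
    }) |> dplyr::bind_rows()
  })
  pp <- partition_per_pixel(recs, "delta_alpha")
  rcp_share <- pp[pp$component == "rcp", ]
  south <- mean(rcp_share$share_explained[rcp_share$cell > 25])
  north <- mean(rcp_share$share_explained[rcp_share$cell <= 25])
  expect_gt(south, north)
  sums <- pp |>
    dplyr::filter(component != "residual") |>
    dplyr::group_by(cell) |>
    dplyr::summarise(s = sum(share_explained))
  expect_equal(sums$s, rep(100, n_cell), tolerance = 1e-6)
})

test_that("range-bin partitioning recovers bin-specific SDM dominance", {
  # rare species carry stronger SDM effects than widespread ones
  design <- tidyr::expand_grid(
    algorithm = sprintf("S%d", 1:4), gcm = sprintf("G%d", 1:3),
    rcp = sprintf("R%d", 1:2), repetition = 1:2
  )
  withr::with_seed(16, {
    recs <- purrr::map(1:12, function(i) {
      size <- round(10^(1.4 + i * 0.2))
      sdm_strength <- if (size < 200) 3 else 0.3
      dplyr::mutate(
        design,
        species_id = sprintf("sp%02d", i), range_size = size,
        ccs = sdm_strength * as.integer(factor(design$algorithm)) +
          0.5 * as.integer(factor(design$rcp)) + rnorm(nrow(design), 0, 0.2)
      )
    }) |> dplyr::bind_rows()
  })
  bins <- bin_by_range_size(dplyr::distinct(recs, species_id, range_size), 3)
  bp <- partition_by_range_bin(recs, bins, "ccs")
  sdm_by_bin <- bp[bp$component == "sdm", ]
  expect_lt(cor(sdm_by_bin$bin, sdm_by_bin$share_explained, method = "spearman"), 0)
  shares <- bp |>
    dplyr::filter(component != "residual") |>
    dplyr::group_by(bin) |>
    dplyr::summarise(s = sum(share_explained))
  expect_equal(shares$s, rep(100, nrow(shares)), tolerance = 1e-6)
  single <- partition_by_range_bin(recs, bin_by_range_size(
    dplyr::distinct(recs, species_id, range_size), 1
  ), "ccs")
  pooled <- nested_partition(recs, response = "ccs")
  expect_equal(single$deviance[1:4], pooled$table$deviance, tolerance = 1e-9)
})

test_that("threshold comparison drops a planted low-quality algorithm", {
  design <- tidyr::expand_grid(
    algorithm = c("GLM", "GAM", "BRT", "NOISY"), gcm = sprintf("G%d", 1:2),
    rcp = sprintf("R%d", 1:2), repetition = 1:3
  )
  withr::with_seed(17, {
    base <- dplyr::mutate(
      design,
      lcs = 0.3 + 0.1 * as.integer(factor(rcp)) +
        ifelse(algorithm == "NOISY", rnorm(nrow(design), 0, 0.25), 0) +
        rnorm(nrow(design), 0, 0.02)
    )
  })
  recs <- list(
    "0.4" = base,
    "0.6" = base,
    "0.7" = dplyr::filter(base, algorithm != "NOISY") # the noisy fit falls below 0.7
  )
  cmp <- threshold_sensitivity(recs, "lcs")
  expect_true(all(c(0.4, 0.6, 0.7) %in% cmp$threshold))
  n_rows <- dplyr::distinct(cmp, threshold, n_rows)$n_rows
  expect_true(all(diff(n_rows) <= 0))
  sdm_shares <- cmp$share_explained[cmp$component == "sdm"]
  expect_gt(abs(sdm_shares[1] - sdm_shares[3]), 1)
  expect_warning(
    threshold_sensitivity(list("0.4" = base, "0.9" = base[0, ]), "lcs"),
    "retains no usable records"
  )
})
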
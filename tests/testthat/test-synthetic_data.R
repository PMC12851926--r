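test_that("sector index echoes requested dimensions and flags the consuming bloc", {
  idx <- generate_sector_index(2, 2, 1, 2, eu_fraction = 0.5, seed = 1)
  expect_length(idx$regions, 2)
  expect_equal(nrow(idx$commodities), 3)
  expect_equal(n_sectors(idx), 6)
  expect_equal(idx$eu_members, "R01")
  expect_setequal(unique(idx$commodities$kind), c("crop", "livestock_product"))

  # full-database shape: 187 regions, 100 + 23 = 123 commodities, 6 categories
  big <- generate_sector_index(187, 100, 23, 6, eu_fraction = 0.15, seed = 1)
  expect_length(big$regions, 187)
  expect_equal(nrow(big$commodities), 123)
  expect_length(big$fd_categories, 6)

  expect_error(generate_sector_index(0, 1, 1, 1), class = "agstrand_error_invalid_argument")
  expect_error(generate_sector_index(2, 2, 1, 2, eu_fraction = 0),
               class = "agstrand_error_invalid_argument")
})

test_that("generated MRIO systems are balanced, productive and deterministic", {
  for (seed in 1:5) {
    idx <- generate_sector_index(seed = seed)
    sys <- generate_mrio(idx, feed_share = 0.4, seed = seed)
    expect_true(all(sys$Z >= 0) && all(sys$Y >= 0))
    # bit-exact row balance by construction
    expect_identical(sys$x, rowSums(sys$Z) + rowSums(sys$Y))
    A <- technical_coefficients(sys)
    expect_lt(max(Mod(eigen(A, only.values = TRUE)$values)), 1 - 1e-9)
  }
  idx <- generate_sector_index(seed = 3)
  expect_identical(generate_mrio(idx, seed = 11), generate_mrio(idx, seed = 11))
  expect_false(identical(generate_mrio(idx, seed = 11),
                         generate_mrio(idx, seed = 12)))
})

test_that("feed topology follows the feed_share argument", {
  idx <- generate_sector_index(seed = 2)
  st <- sector_table(idx)
  lvst <- which(st$kind == "livestock_product")

  no_feed <- generate_mrio(idx, feed_share = 0, seed = 2)
  expect_true(all(no_feed$Z[, lvst] == 0))

  fed <- generate_mrio(idx, feed_share = 0.4, seed = 7)
  expect_true(sum(fed$Z[st$kind == "crop", lvst]) > 0)
  # livestock sectors draw inputs only from crops; livestock rows sell nothing
  expect_true(all(fed$Z[lvst, ] == 0))
})

test_that("farm accounts conserve class totals and shape the concordance by kind", {
  idx <- generate_sector_index(seed = 1)
  totals <- c(buildings = 1000, machinery_equipment = 500,
              breeding_livestock = 200, land = 3000)
  fa <- generate_farm_accounts(idx, n_farm_types = 14, totals_by_class = totals,
                               seed = 1)
  got <- tapply(fa$account$values$eur, fa$account$values$asset_class, sum)
  expect_equal(got[names(totals)], totals, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(length(unique(fa$account$values$farm_type)), 14)
  expect_true(all(fa$account$values$eur >= 0))
  expect_setequal(unique(fa$account$values$asset_class), asset_classes())

  # livestock-oriented types map only to livestock products (and vice versa)
  ori <- fa$account$orientation
  com <- idx$commodities
  for (f in names(ori)) {
    kinds <- com$kind[fa$concordance[f, ] > 0]
    expected <- if (ori[[f]] == "livestock") "livestock_product" else "crop"
    expect_true(all(kinds == expected))
  }

  expect_error(generate_farm_accounts(idx, n_farm_types = 0),
               class = "agstrand_error_invalid_argument")
})

test_that("zero-weight farm types are generated on request and keep their values", {
  idx <- generate_sector_index(seed = 1)
  fa <- generate_farm_accounts(idx, n_farm_types = 4, n_zero_weight = 1, seed = 5)
  zero_rows <- rowSums(fa$concordance) == 0
  expect_equal(sum(zero_rows), 1)
  ft <- names(which(zero_rows))
  expect_gt(sum(fa$account$values$eur[fa$account$values$farm_type == ft]), 0)
})

test_that("diet tables are isocaloric, deterministic and fully mapped", {
  idx <- generate_sector_index(seed = 1)
  diet <- generate_diet_table(idx, kcal_target = 2500, seed = 4)
  expect_equal(sum(diet$items$intake_g_day * diet$items$kcal_per_g), 2500)
  expect_true(all(diet$items$kcal_per_g > 0))
  expect_true(all(diet$items$waste_fraction >= 0 & diet$items$waste_fraction < 1))
  # every commodity maps to exactly one item; excluded items map to none
  food <- diet$items[diet$items$group != "excluded", ]
  expect_setequal(food$commodity, idx$commodities$commodity)
  expect_true(all(is.na(diet$items$commodity[diet$items$group == "excluded"])))
  # ranges exist exactly where the scenario rules need them
  ranged <- diet$items$group %in% c("asf", "legume_nut_oil")
  expect_true(all(!is.na(diet$items$lower_g[ranged])))
  expect_true(all(diet$items$lower_g[ranged] <= diet$items$upper_g[ranged]))
  expect_identical(diet, generate_diet_table(idx, 2500, seed = 4))
  expect_error(generate_diet_table(idx, kcal_target = 0),
               class = "agstrand_error_invalid_argument")
})

test_that("deflators are normalised at base year and follow the closed form", {
  d <- generate_deflator(2014:2020, base_year = 2020, rate = 0.02)
  expect_equal(d$index[d$year == 2020], 1.0)
  expect_equal(d$index[d$year == 2019], 1 / 1.02)
  expect_equal(d$index[d$year == 2014], 1 / 1.02^6)
  r <- generate_deflator(2014:2020, seed = 9)
  expect_true(all(r$index > 0))
  expect_identical(r, generate_deflator(2014:2020, seed = 9))
  expect_error(generate_deflator(integer(0)),
               class = "agstrand_error_invalid_argument")
  expect_error(generate_deflator(2014:2019, base_year = 2020),
               class = "agstrand_error_invalid_argument")
})
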
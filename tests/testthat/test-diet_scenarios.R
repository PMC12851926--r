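test_that("scenario specs pair the ASF and legume rules as defined", {
  expect_equal(scenario_spec("moderate_asf")[c("asf_rule", "legume_rule")],
               list(asf_rule = "upper", legume_rule = "lower"))
  expect_equal(scenario_spec("low_asf")[c("asf_rule", "legume_rule")],
               list(asf_rule = "midpoint", legume_rule = "midpoint"))
  expect_equal(scenario_spec("zero_asf")[c("asf_rule", "legume_rule")],
               list(asf_rule = "zero", legume_rule = "upper"))
  expect_error(scenario_spec("vegan"))
})

test_that("scenario diets hit the range rules exactly and stay isocaloric", {
  idx <- generate_sector_index(seed = 1)
  diet <- generate_diet_table(idx, kcal_target = 2500, seed = 2)
  it <- diet$items

  for (level in c("moderate_asf", "low_asf", "zero_asf")) {
    sd <- build_scenario_diet(diet, scenario_spec(level, 2500))
    out <- sd$items
    expect_false(any(out$group == "excluded"))
    expect_equal(sum(out$intake_g_day * out$kcal_per_g), 2500,
                 tolerance = 1e-6 / 2500)
    asf <- out[out$group == "asf", ]
    expected_asf <- switch(level,
      moderate_asf = asf$upper_g,
      low_asf = (asf$lower_g + asf$upper_g) / 2,
      zero_asf = 0 * asf$upper_g
    )
    expect_equal(asf$intake_g_day, expected_asf)
    lno <- out[out$group == "legume_nut_oil", ]
    expected_lno <- switch(level,
      moderate_asf = lno$lower_g,
      low_asf = (lno$lower_g + lno$upper_g) / 2,
      zero_asf = lno$upper_g
    )
    expect_equal(lno$intake_g_day, expected_lno)
  }

  # ASF energy declines monotonically across the scenario ladder
  asf_kcal <- vapply(c("moderate_asf", "low_asf", "zero_asf"), function(lv) {
    out <- build_scenario_diet(diet, scenario_spec(lv, 2500))$items
    sum(out$intake_g_day[out$group == "asf"] * out$kcal_per_g[out$group == "asf"])
  }, numeric(1))
  expect_true(asf_kcal[1] >= asf_kcal[2] && asf_kcal[2] >= asf_kcal[3])
  expect_equal(unname(asf_kcal[3]), 0)
})

test_that("the other_plant rescale factor follows the energy bookkeeping", {
  # baseline: ASF 1000 kcal, legumes 500 kcal, other plant 1000 kcal;
  # forcing ASF -> 0 and legumes -> 1100 kcal leaves a 1400 kcal gap,
  # so other plant scales by 1.4
  items <- tibble::tibble(
    item = c("meat", "beans", "grain"),
    commodity = c("LVST01", "CROP01", "CROP02"),
    group = c("asf", "legume_nut_oil", "other_plant"),
    intake_g_day = c(500, 250, 500),
    kcal_per_g = c(2, 2, 2),
    waste_fraction = c(0.1, 0.1, 0.1),
    lower_g = c(50, 300, NA),
    upper_g = c(400, 550, NA)
  )
  diet <- make_diet_table(items, kcal_target = 2500)
  sd <- build_scenario_diet(diet, scenario_spec("zero_asf", 2500))
  expect_equal(sd$other_plant_factor, 1.4)
  expect_equal(sd$items$intake_g_day[sd$items$item == "grain"], 700)
  expect_equal(sd$asf_reduction_kcal, 1)

  # an ASF upper bound at 90.5% of baseline energy gives a 9.5% reduction
  items2 <- items
  items2$upper_g[1] <- 0.905 * items2$intake_g_day[1]
  sd2 <- build_scenario_diet(make_diet_table(items2),
                             scenario_spec("moderate_asf", 2500))
  expect_equal(sd2$asf_reduction_kcal, 0.095, tolerance = 1e-12)

  # no other_plant energy to close a residual gap -> infeasible
  items3 <- items[items$group != "other_plant", ]
  expect_error(build_scenario_diet(make_diet_table(items3),
                                   scenario_spec("zero_asf", 2500)),
               class = "agstrand_error_infeasible_scenario")
})

test_that("waste fractions convert intake to primary demand and cancel in ratios", {
  idx <- generate_sector_index(seed = 1)
  diet <- generate_diet_table(idx, seed = 3)
  base <- apply_waste(build_scenario_diet(diet, scenario_spec("baseline")))
  expect_equal(base$items$demand_g_day,
               base$items$intake_g_day / (1 - base$items$waste_fraction))

  one <- base
  one$items <- one$items[1, ]
  expect_equal(apply_waste(one, waste = 0.2)$items$demand_g_day,
               one$items$intake_g_day / 0.8)
  expect_equal(apply_waste(one, waste = 0)$items$demand_g_day,
               one$items$intake_g_day)
  expect_error(apply_waste(one, waste = 1),
               class = "agstrand_error_invalid_argument")

  # scenario/baseline demand ratio equals the intake ratio item-wise
  scen <- apply_waste(build_scenario_diet(diet, scenario_spec("low_asf")))
  joined <- dplyr::inner_join(scen$items, base$items, by = "item",
                              suffix = c("_s", "_b"))
  expect_equal(joined$demand_g_day_s / joined$demand_g_day_b,
               joined$intake_g_day_s / joined$intake_g_day_b,
               tolerance = 1e-12)
})

test_that("scenario final demand scales EU columns and leaves the rest untouched", {
  idx <- generate_sector_index(seed = 1)
  sys <- generate_mrio(idx, seed = 1)
  diet <- generate_diet_table(idx, seed = 1)
  base <- apply_waste(build_scenario_diet(diet, scenario_spec("baseline")))

  # identity shock
  Y_same <- scenario_final_demand(sys$Y, base$items, base$items, idx,
                                  population = diet$population)
  expect_identical(Y_same, sys$Y)

  zero <- apply_waste(build_scenario_diet(diet, scenario_spec("zero_asf")))
  Y0 <- scenario_final_demand(sys$Y, base$items, zero$items, idx,
                              population = diet$population)
  st <- sector_table(idx)
  fd <- agstrand:::fd_col_table(idx)
  eu_cols <- fd$region %in% idx$eu_members
  expect_true(all(Y0[st$kind == "livestock_product", eu_cols] == 0))
  expect_identical(Y0[, !eu_cols], sys$Y[, !eu_cols])

  # halving one commodity's demand halves its attributed embodied assets
  fa <- generate_farm_accounts(idx, seed = 1)
  ext <- allocate_assets(fa$account, fa$concordance, sys)
  b <- asset_intensity(ext, sys)
  L <- leontief_inverse(technical_coefficients(sys))
  target <- "CROP02"
  Yh <- sys$Y
  Yh[st$commodity == target, ] <- 0.5 * Yh[st$commodity == target, ]
  full <- embodied_assets(b, L, sys$Y, idx)$by_item
  halved <- embodied_assets(b, L, Yh, idx)$by_item
  expect_equal(halved$value[halved$commodity == target],
               0.5 * full$value[full$commodity == target], tolerance = 1e-12)
  expect_equal(halved$value[halved$commodity != target],
               full$value[full$commodity != target], tolerance = 1e-12)

  bad <- base$items
  bad$commodity[1] <- "NOT_A_COMMODITY"
  expect_error(scenario_final_demand(sys$Y, bad, bad, idx),
               class = "agstrand_error_mapping")
})

test_that("items appearing only in the scenario are sourced pro rata to producers", {
  idx <- generate_sector_index(seed = 1)
  sys <- generate_mrio(idx, seed = 1)
  st <- sector_table(idx)
  target <- "CROP01"
  rows <- st$commodity == target
  Yb <- sys$Y
  Yb[rows, ] <- 0  # no baseline demand for the target item

  base <- tibble::tibble(commodity = target, demand_g_day = 0)
  scen <- tibble::tibble(commodity = target, demand_g_day = 100)
  pop <- tibble::tibble(region = idx$eu_members,
                        population = rep(1e7, length(idx$eu_members)))
  Y2 <- scenario_final_demand(Yb, base, scen, idx, population = pop)
  added <- sum(Y2[rows, ]) - sum(Yb[rows, ])
  expect_equal(added, 100 * sum(pop$population) * 365 / 1e6, tolerance = 1e-9)
  expect_error(scenario_final_demand(Yb, base, scen, idx),
               class = "agstrand_error_mapping")
})
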
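embodied_for <- function(study, Y) {
  ext <- allocate_assets(study$account, study$conc, study$mrio)
  b <- asset_intensity(ext, study$mrio)
  L <- leontief_inverse(technical_coefficients(study$mrio))
  embodied_assets(b, L, Y, study$index)
}

test_that("identical baseline and scenario strand nothing", {
  study <- default_study(seed = 2)
  emb <- embodied_for(study, study$mrio$Y)
  s <- compute_stranding(emb, emb)
  expect_true(all(s$cells$stranded_eur == 0))
  expect_true(all(s$cells$new_requirement_eur == 0))
  expect_equal(s$totals$stranded_share, c(0, 0))
})

test_that("stranding cells split losses and gains without netting", {
  study <- default_study(seed = 7)
  emb_base <- embodied_for(study, study$mrio$Y)
  st <- sector_table(study$index)
  Y2 <- study$mrio$Y
  Y2[st$kind == "livestock_product", ] <- 0.5 * Y2[st$kind == "livestock_product", ]
  Y2[st$kind == "crop", ] <- 1.2 * Y2[st$kind == "crop", ]
  s <- compute_stranding(emb_base, embodied_for(study, Y2))
  expect_true(all(s$cells$stranded_eur >= 0))
  expect_true(all(s$cells$new_requirement_eur >= 0))
  expect_true(all(s$cells$stranded_eur * s$cells$new_requirement_eur == 0))
  expect_true(all(s$cells$stranded_eur <= s$cells$baseline_eur + 1e-12))
  # stranded + retained = baseline, cell by cell
  expect_equal(s$cells$stranded_eur + s$cells$retained_eur,
               s$cells$baseline_eur, tolerance = 1e-12)
  # plant-side gains are reported, not netted against ASF losses
  expect_gt(sum(s$cells$new_requirement_eur[s$cells$chain == "plant_food"]), 0)
})

test_that("stranded totals are monotone in the ASF reduction fraction", {
  study <- default_study(seed = 3)
  emb_base <- embodied_for(study, study$mrio$Y)
  st <- sector_table(study$index)
  asf_rows <- st$kind == "livestock_product"

  stranded <- vapply(c(0, 0.095, 0.60, 1.0), function(f) {
    Y2 <- study$mrio$Y
    Y2[asf_rows, ] <- (1 - f) * Y2[asf_rows, ]
    s <- compute_stranding(emb_base, embodied_for(study, Y2))
    s$totals$stranded_eur[s$totals$denominator == "fixed_assets_excluding_land"]
  }, numeric(1))
  expect_equal(stranded[1], 0)
  expect_true(all(diff(stranded) >= 0))

  # the 100% case strands all ASF-linked embodied assets in a closed system
  Y0 <- study$mrio$Y
  Y0[asf_rows, ] <- 0
  s100 <- compute_stranding(emb_base, embodied_for(study, Y0))
  expect_equal(s100$asf_stranded_share, 1)
})

test_that("depreciation rate is the flow over the depreciable stock", {
  expect_equal(depreciation_rate(9, 100), 0.09)
  expect_equal(depreciation_rate(0, 50), 0)
  expect_equal(depreciation_rate(9, c(40, 60)), 0.09)
  expect_error(depreciation_rate(9, 0), class = "agstrand_error_invalid_input")

  # planted-rate recovery from the synthetic account
  idx <- generate_sector_index(seed = 1)
  fa <- generate_farm_accounts(idx, depreciation_rate = 0.07, seed = 1)
  fixed <- fa$account$values$eur[
    fa$account$values$asset_class %in%
      c("buildings", "machinery_equipment", "breeding_livestock")
  ]
  expect_equal(depreciation_rate(fa$account$depreciation_total, fixed), 0.07,
               tolerance = 1e-12)
})

test_that("depreciation trajectories follow their closed forms", {
  sl <- depreciation_schedule(0.10, "straight_line", horizon = 15)
  path <- depreciation_path(100, sl)
  expect_equal(path$value[path$year == 5], 50)
  expect_equal(path$value[path$year == 10], 0)
  expect_equal(sl$full_depreciation_year, 10)
  expect_true(all(diff(path$value) <= 0) && all(path$value >= 0))

  sl9 <- depreciation_schedule(0.09, "straight_line")
  expect_equal(sl9$full_depreciation_year, 12)  # value hits 0 at t = 1/0.09 ~ 11.1
  expect_equal(depreciation_path(100, sl9)$value[11 + 1], 100 * (1 - 0.09 * 11))
  expect_equal(depreciation_path(100, sl9)$value[12 + 1], 0)

  db <- depreciation_schedule(0.09, "declining_balance", horizon = 12)
  expect_true(is.na(db$full_depreciation_year))
  expect_equal(depreciation_path(100, db)$value[10 + 1], 100 * 0.91^10)

  # both methods agree at t = 0 and to first order in r at t = 1
  r <- 0.001
  p_sl <- depreciation_path(1, depreciation_schedule(r, "straight_line", 1))
  p_db <- depreciation_path(1, depreciation_schedule(r, "declining_balance", 1))
  expect_equal(p_sl$value[1], p_db$value[1])
  expect_lt(abs(p_sl$value[2] - p_db$value[2]), r^2)

  expect_error(depreciation_schedule(0, "straight_line"),
               class = "agstrand_error_undefined_full_depreciation")
})

test_that("accelerated phase-out residuals equal undepreciated book value", {
  sl <- depreciation_schedule(0.09, "straight_line")
  expect_equal(accelerated_phaseout_residual(100, sl, 10), 10)
  expect_equal(accelerated_phaseout_residual(100, sl, 0), 100)
  expect_equal(accelerated_phaseout_residual(100, sl, 12), 0)
  expect_equal(accelerated_phaseout_residual(c(60, 40), sl, 10), 10)
  expect_error(accelerated_phaseout_residual(100, sl, -1),
               class = "agstrand_error_invalid_argument")
})

test_that("sensitivity intervals recover min and max historical deviations", {
  flat <- tibble::tibble(year = 2014:2019, index = 1)
  attr(flat, "base_year") <- 2020L
  flat <- dplyr::bind_rows(flat, tibble::tibble(year = 2020, index = 1))
  hist <- tibble::tibble(item = "a", year = 2014:2019,
                         eur_nominal = c(90, 95, 100, 102, 105, 110))
  base <- tibble::tibble(item = "a", eur = 100)
  si <- sensitivity_intervals(hist, flat, base, 2020)
  expect_equal(si$min_dev, -0.10)
  expect_equal(si$max_dev, 0.10)
  expect_equal(c(si$lower_eur, si$upper_eur), c(90, 110))

  # constant history at the base value gives a degenerate interval
  hist0 <- tibble::tibble(item = "a", year = 2014:2019, eur_nominal = 100)
  si0 <- sensitivity_intervals(hist0, flat, base, 2020)
  expect_equal(c(si0$min_dev, si0$max_dev), c(0, 0))
  expect_equal(c(si0$lower_eur, si0$upper_eur), c(100, 100))

  # nominal history under compounding inflation deflates to the hand result
  defl <- generate_deflator(2014:2020, base_year = 2020, rate = 0.02)
  nominal <- tibble::tibble(item = "a", year = 2014:2019,
                            eur_nominal = c(90, 95, 100, 102, 105, 110))
  real_hand <- nominal$eur_nominal * 1.02^(2020 - nominal$year)
  si2 <- sensitivity_intervals(nominal, defl, base, 2020)
  expect_equal(si2$min_dev, min(real_hand - 100) / 100, tolerance = 1e-12)
  expect_equal(si2$max_dev, max(real_hand - 100) / 100, tolerance = 1e-12)

  expect_error(sensitivity_intervals(hist, flat, tibble::tibble(item = "a", eur = 0)),
               class = "agstrand_error_undefined_deviation")
})

test_that("synthetic histories deflate back inside the planted volatility band", {
  idx <- generate_sector_index(seed = 1)
  fa <- generate_farm_accounts(idx, seed = 1)
  defl <- generate_deflator(2014:2020, base_year = 2020, seed = 2)
  hist <- generate_asset_history(fa$account, defl, volatility = 0.1, seed = 3)
  base <- fa$account$values |>
    dplyr::summarise(eur = sum(eur), .by = c("asset_class", "region"))
  si <- sensitivity_intervals(hist, defl, base, 2020)
  expect_true(all(si$min_dev >= -0.1 - 1e-9))
  expect_true(all(si$max_dev <= 0.1 + 1e-9))
  expect_true(all(si$min_dev <= si$max_dev))
})
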
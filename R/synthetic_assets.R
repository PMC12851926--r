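#' Generate FADN-like farm-type asset accounts and a concordance matrix
#'
#' Creates per-farm-type, per-region asset values (in million EUR) for the
#' four asset classes, together with a farm-type-to-commodity concordance.
#' Accounts cover only the consuming-bloc (EU-like) regions, mirroring the
#' coverage of farm accountancy surveys. Farm types are split into
#' livestock-oriented and crop-oriented; breeding-livestock assets sit only on
#' livestock-oriented farms. Class-wise sums of the generated values equal
#' `totals_by_class` up to floating-point rounding. The planted depreciation
#' rate is applied to the three fixed-asset classes to produce a total
#' depreciation figure for the account year (land does not depreciate).
#'
#' @param index A [generate_sector_index()] object.
#' @param n_farm_types Number of farm types (>= 1); the first
#'   `ceiling(n_farm_types / 2)` are livestock-oriented.
#' @param totals_by_class Named non-negative vector over the four asset
#'   classes, million EUR. Defaults are EU-scale magnitudes (land ~ 70% of
#'   total farm capital, buildings ~ 14%, machinery ~ 12%, breeding
#'   livestock ~ 4%).
#' @param depreciation_rate Planted annual depreciation rate applied to the
#'   fixed-asset classes.
#' @param mixed_weight Optional fractional concordance weight linking each
#'   livestock-oriented farm type to one crop commodity (models mixed farms).
#' @param n_zero_weight Number of farm types (taken from the end) whose
#'   concordance rows are all zero, modelling unallocatable assets such as
#'   aquaculture holdings outside the commodity scope.
#' @param year Account year label.
#' @param seed Integer seed.
#' @return A list with `account` (a `farm_asset_account`: tibble of
#'   `farm_type`, `region`, `asset_class`, `eur` plus the year, total
#'   depreciation and planted rate) and `concordance` (farm_type x commodity
#'   weight matrix of class `concordance`).
#' @export
generate_farm_accounts <- function(index, n_farm_types = 4,
                                   totals_by_class = c(
                                     buildings = 150000,
                                     machinery_equipment = 130000,
                                     breeding_livestock = 45000,
                                     land = 770000
                                   ),
                                   depreciation_rate = 0.09,
                                   mixed_weight = 0,
                                   n_zero_weight = 0,
                                   year = 2020, seed = 1L) {
  assert_that(inherits(index, "sector_index"), "`index` must be a sector_index")
  assert_that(n_farm_types >= 1, "`n_farm_types` must be >= 1")
  assert_that(all(ASSET_CLASSES %in% names(totals_by_class)),
              "`totals_by_class` must name all four asset classes")
  assert_that(all(totals_by_class >= 0), "`totals_by_class` must be >= 0")
  assert_that(n_zero_weight >= 0 && n_zero_weight <= n_farm_types,
              "`n_zero_weight` must be between 0 and `n_farm_types`")

  set.seed(as.integer(seed))
  farm_types <- sprintf("FT%02d", seq_len(n_farm_types))
  n_lvst_types <- ceiling(n_farm_types / 2)
  orientation <- c(rep("livestock", n_lvst_types),
                   rep("crop", n_farm_types - n_lvst_types))
  regions <- index$eu_members
  commodities <- index$commodities

  # concordance: each farm type maps to a random non-empty subset of
  # commodities of its own kind, weight 1; zero-weight types stay all-zero
  conc <- matrix(0, n_farm_types, nrow(commodities),
                 dimnames = list(farm_types, commodities$commodity))
  zero_types <- if (n_zero_weight > 0) {
    farm_types[seq(n_farm_types - n_zero_weight + 1, n_farm_types)]
  } else {
    character()
  }
  for (f in seq_len(n_farm_types)) {
    if (farm_types[f] %in% zero_types) next
    kind <- if (orientation[f] == "livestock") "livestock_product" else "crop"
    pool <- which(commodities$kind == kind)
    if (length(pool) == 0) next
    k <- sample.int(length(pool), size = max(1L, ceiling(length(pool) / 2)))
    conc[f, pool[k]] <- 1
    if (mixed_weight > 0 && orientation[f] == "livestock") {
      crops <- which(commodities$kind == "crop")
      if (length(crops) > 0) conc[f, crops[sample.int(length(crops), 1)]] <- mixed_weight
    }
  }
  class(conc) <- c("concordance", class(conc))

  # values: random shares over farm_type x region per class, scaled to totals;
  # breeding livestock is restricted to livestock-oriented farm types
  grid <- tidyr::expand_grid(farm_type = farm_types, region = regions)
  values <- lapply(ASSET_CLASSES, function(cl) {
    w <- runif(nrow(grid))
    if (cl == "breeding_livestock") {
      mask <- orientation[match(grid$farm_type, farm_types)] == "livestock"
      if (any(mask)) w[!mask] <- 0
    }
    tibble::tibble(
      farm_type = grid$farm_type, region = grid$region,
      asset_class = cl,
      eur = totals_by_class[[cl]] * w / sum(w)
    )
  })
  values <- dplyr::bind_rows(values)

  fixed_total <- sum(values$eur[values$asset_class %in% FIXED_ASSET_CLASSES])
  account <- structure(
    list(
      values = values,
      year = year,
      orientation = setNames(orientation, farm_types),
      depreciation_total = depreciation_rate * fixed_total,
      planted_depreciation_rate = depreciation_rate
    ),
    class = "farm_asset_account"
  )
  list(account = account, concordance = conc)
}

#' @export
print.farm_asset_account <- function(x, ...) {
  tot <- tapply(x$values$eur, x$values$asset_class, sum)
  cat(sprintf("<farm_asset_account> year %d, %d farm types x %d regions\n",
              x$year, length(unique(x$values$farm_type)),
              length(unique(x$values$region))))
  for (cl in ASSET_CLASSES) {
    cat(sprintf("  %-20s %12.1f MEUR\n", cl, tot[[cl]]))
  }
  invisible(x)
}

#' Generate a synthetic nominal asset-value history
#'
#' Produces nominal historical asset values per asset class and region for the
#' years preceding the account year. Real (base-year price) values fluctuate
#' around the account value by at most `volatility`; nominal values are the
#' real values re-inflated with the deflator, so deflating them back recovers
#' deviations within `c(-volatility, volatility)` of the base value.
#'
#' @param account A `farm_asset_account`.
#' @param deflator A [generate_deflator()] table covering `years` and the
#'   account year.
#' @param years Historical years.
#' @param volatility Maximum absolute fractional deviation of real historical
#'   values from the account value.
#' @param seed Integer seed.
#' @return Tibble `(asset_class, region, year, eur_nominal)`.
#' @export
generate_asset_history <- function(account, deflator, years = 2014:2019,
                                   volatility = 0.1, seed = 1L) {
  assert_that(inherits(account, "farm_asset_account"),
              "`account` must be a farm_asset_account")
  assert_that(all(years %in% deflator$year), "`deflator` must cover `years`")
  set.seed(as.integer(seed))
  base <- account$values |>
    dplyr::summarise(eur = sum(.data$eur), .by = c("asset_class", "region"))
  idx <- setNames(deflator$index, deflator$year)
  tidyr::expand_grid(base, year = years) |>
    dplyr::mutate(
      eur_nominal = .data$eur * (1 + runif(dplyr::n(), -volatility, volatility)) *
        idx[as.character(.data$year)]
    ) |>
    dplyr::select("asset_class", "region", "year", "eur_nominal")
}
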
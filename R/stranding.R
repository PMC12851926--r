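#' Stranded assets and new-asset requirements between two embodied results
#'
#' Compares baseline and scenario embodied-asset results cell by cell
#' (commodity x asset class x value-chain tag). Stranded value is the
#' positive part of the decline, the new-asset requirement the positive part
#' of the increase; a cell never has both. Losses and gains are reported
#' gross, never netted. Land is summarised separately from the three
#' fixed-asset classes, and every share is reported next to its denominator.
#'
#' @param baseline,scenario `embodied_result` objects on the same index.
#' @return A `stranding_result`: list with `cells` (per-cell tibble),
#'   `by_class` (per asset class: baseline, scenario, stranded, new
#'   requirement, stranded share), `totals` (fixed-assets-excluding-land and
#'   land rows, with the denominator named) and `asf_stranded_share`
#'   (stranded fraction of baseline ASF-linked fixed assets).
#' @export
compute_stranding <- function(baseline, scenario) {
  assert_that(inherits(baseline, "embodied_result") &&
                inherits(scenario, "embodied_result"),
              "inputs must be embodied_result objects", "schema")
  key <- c("commodity", "kind", "asset_class", "chain")
  b <- dplyr::rename(baseline$by_item, baseline_eur = "value")
  s <- dplyr::rename(scenario$by_item, scenario_eur = "value")
  assert_that(identical(b[key], s[key]),
              "baseline and scenario results are not aligned", "schema")
  cells <- dplyr::left_join(b, s, by = key) |>
    dplyr::mutate(
      stranded_eur = pmax(0, .data$baseline_eur - .data$scenario_eur),
      new_requirement_eur = pmax(0, .data$scenario_eur - .data$baseline_eur),
      retained_eur = pmin(.data$baseline_eur, .data$scenario_eur)
    )

  by_class <- cells |>
    dplyr::summarise(dplyr::across(
      c("baseline_eur", "scenario_eur", "stranded_eur", "new_requirement_eur"),
      sum
    ), .by = "asset_class") |>
    dplyr::mutate(
      stranded_share = ifelse(.data$baseline_eur > 0,
                              .data$stranded_eur / .data$baseline_eur, 0)
    )

  total_of <- function(classes, label) {
    sub <- dplyr::filter(cells, .data$asset_class %in% classes)
    tibble::tibble(
      denominator = label,
      baseline_eur = sum(sub$baseline_eur),
      stranded_eur = sum(sub$stranded_eur),
      new_requirement_eur = sum(sub$new_requirement_eur),
      stranded_share = ifelse(sum(sub$baseline_eur) > 0,
                              sum(sub$stranded_eur) / sum(sub$baseline_eur), 0)
    )
  }
  totals <- dplyr::bind_rows(
    total_of(FIXED_ASSET_CLASSES, "fixed_assets_excluding_land"),
    total_of("land", "land")
  )

  asf <- dplyr::filter(cells, .data$chain %in% c("livestock", "feed"),
                       .data$asset_class %in% FIXED_ASSET_CLASSES)
  asf_share <- ifelse(sum(asf$baseline_eur) > 0,
                      sum(asf$stranded_eur) / sum(asf$baseline_eur), 0)

  structure(
    list(cells = cells, by_class = by_class, totals = totals,
         asf_stranded_share = asf_share),
    class = "stranding_result"
  )
}

#' @export
print.stranding_result <- function(x, ...) {
  t <- x$totals
  for (i in seq_len(nrow(t))) {
    cat(sprintf(
      "%-28s stranded %10.1f of %10.1f MEUR (%.1f%%), new requirement %10.1f MEUR\n",
      t$denominator[i], t$stranded_eur[i], t$baseline_eur[i],
      100 * t$stranded_share[i], t$new_requirement_eur[i]
    ))
  }
  cat(sprintf("ASF-linked fixed assets stranded: %.1f%% of their baseline\n",
              100 * x$asf_stranded_share))
  invisible(x)
}

#' Mean depreciation rate from depreciation flow and depreciable stock
#'
#' @param total_depreciation Depreciation allocated to the account year (EUR).
#' @param depreciable_values Depreciable asset values (EUR); summed if a
#'   vector.
#' @return The annual rate `total_depreciation / sum(depreciable_values)`.
#' @export
depreciation_rate <- function(total_depreciation, depreciable_values) {
  total <- sum(depreciable_values)
  assert_that(total > 0, "depreciable asset values must sum to > 0",
              "invalid_input")
  assert_that(total_depreciation >= 0, "`total_depreciation` must be >= 0",
              "invalid_input")
  total_depreciation / total
}

#' Depreciation schedule
#'
#' Straight-line book value declines linearly, `V(t) = V0 * max(0, 1 - r t)`,
#' reaching zero at `t = 1/r`; declining balance follows
#' `V(t) = V0 * (1 - r)^t` and never reaches zero exactly.
#'
#' @param rate Annual depreciation rate `r` (per year).
#' @param method `"straight_line"` (default) or `"declining_balance"`.
#' @param horizon Trajectory length in years.
#' @return A `depreciation_schedule` with `rate`, `method`, `horizon` and
#'   `full_depreciation_year` (`ceiling(1/r)` for straight line, `NA` for
#'   declining balance).
#' @export
depreciation_schedule <- function(rate, method = c("straight_line", "declining_balance"),
                                  horizon = 40L) {
  method <- match.arg(method)
  assert_that(horizon >= 0, "`horizon` must be >= 0")
  if (method == "straight_line" && rate <= 0) {
    stop_agstrand(
      "straight-line full depreciation is undefined for rate <= 0",
      "undefined_full_depreciation"
    )
  }
  assert_that(rate >= 0 && rate <= 1, "`rate` must be in [0, 1]")
  structure(
    list(rate = rate, method = method, horizon = as.integer(horizon),
         full_depreciation_year = if (method == "straight_line") {
           ceiling(1 / rate)
         } else {
           NA_integer_
         }),
    class = "depreciation_schedule"
  )
}

# Remaining book-value fraction at integer or fractional year t.
depreciation_factor <- function(schedule, t) {
  switch(schedule$method,
    straight_line = pmax(0, 1 - schedule$rate * t),
    declining_balance = (1 - schedule$rate)^t
  )
}

#' Book-value trajectory under a depreciation schedule
#'
#' @param V0 Initial value (EUR), >= 0.
#' @param schedule A [depreciation_schedule()].
#' @return Tibble `(year, value)` for years `0:horizon`.
#' @examples
#' sched <- depreciation_schedule(0.09)
#' depreciation_path(100, sched)
#' @export
depreciation_path <- function(V0, schedule) {
  assert_that(V0 >= 0, "`V0` must be >= 0")
  assert_that(inherits(schedule, "depreciation_schedule"),
              "`schedule` must be a depreciation_schedule")
  years <- 0:schedule$horizon
  tibble::tibble(year = years, value = V0 * depreciation_factor(schedule, years))
}

#' Residual stranded value under an accelerated phase-out
#'
#' With assets retired at a deadline instead of running to full depreciation,
#' the stranded loss is the undepreciated book value remaining at the
#' deadline (a complete investment stop from year zero is assumed; book
#' value follows the depreciation schedule regardless of utilisation).
#'
#' @param stranded_values Stranded asset values (EUR), one per item; summed.
#' @param schedule A [depreciation_schedule()].
#' @param deadline_years Years until forced retirement (>= 0).
#' @return Total residual book value at the deadline (EUR).
#' @export
accelerated_phaseout_residual <- function(stranded_values, schedule,
                                          deadline_years) {
  assert_that(deadline_years >= 0, "`deadline_years` must be >= 0")
  assert_that(all(stranded_values >= 0), "stranded values must be >= 0")
  sum(stranded_values) * depreciation_factor(schedule, deadline_years)
}

#' Historical sensitivity intervals for asset values
#'
#' Deflates nominal historical values to base-year prices, computes each
#' group's minimum and maximum fractional deviation from its base-year
#' value, and returns the implied value interval
#' `base * (1 + min_dev, 1 + max_dev)`. Re-running scenarios at the interval
#' endpoints brackets the headline results.
#'
#' @param history Tibble with grouping columns plus `year` and
#'   `eur_nominal` (historical nominal values).
#' @param deflator A [generate_deflator()] table covering the history years;
#'   real value = nominal / index.
#' @param base Tibble with the same grouping columns plus `eur`: the
#'   base-year (already real) values.
#' @param base_year Base year label (must match the deflator normalisation).
#' @return Tibble: grouping columns plus `base_eur`, `min_dev`, `max_dev`,
#'   `lower_eur`, `upper_eur`.
#' @export
sensitivity_intervals <- function(history, deflator, base, base_year = 2020) {
  assert_that(all(c("year", "eur_nominal") %in% names(history)),
              "`history` needs `year` and `eur_nominal` columns", "schema")
  assert_that("eur" %in% names(base), "`base` needs an `eur` column", "schema")
  assert_that(nrow(history) > 0, "`history` must contain at least one year")
  assert_that(attr(deflator, "base_year") %||% base_year == base_year,
              "deflator is not normalised to `base_year`", "schema")
  assert_that(all(history$year %in% deflator$year),
              "`deflator` must cover all history years", "schema")

  keys <- setdiff(names(base), "eur")
  idx <- setNames(deflator$index, deflator$year)
  real <- history |>
    dplyr::mutate(eur_real = .data$eur_nominal / idx[as.character(.data$year)]) |>
    dplyr::inner_join(dplyr::rename(base, base_eur = "eur"), by = keys)
  if (any(real$base_eur == 0)) {
    stop_agstrand("deviation undefined: base-year value is zero",
                  "undefined_deviation")
  }
  real |>
    dplyr::mutate(dev = (.data$eur_real - .data$base_eur) / .data$base_eur) |>
    dplyr::summarise(
      base_eur = .data$base_eur[1],
      min_dev = min(.data$dev), max_dev = max(.data$dev),
      .by = dplyr::all_of(keys)
    ) |>
    dplyr::mutate(lower_eur = .data$base_eur * (1 + .data$min_dev),
                  upper_eur = .data$base_eur * (1 + .data$max_dev))
}
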
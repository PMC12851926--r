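#' Generate a synthetic baseline diet table
#'
#' Builds one diet item per commodity (same code), plus the two items outside
#' healthy-reference-diet scope (`alcohol`, `other`, group `excluded`, mapped
#' to no commodity). Items carry per-capita intake (g per person per day),
#' energy density (kcal per g), a food-specific waste fraction, a diet group,
#' and, for the animal-sourced-food (ASF) and legume/nut/oil groups, reference
#' intake ranges used by the scenario rules. Baseline intakes are rescaled so
#' total energy equals `kcal_target` exactly; ranges are then defined relative
#' to the rescaled baseline. A per-region population for the consuming bloc is
#' included.
#'
#' @param index A [generate_sector_index()] object.
#' @param kcal_target Total baseline energy intake, kcal per person per day.
#' @param legume_fraction Fraction of crop commodities assigned to the
#'   legume/nut/oil group; at least one crop always remains in the freely
#'   scaling `other_plant` group.
#' @param seed Integer seed.
#' @return A `diet_table`: list with `items` (tibble: `item`, `commodity`,
#'   `group`, `intake_g_day`, `kcal_per_g`, `waste_fraction`, `lower_g`,
#'   `upper_g`), `population` (tibble: `region`, `population`) and
#'   `kcal_target`.
#' @export
generate_diet_table <- function(index, kcal_target = 2500,
                                legume_fraction = 0.3, seed = 1L) {
  assert_that(inherits(index, "sector_index"), "`index` must be a sector_index")
  assert_that(kcal_target > 0, "`kcal_target` must be > 0")
  set.seed(as.integer(seed))

  com <- index$commodities
  crops <- com$commodity[com$kind == "crop"]
  n_legume <- min(floor(legume_fraction * length(crops)), length(crops) - 1L)
  legumes <- if (n_legume > 0) crops[seq_len(n_legume)] else character()

  items <- tibble::tibble(
    item = c(com$commodity, "alcohol", "other"),
    commodity = c(com$commodity, NA, NA),
    group = c(
      ifelse(com$kind == "livestock_product", "asf",
             ifelse(com$commodity %in% legumes, "legume_nut_oil", "other_plant")),
      "excluded", "excluded"
    )
  ) |>
    dplyr::mutate(
      intake_g_day = c(runif(nrow(com), 50, 300), runif(2, 20, 80)),
      kcal_per_g = runif(dplyr::n(), 0.8, 3.5),
      waste_fraction = runif(dplyr::n(), 0.05, 0.3)
    )

  # isocaloric rescale of the baseline, then ranges relative to it
  total_kcal <- sum(items$intake_g_day * items$kcal_per_g)
  items$intake_g_day <- items$intake_g_day * kcal_target / total_kcal

  upper <- rep(NA_real_, nrow(items))
  lower <- rep(NA_real_, nrow(items))
  is_asf <- items$group == "asf"
  is_lno <- items$group == "legume_nut_oil"
  upper[is_asf] <- items$intake_g_day[is_asf] * runif(sum(is_asf), 0.6, 0.95)
  lower[is_asf] <- upper[is_asf] * runif(sum(is_asf), 0.2, 0.6)
  lower[is_lno] <- items$intake_g_day[is_lno] * runif(sum(is_lno), 1.05, 1.3)
  upper[is_lno] <- lower[is_lno] * runif(sum(is_lno), 1.2, 1.8)
  items$lower_g <- lower
  items$upper_g <- upper

  population <- tibble::tibble(
    region = index$eu_members,
    population = round(runif(length(index$eu_members), 5e6, 6e7))
  )

  structure(
    list(items = items, population = population, kcal_target = kcal_target),
    class = "diet_table"
  )
}

#' @export
print.diet_table <- function(x, ...) {
  cat(sprintf(
    "<diet_table> %d items (%s); %.0f kcal/person/day; population %.3g\n",
    nrow(x$items),
    paste(sprintf("%s: %d", names(table(x$items$group)), table(x$items$group)),
          collapse = ", "),
    sum(x$items$intake_g_day * x$items$kcal_per_g),
    sum(x$population$population)
  ))
  invisible(x)
}

#' Generate a GDP-style price deflator index
#'
#' Produces a per-year price index normalised to 1 at `base_year`. With a
#' constant inflation `rate`, the index is `(1 + rate)^(year - base_year)`
#' (so the year before base is `1 / (1 + rate)`); with `rate = NULL` yearly
#' inflation is drawn uniformly from 0-5% as a seeded random walk. Nominal
#' values are converted to base-year prices by dividing by the index.
#'
#' @param years Years to cover (must include `base_year`).
#' @param base_year Normalisation year.
#' @param rate Constant annual inflation rate, or `NULL` for a random walk.
#' @param seed Integer seed (unused when `rate` is given).
#' @return Tibble `(year, index)` with attribute `base_year`.
#' @export
generate_deflator <- function(years = 2014:2020, base_year = 2020,
                              rate = NULL, seed = 1L) {
  assert_that(length(years) > 0, "`years` must be non-empty")
  assert_that(base_year %in% years, "`base_year` must be in `years`")
  yrs <- sort(unique(as.integer(years)))
  if (is.null(rate)) {
    set.seed(as.integer(seed))
    infl <- runif(length(yrs) - 1, 0, 0.05)
  } else {
    assert_that(rate > -1, "`rate` must be > -1")
    infl <- rep(rate, length(yrs) - 1)
  }
  logp <- cumsum(c(0, log1p(infl)))
  index <- exp(logp - logp[match(base_year, yrs)])
  out <- tibble::tibble(year = yrs, index = index)
  attr(out, "base_year") <- as.integer(base_year)
  out
}
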
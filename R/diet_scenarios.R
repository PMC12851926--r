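SCENARIO_LEVELS <- c("baseline", "moderate_asf", "low_asf", "zero_asf")

#' Scenario specification for healthy-reference-diet shocks
#'
#' Encodes the three animal-sourced-food (ASF) reduction scenarios as fixed
#' rule pairs: `moderate_asf` sets ASF items to the upper limit of their
#' reference intake range and legumes/nuts/oils to their lower limit;
#' `low_asf` sets both groups to range midpoints; `zero_asf` removes ASF
#' entirely and sets legumes/nuts/oils to their upper limit. All scenarios
#' are rescaled to an isocaloric target via the freely adjusting
#' `other_plant` group.
#'
#' @param level One of `"baseline"`, `"moderate_asf"`, `"low_asf"`,
#'   `"zero_asf"`.
#' @param kcal_target Isocaloric target, kcal per person per day.
#' @return A `scenario_spec` list with `level`, `asf_rule`, `legume_rule`
#'   and `kcal_target`.
#' @export
scenario_spec <- function(level, kcal_target = 2500) {
  level <- match.arg(level, SCENARIO_LEVELS)
  assert_that(kcal_target > 0, "`kcal_target` must be > 0")
  rules <- switch(level,
    baseline = c(asf = "baseline", legume = "baseline"),
    moderate_asf = c(asf = "upper", legume = "lower"),
    low_asf = c(asf = "midpoint", legume = "midpoint"),
    zero_asf = c(asf = "zero", legume = "upper")
  )
  structure(
    list(level = level, asf_rule = rules[["asf"]],
         legume_rule = rules[["legume"]], kcal_target = kcal_target),
    class = "scenario_spec"
  )
}

rule_intake <- function(rule, lower, upper, baseline) {
  switch(rule,
    baseline = baseline,
    lower = lower,
    midpoint = (lower + upper) / 2,
    upper = upper,
    zero = 0 * baseline
  )
}

#' Build a scenario diet from a baseline diet table
#'
#' Applies the spec's rules: ASF and legume/nut/oil intakes are set from
#' their reference ranges, the out-of-scope items (`alcohol`, `other`) are
#' removed, and the remaining plant items (`other_plant`) are rescaled by a
#' single common factor so total energy equals the isocaloric target. The
#' factor may be above or below one and is reported. The resulting ASF
#' reduction relative to baseline is reported on both a kcal and a mass
#' basis.
#'
#' @param baseline A `diet_table`.
#' @param spec A [scenario_spec()].
#' @return A `scenario_diet`: list with `items` (baseline columns plus
#'   scenario `intake_g_day`), `level`, `kcal_target`, `other_plant_factor`,
#'   `asf_reduction_kcal` and `asf_reduction_mass`.
#' @export
build_scenario_diet <- function(baseline, spec) {
  assert_that(inherits(baseline, "diet_table"), "`baseline` must be a diet_table")
  assert_that(inherits(spec, "scenario_spec"), "`spec` must be a scenario_spec")
  items <- baseline$items

  if (spec$level == "baseline") {
    out <- items
    factor_op <- 1
    red_kcal <- red_mass <- 0
  } else {
    ranged <- items$group %in% c("asf", "legume_nut_oil")
    missing_range <- ranged & (is.na(items$lower_g) | is.na(items$upper_g))
    assert_that(!any(missing_range),
                "every ASF and legume/nut/oil item needs an intake range",
                "schema")
    out <- items[items$group != "excluded", , drop = FALSE]
    base_asf_kcal <- sum(out$intake_g_day[out$group == "asf"] *
                           out$kcal_per_g[out$group == "asf"])
    base_asf_mass <- sum(out$intake_g_day[out$group == "asf"])

    is_asf <- out$group == "asf"
    is_lno <- out$group == "legume_nut_oil"
    is_op <- out$group == "other_plant"
    out$intake_g_day[is_asf] <- rule_intake(
      spec$asf_rule, out$lower_g[is_asf], out$upper_g[is_asf],
      out$intake_g_day[is_asf]
    )
    out$intake_g_day[is_lno] <- rule_intake(
      spec$legume_rule, out$lower_g[is_lno], out$upper_g[is_lno],
      out$intake_g_day[is_lno]
    )

    fixed_kcal <- sum(out$intake_g_day[!is_op] * out$kcal_per_g[!is_op])
    op_kcal <- sum(out$intake_g_day[is_op] * out$kcal_per_g[is_op])
    gap <- spec$kcal_target - fixed_kcal
    if (op_kcal <= 0 && abs(gap) > 1e-9) {
      stop_agstrand(
        "scenario is infeasible: no other_plant energy available to close the kcal gap",
        "infeasible_scenario"
      )
    }
    factor_op <- if (op_kcal > 0) gap / op_kcal else 1
    if (factor_op < 0) {
      stop_agstrand(
        "scenario is infeasible: fixed-group energy already exceeds the kcal target",
        "infeasible_scenario"
      )
    }
    out$intake_g_day[is_op] <- out$intake_g_day[is_op] * factor_op

    new_asf_kcal <- sum(out$intake_g_day[is_asf] * out$kcal_per_g[is_asf])
    new_asf_mass <- sum(out$intake_g_day[is_asf])
    red_kcal <- if (base_asf_kcal > 0) 1 - new_asf_kcal / base_asf_kcal else 0
    red_mass <- if (base_asf_mass > 0) 1 - new_asf_mass / base_asf_mass else 0
  }

  structure(
    list(items = out, level = spec$level, kcal_target = spec$kcal_target,
         other_plant_factor = factor_op,
         asf_reduction_kcal = red_kcal, asf_reduction_mass = red_mass),
    class = "scenario_diet"
  )
}

#' @export
print.scenario_diet <- function(x, ...) {
  cat(sprintf(
    "<scenario_diet> level %s: %.1f kcal/person/day, ASF reduction %.1f%% (kcal), other_plant factor %.3f\n",
    x$level, sum(x$items$intake_g_day * x$items$kcal_per_g),
    100 * x$asf_reduction_kcal, x$other_plant_factor
  ))
  invisible(x)
}

#' Convert intake to primary demand by applying food-waste fractions
#'
#' Each item's waste fraction `w` is the share of supplied food lost between
#' supply and intake, so demand = intake / (1 - w). Applied identically to
#' baseline and scenario diets, the waste factor cancels from the
#' scenario-to-baseline demand ratio used to shock final demand.
#'
#' @param diet A `scenario_diet` (or `diet_table`).
#' @param waste Optional per-item waste fractions overriding the table's own
#'   `waste_fraction` column; values must satisfy `0 <= w < 1`.
#' @return The input object with a `demand_g_day` column added to `items`.
#' @export
apply_waste <- function(diet, waste = NULL) {
  items <- diet$items
  w <- waste %||% items$waste_fraction
  assert_that(length(w) %in% c(1L, nrow(items)),
              "`waste` must be scalar or one value per item")
  assert_that(all(w >= 0 & w < 1), "waste fractions must satisfy 0 <= w < 1")
  diet$items$demand_g_day <- items$intake_g_day / (1 - w)
  diet
}

#' Shock final demand with a scenario diet
#'
#' Scales the consuming-bloc columns of the final-demand matrix commodity by
#' commodity with the scenario-to-baseline demand ratio. Non-EU demand
#' (exports of EU production to the rest of the world) is unchanged unless
#' `global_adoption = TRUE`. A food item with zero baseline demand but
#' positive scenario demand has its new demand allocated across EU
#' final-demand columns in proportion to population and sourced pro-rata to
#' the commodity's current producers (static technology and trade
#' structure).
#'
#' @param Y Final-demand matrix (sector x region-category).
#' @param baseline_demand,scenario_demand Tibbles with `commodity` and
#'   `demand_g_day` columns (e.g. `apply_waste(...)$items`); rows with `NA`
#'   commodity (non-food items) are ignored.
#' @param index The system's `sector_index`.
#' @param population Tibble `(region, population)`; needed only for
#'   zero-baseline items.
#' @param global_adoption If `TRUE`, demand columns of all regions are
#'   shocked, not only the consuming bloc.
#' @return The shocked final-demand matrix `Y'`, same dimensions as `Y`.
#' @export
scenario_final_demand <- function(Y, baseline_demand, scenario_demand, index,
                                  population = NULL, global_adoption = FALSE) {
  base <- baseline_demand[!is.na(baseline_demand$commodity),
                          c("commodity", "demand_g_day")]
  scen <- scenario_demand[!is.na(scenario_demand$commodity),
                          c("commodity", "demand_g_day")]
  known <- index$commodities$commodity
  bad <- setdiff(unique(c(base$commodity, scen$commodity)), known)
  if (length(bad) > 0) {
    stop_agstrand(
      paste0("food items map to unknown commodities: ", paste(bad, collapse = ", ")),
      "mapping"
    )
  }

  st <- sector_table(index)
  fd <- fd_col_table(index)
  shock_cols <- if (global_adoption) {
    seq_len(nrow(fd))
  } else {
    which(fd$region %in% index$eu_members)
  }

  base_d <- setNames(base$demand_g_day, base$commodity)
  scen_d <- setNames(scen$demand_g_day, scen$commodity)
  Y2 <- Y
  for (s in known) {
    b <- if (s %in% names(base_d)) base_d[[s]] else 0
    v <- if (s %in% names(scen_d)) scen_d[[s]] else 0
    rows <- which(st$commodity == s)
    if (b > 0) {
      Y2[rows, shock_cols] <- Y[rows, shock_cols] * (v / b)
    } else if (v > 0) {
      assert_that(!is.null(population),
                  "`population` is required for items with zero baseline demand",
                  "mapping")
      pop <- setNames(population$population, population$region)
      col_w <- pop[fd$region[shock_cols]]
      col_w[is.na(col_w)] <- 0
      total_t <- v * sum(pop) * 365 / 1e6  # g/day/person -> tonnes/yr
      src_w <- rowSums(Y[rows, , drop = FALSE])
      if (sum(src_w) == 0) src_w <- rep(1, length(rows))
      src_w <- src_w / sum(src_w)
      if (sum(col_w) > 0) {
        # population-proportional across regions, even across a region's
        # fd categories (col_w repeats the region population per category)
        col_share <- col_w / sum(col_w)
        Y2[rows, shock_cols] <- Y[rows, shock_cols] +
          total_t * outer(src_w, col_share)
      }
    }
  }
  Y2
}
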
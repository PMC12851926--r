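RUN_CONFIG_KEYS <- c(
  "seed", "n_regions", "n_crops", "n_livestock", "n_fd", "eu_fraction",
  "n_farm_types", "n_zero_weight", "mixed_weight", "totals_by_class",
  "planted_depreciation_rate", "feed_share", "crop_use_share", "fd_scale",
  "kcal_target", "legume_fraction", "scenarios", "global_adoption",
  "depreciation_method", "phaseout_deadline_years", "history_years",
  "base_year", "inflation_rate", "history_volatility", "out_dir"
)

#' Build and validate a pipeline run configuration
#'
#' Unknown keys are rejected; scenario levels are checked against the known
#' set. Defaults give the desk-scale study: a 3-region x 6-commodity x
#' 2-category system with 4 farm types, the 2,500 kcal isocaloric target,
#' all three ASF-reduction scenarios, straight-line depreciation and a
#' 10-year accelerated phase-out deadline.
#'
#' @param ... Named configuration values overriding the defaults (see
#'   `agstrand:::RUN_CONFIG_KEYS` for the full set).
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 42L, n_regions = 3L, n_crops = 4L, n_livestock = 2L, n_fd = 2L,
    eu_fraction = 2 / 3, n_farm_types = 4L, n_zero_weight = 0L,
    mixed_weight = 0,
    totals_by_class = c(buildings = 150000, machinery_equipment = 130000,
                        breeding_livestock = 45000, land = 770000),
    planted_depreciation_rate = 0.09,
    feed_share = 0.4, crop_use_share = 0.05, fd_scale = 1000,
    kcal_target = 2500, legume_fraction = 0.3,
    scenarios = c("moderate_asf", "low_asf", "zero_asf"),
    global_adoption = FALSE,
    depreciation_method = "straight_line", phaseout_deadline_years = 10,
    history_years = 2014:2019, base_year = 2020L, inflation_rate = NULL,
    history_volatility = 0.1, out_dir = NULL
  )
  override <- list(...)
  if (length(override) == 1 && is.null(names(override)) &&
      is.list(override[[1]])) {
    override <- override[[1]]
  }
  unknown <- setdiff(names(override), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop_agstrand(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
                  "config")
  }
  cfg[names(override)] <- override
  assert_that(all(cfg$scenarios %in% setdiff(SCENARIO_LEVELS, "baseline")),
              "`scenarios` must be drawn from moderate_asf/low_asf/zero_asf",
              "config")
  assert_that(cfg$depreciation_method %in% c("straight_line", "declining_balance"),
              "`depreciation_method` must be straight_line or declining_balance",
              "config")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [run_config()] keys.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_agstrand(paste0("config not found: ", path), "io")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$totals_by_class)) {
    raw$totals_by_class <- unlist(raw$totals_by_class)
  }
  run_config(raw)
}

# Canonical JSON form of a config (named lists sorted, vectors preserved).
# out_dir is excluded so runs of the same study to different directories
# hash identically.
config_json <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg <- cfg[order(names(cfg))]
  jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full pipeline: generate, allocate, footprint, shock, strand
#'
#' Executes the end-to-end study on synthetic data: sector index, balanced
#' MRIO system, farm accounts and concordance, baseline diet, deflator and
#' asset history are generated from the config seed; assets are allocated to
#' sectors; embodied assets are computed for the baseline and each scenario
#' final demand; stranding, depreciation pathways, accelerated phase-out
#' residuals and historical sensitivity intervals are derived. When
#' `config$out_dir` is set, all inputs and results are written as delimited
#' tables together with a manifest (seed, config hash, per-file MD5
#' checksums); identical config and seed give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all intermediate and final objects:
#'   `index`, `mrio`, `account`, `concordance`, `diet`, `deflator`,
#'   `history`, `extension`, `intensity`, `leontief`, `baseline_embodied`,
#'   `scenario_diets`, `scenario_embodied`, `stranding`,
#'   `depreciation_rate`, `depreciation_paths`, `phaseout_residuals`,
#'   `sensitivity`, `summary`, and `manifest` (when written).
#' @export
run_pipeline <- function(config = run_config()) {
  assert_that(inherits(config, "run_config"), "`config` must be a run_config")
  seed <- as.integer(config$seed)
  # stage-specific seeds, kept inside 32-bit integer range for any input seed
  sub_seed <- function(k) as.integer((as.numeric(seed) + k) %% .Machine$integer.max)

  stage <- function(name, expr) {
    tryCatch(expr, agstrand_error = function(e) {
      stop_agstrand(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                    "pipeline", parent = e)
    })
  }

  index <- stage("index", generate_sector_index(
    config$n_regions, config$n_crops, config$n_livestock, config$n_fd,
    config$eu_fraction, sub_seed(0)
  ))
  mrio <- stage("mrio", generate_mrio(
    index, config$feed_share, config$crop_use_share, config$fd_scale, sub_seed(1)
  ))
  fa <- stage("accounts", generate_farm_accounts(
    index, config$n_farm_types, config$totals_by_class,
    depreciation_rate = config$planted_depreciation_rate,
    mixed_weight = config$mixed_weight, n_zero_weight = config$n_zero_weight,
    year = config$base_year, seed = sub_seed(2)
  ))
  diet <- stage("diet", generate_diet_table(
    index, config$kcal_target, config$legume_fraction, sub_seed(3)
  ))
  deflator <- stage("deflator", generate_deflator(
    c(config$history_years, config$base_year), config$base_year,
    config$inflation_rate, sub_seed(4)
  ))
  history <- stage("history", generate_asset_history(
    fa$account, deflator, config$history_years, config$history_volatility,
    sub_seed(5)
  ))

  ext <- stage("allocate", allocate_assets(fa$account, fa$concordance, mrio))
  A <- stage("coefficients", technical_coefficients(mrio))
  L <- stage("leontief", leontief_inverse(A))
  b <- stage("intensity", asset_intensity(ext, mrio))
  emb_base <- stage("footprint_baseline", embodied_assets(b, L, mrio$Y, index))

  base_diet <- stage("diet_baseline", apply_waste(
    build_scenario_diet(diet, scenario_spec("baseline", config$kcal_target))
  ))

  scenario_diets <- list()
  scenario_embodied <- list()
  stranding <- list()
  for (level in config$scenarios) {
    sd <- stage(paste0("diet_", level), apply_waste(
      build_scenario_diet(diet, scenario_spec(level, config$kcal_target))
    ))
    Y2 <- stage(paste0("shock_", level), scenario_final_demand(
      mrio$Y, base_diet$items, sd$items, index,
      population = diet$population, global_adoption = config$global_adoption
    ))
    emb <- stage(paste0("footprint_", level),
                 embodied_assets(b, L, Y2, index))
    scenario_diets[[level]] <- sd
    scenario_embodied[[level]] <- emb
    stranding[[level]] <- stage(paste0("strand_", level),
                                compute_stranding(emb_base, emb))
  }

  fixed_vals <- fa$account$values$eur[
    fa$account$values$asset_class %in% FIXED_ASSET_CLASSES
  ]
  dep_rate <- stage("depreciation_rate", depreciation_rate(
    fa$account$depreciation_total, fixed_vals
  ))
  schedule <- stage("schedule", depreciation_schedule(
    dep_rate, config$depreciation_method
  ))
  depreciation_paths <- dplyr::bind_rows(lapply(config$scenarios, function(lv) {
    fixed <- dplyr::filter(stranding[[lv]]$totals,
                           .data$denominator == "fixed_assets_excluding_land")
    dplyr::mutate(depreciation_path(fixed$stranded_eur, schedule),
                  scenario = lv, .before = 1)
  }))
  phaseout_residuals <- tibble::tibble(
    scenario = config$scenarios,
    deadline_years = config$phaseout_deadline_years,
    residual_eur = vapply(config$scenarios, function(lv) {
      fixed <- dplyr::filter(stranding[[lv]]$totals,
                             .data$denominator == "fixed_assets_excluding_land")
      accelerated_phaseout_residual(fixed$stranded_eur, schedule,
                                    config$phaseout_deadline_years)
    }, numeric(1))
  )

  base_vals <- fa$account$values |>
    dplyr::summarise(eur = sum(.data$eur), .by = c("asset_class", "region"))
  sensitivity <- stage("sensitivity", sensitivity_intervals(
    history, deflator, base_vals, config$base_year
  ))

  summary <- dplyr::bind_rows(lapply(config$scenarios, function(lv) {
    dplyr::mutate(stranding[[lv]]$totals, scenario = lv, .before = 1)
  }))

  result <- list(
    config = config, index = index, mrio = mrio, account = fa$account,
    concordance = fa$concordance, diet = diet, deflator = deflator,
    history = history, extension = ext, intensity = b, leontief = L,
    baseline_embodied = emb_base, baseline_diet = base_diet,
    scenario_diets = scenario_diets, scenario_embodied = scenario_embodied,
    stranding = stranding, depreciation_rate = dep_rate,
    schedule = schedule, depreciation_paths = depreciation_paths,
    phaseout_residuals = phaseout_residuals, sensitivity = sensitivity,
    summary = summary
  )

  if (!is.null(config$out_dir)) {
    result$manifest <- write_run(result, config$out_dir)
  }
  invisible(result)
}

# Write all run artifacts plus a manifest with seed, config hash and
# per-file checksums. File set and contents are fully determined by
# (config, seed), so manifests of identical runs are byte-identical.
write_run <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- result$config

  write_mrio(result$mrio, dir)
  write_study_inputs(result$account, result$concordance, result$diet,
                     result$deflator, dir)
  write_table(result$history, file.path(dir, "asset_history.csv"))
  write_table(result$extension$allocation_report,
              file.path(dir, "allocation_report.csv"))

  by_item <- dplyr::bind_rows(c(
    list(baseline = result$baseline_embodied$by_item),
    lapply(result$scenario_embodied, function(e) e$by_item)
  ), .id = "scenario")
  write_table(by_item, file.path(dir, "embodied_by_item.csv"))

  cells <- dplyr::bind_rows(lapply(result$stranding, function(s) s$cells),
                            .id = "scenario")
  write_table(cells, file.path(dir, "stranding_cells.csv"))
  write_table(result$summary, file.path(dir, "stranding_summary.csv"))
  write_table(result$depreciation_paths, file.path(dir, "depreciation_paths.csv"))
  write_table(result$phaseout_residuals, file.path(dir, "phaseout_residuals.csv"))
  write_table(result$sensitivity, file.path(dir, "sensitivity.csv"))

  diets <- dplyr::bind_rows(c(
    list(baseline = result$baseline_diet$items),
    lapply(result$scenario_diets, function(d) d$items)
  ), .id = "scenario")
  write_table(diets, file.path(dir, "scenario_diets.csv"))

  cfg_path <- file.path(dir, "config.json")
  writeLines(config_json(config), cfg_path)

  files <- sort(setdiff(list.files(dir), "manifest.json"))
  checksums <- unname(tools::md5sum(file.path(dir, files)))
  manifest <- list(
    seed = as.integer(config$seed),
    config_hash = unname(tools::md5sum(cfg_path)),
    files = lapply(seq_along(files), function(i) {
      list(path = files[i], md5 = checksums[i])
    })
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}
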
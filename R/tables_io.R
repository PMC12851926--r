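#' @importFrom readr read_csv write_csv cols col_character col_double col_integer col_logical
NULL

write_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

read_table <- function(path, col_types) {
  if (!file.exists(path)) {
    stop_agstrand(paste0("cannot read table: ", path), "io")
  }
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' Write a synthetic MRIO system to canonical delimited tables
#'
#' Emits `regions.csv`, `commodities.csv`, `fd_categories.csv`,
#' `mrio_z.csv` (long, non-zero flows), `mrio_y.csv` and `mrio_x.csv` into
#' `dir`. All tables are comma-separated UTF-8 with a header row; doubles are
#' written in shortest round-trip form, so readers recover values exactly.
#'
#' @param mrio An `mrio_system`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_mrio <- function(mrio, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- mrio$index
  st <- sector_table(idx)
  fd <- fd_col_table(idx)

  paths <- c(
    write_table(tibble::tibble(region = idx$regions,
                               eu_member = idx$regions %in% idx$eu_members),
                file.path(dir, "regions.csv")),
    write_table(idx$commodities, file.path(dir, "commodities.csv")),
    write_table(tibble::tibble(fd_category = idx$fd_categories),
                file.path(dir, "fd_categories.csv"))
  )

  nz <- which(mrio$Z != 0, arr.ind = TRUE)
  z_long <- tibble::tibble(
    origin_region = st$region[nz[, 1]], origin_commodity = st$commodity[nz[, 1]],
    dest_region = st$region[nz[, 2]], dest_commodity = st$commodity[nz[, 2]],
    tonnes = mrio$Z[nz]
  ) |> dplyr::arrange(.data$origin_region, .data$origin_commodity,
                      .data$dest_region, .data$dest_commodity)
  ny <- which(mrio$Y != 0, arr.ind = TRUE)
  y_long <- tibble::tibble(
    origin_region = st$region[ny[, 1]], origin_commodity = st$commodity[ny[, 1]],
    dest_region = fd$region[ny[, 2]], fd_category = fd$fd_category[ny[, 2]],
    tonnes = mrio$Y[ny]
  ) |> dplyr::arrange(.data$origin_region, .data$origin_commodity,
                      .data$dest_region, .data$fd_category)
  x_long <- tibble::tibble(region = st$region, commodity = st$commodity,
                           tonnes = as.numeric(mrio$x))

  c(paths,
    write_table(z_long, file.path(dir, "mrio_z.csv")),
    write_table(y_long, file.path(dir, "mrio_y.csv")),
    write_table(x_long, file.path(dir, "mrio_x.csv"))) |>
    invisible()
}

#' Read an MRIO system from canonical delimited tables
#'
#' @param dir Directory containing the tables written by [write_mrio()].
#' @return An `mrio_system`.
#' @export
read_mrio <- function(dir) {
  regions <- read_table(file.path(dir, "regions.csv"),
                        cols(region = col_character(), eu_member = col_logical()))
  commodities <- read_table(file.path(dir, "commodities.csv"),
                            cols(commodity = col_character(), kind = col_character()))
  fdc <- read_table(file.path(dir, "fd_categories.csv"),
                    cols(fd_category = col_character()))
  index <- structure(
    list(regions = regions$region, commodities = commodities,
         fd_categories = fdc$fd_category,
         eu_members = regions$region[regions$eu_member], seed = NA_integer_),
    class = "sector_index"
  )
  st <- sector_table(index)
  fd <- fd_col_table(index)

  z_long <- read_table(file.path(dir, "mrio_z.csv"),
                       cols(origin_region = col_character(),
                            origin_commodity = col_character(),
                            dest_region = col_character(),
                            dest_commodity = col_character(),
                            tonnes = col_double()))
  y_long <- read_table(file.path(dir, "mrio_y.csv"),
                       cols(origin_region = col_character(),
                            origin_commodity = col_character(),
                            dest_region = col_character(),
                            fd_category = col_character(),
                            tonnes = col_double()))
  x_long <- read_table(file.path(dir, "mrio_x.csv"),
                       cols(region = col_character(), commodity = col_character(),
                            tonnes = col_double()))

  Z <- matrix(0, nrow(st), nrow(st), dimnames = list(st$sector, st$sector))
  Z[cbind(match(paste(z_long$origin_region, z_long$origin_commodity, sep = "."),
                st$sector),
          match(paste(z_long$dest_region, z_long$dest_commodity, sep = "."),
                st$sector))] <- z_long$tonnes
  Y <- matrix(0, nrow(st), nrow(fd), dimnames = list(st$sector, fd$col))
  Y[cbind(match(paste(y_long$origin_region, y_long$origin_commodity, sep = "."),
                st$sector),
          match(paste(y_long$dest_region, y_long$fd_category, sep = "."),
                fd$col))] <- y_long$tonnes
  x <- setNames(numeric(nrow(st)), st$sector)
  x[paste(x_long$region, x_long$commodity, sep = ".")] <- x_long$tonnes

  structure(list(Z = Z, Y = Y, x = x, index = index), class = "mrio_system")
}

#' Write farm accounts, concordance, diet, population and deflator tables
#'
#' @param account A `farm_asset_account`.
#' @param conc A `concordance` matrix.
#' @param diet A `diet_table`.
#' @param deflator A deflator tibble.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_study_inputs <- function(account, conc, diet, deflator, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conc_long <- tibble::tibble(
    farm_type = rep(rownames(conc), ncol(conc)),
    commodity = rep(colnames(conc), each = nrow(conc)),
    weight = as.numeric(conc)
  ) |> dplyr::filter(.data$weight != 0)
  meta <- tibble::tibble(
    key = c("year", "depreciation_total", "planted_depreciation_rate"),
    value = c(account$year, account$depreciation_total,
              account$planted_depreciation_rate)
  )
  farm_types <- tibble::tibble(farm_type = names(account$orientation),
                               orientation = unname(account$orientation))
  paths <- c(
    write_table(account$values, file.path(dir, "assets.csv")),
    write_table(farm_types, file.path(dir, "farm_types.csv")),
    write_table(meta, file.path(dir, "account_meta.csv")),
    write_table(conc_long, file.path(dir, "concordance.csv")),
    write_table(diet$items, file.path(dir, "diet.csv")),
    write_table(diet$population, file.path(dir, "population.csv")),
    write_table(deflator, file.path(dir, "deflator.csv"))
  )
  invisible(paths)
}

#' Read farm accounts, concordance, diet and deflator tables
#'
#' @param dir Directory written by [write_study_inputs()].
#' @param index The system's `sector_index` (supplies the commodity list for
#'   the concordance matrix).
#' @param base_year Deflator base year.
#' @return List with `account`, `concordance`, `diet`, `deflator`.
#' @export
read_study_inputs <- function(dir, index, base_year = 2020) {
  values <- read_table(file.path(dir, "assets.csv"),
                       cols(farm_type = col_character(), region = col_character(),
                            asset_class = col_character(), eur = col_double()))
  farm_types <- read_table(file.path(dir, "farm_types.csv"),
                           cols(farm_type = col_character(),
                                orientation = col_character()))
  meta <- read_table(file.path(dir, "account_meta.csv"),
                     cols(key = col_character(), value = col_double()))
  metav <- setNames(meta$value, meta$key)
  account <- structure(
    list(values = values, year = as.integer(metav[["year"]]),
         orientation = setNames(farm_types$orientation, farm_types$farm_type),
         depreciation_total = metav[["depreciation_total"]],
         planted_depreciation_rate = metav[["planted_depreciation_rate"]]),
    class = "farm_asset_account"
  )

  conc_long <- read_table(file.path(dir, "concordance.csv"),
                          cols(farm_type = col_character(),
                               commodity = col_character(),
                               weight = col_double()))
  conc <- matrix(0, nrow(farm_types), nrow(index$commodities),
                 dimnames = list(farm_types$farm_type,
                                 index$commodities$commodity))
  conc[cbind(match(conc_long$farm_type, rownames(conc)),
             match(conc_long$commodity, colnames(conc)))] <- conc_long$weight
  class(conc) <- c("concordance", class(conc))

  items <- read_table(file.path(dir, "diet.csv"),
                      cols(item = col_character(), commodity = col_character(),
                           group = col_character(), intake_g_day = col_double(),
                           kcal_per_g = col_double(), waste_fraction = col_double(),
                           lower_g = col_double(), upper_g = col_double()))
  population <- read_table(file.path(dir, "population.csv"),
                           cols(region = col_character(), population = col_double()))
  diet <- structure(
    list(items = items, population = population,
         kcal_target = sum(items$intake_g_day * items$kcal_per_g)),
    class = "diet_table"
  )

  deflator <- read_table(file.path(dir, "deflator.csv"),
                         cols(year = col_integer(), index = col_double()))
  attr(deflator, "base_year") <- as.integer(base_year)

  list(account = account, concordance = conc, diet = diet, deflator = deflator)
}

#' Validate canonical input tables against their schemas
#'
#' Checks every recognised table present in `dir` for required columns,
#' non-negativity, waste fractions in `[0, 1)`, a positive deflator index,
#' and — when the three MRIO tables are present — the row balance
#' `x = Z 1 + Y 1` per sector. Failures are listed with their table, row and
#' a message naming the offending coordinate.
#'
#' @param dir Directory of tables.
#' @param balance_tol Relative tolerance for the row-balance check.
#' @return List with `ok` (logical) and `violations` (tibble `table`, `row`,
#'   `message`).
#' @export
validate_tables <- function(dir, balance_tol = 1e-8) {
  violations <- list()
  note <- function(tab, row, msg) {
    violations[[length(violations) + 1]] <<-
      tibble::tibble(table = tab, row = as.integer(row), message = msg)
  }
  check_nonneg <- function(tab, df, col) {
    bad <- which(df[[col]] < 0)
    for (i in bad) {
      note(tab, i, sprintf("%s is negative (%g)", col, df[[col]][i]))
    }
  }
  load <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) return(NULL)
    tryCatch(readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
             error = function(e) {
               stop_agstrand(paste0("unreadable table ", path, ": ",
                                    conditionMessage(e)), "io")
             })
  }

  schemas <- list(
    mrio_z.csv = list(cols = c("origin_region", "origin_commodity",
                               "dest_region", "dest_commodity", "tonnes"),
                      nonneg = "tonnes"),
    mrio_y.csv = list(cols = c("origin_region", "origin_commodity",
                               "dest_region", "fd_category", "tonnes"),
                      nonneg = "tonnes"),
    mrio_x.csv = list(cols = c("region", "commodity", "tonnes"),
                      nonneg = "tonnes"),
    assets.csv = list(cols = c("farm_type", "region", "asset_class", "eur"),
                      nonneg = "eur"),
    concordance.csv = list(cols = c("farm_type", "commodity", "weight"),
                           nonneg = "weight"),
    diet.csv = list(cols = c("item", "group", "intake_g_day", "kcal_per_g",
                             "waste_fraction"),
                    nonneg = "intake_g_day"),
    deflator.csv = list(cols = c("year", "index"), nonneg = "index")
  )
  tables <- list()
  for (name in names(schemas)) {
    df <- load(name)
    if (is.null(df)) next
    tables[[name]] <- df
    missing <- setdiff(schemas[[name]]$cols, names(df))
    if (length(missing) > 0) {
      note(name, NA, paste0("missing columns: ", paste(missing, collapse = ", ")))
      next
    }
    check_nonneg(name, df, schemas[[name]]$nonneg)
  }

  if (!is.null(tables$diet.csv)) {
    df <- tables$diet.csv
    bad <- which(df$waste_fraction < 0 | df$waste_fraction >= 1)
    for (i in bad) note("diet.csv", i, "waste_fraction outside [0, 1)")
    bad <- which(df$group != "excluded" & df$kcal_per_g <= 0)
    for (i in bad) note("diet.csv", i, "kcal_per_g must be > 0 for food items")
  }
  if (!is.null(tables$deflator.csv)) {
    bad <- which(tables$deflator.csv$index <= 0)
    for (i in bad) note("deflator.csv", i, "index must be > 0")
  }

  if (!is.null(tables$mrio_z.csv) && !is.null(tables$mrio_y.csv) &&
      !is.null(tables$mrio_x.csv)) {
    z <- tables$mrio_z.csv; y <- tables$mrio_y.csv; x <- tables$mrio_x.csv
    zo <- paste(z$origin_region, z$origin_commodity, sep = ".")
    yo <- paste(y$origin_region, y$origin_commodity, sep = ".")
    xs <- paste(x$region, x$commodity, sep = ".")
    z_row <- tapply(z$tonnes, factor(zo, levels = xs), sum, default = 0)
    y_row <- tapply(y$tonnes, factor(yo, levels = xs), sum, default = 0)
    resid <- abs(x$tonnes - z_row - y_row)
    bad <- which(resid > balance_tol * pmax(1, abs(x$tonnes)))
    for (i in bad) {
      note("mrio_x.csv", i,
           sprintf("row balance violated for sector %s (residual %g)",
                   xs[i], resid[i]))
    }
  }

  violations <- if (length(violations) > 0) {
    dplyr::bind_rows(violations)
  } else {
    tibble::tibble(table = character(), row = integer(), message = character())
  }
  list(ok = nrow(violations) == 0, violations = violations)
}
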
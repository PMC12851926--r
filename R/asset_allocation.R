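#' Allocate farm-type asset values to commodity sectors
#'
#' Distributes each farm type's asset value (per region and asset class) over
#' its eligible commodities, with weight proportional to concordance weight
#' times the region's own output of the commodity. Assets never cross
#' regions. If a farm type's eligible commodities all have zero weight (zero
#' concordance row, or zero regional output), its value is reported as
#' unallocated rather than spread evenly, mirroring the below-100% coverage
#' that real farm-survey concordances achieve.
#'
#' @param account A `farm_asset_account`.
#' @param conc A `concordance` weight matrix (farm_type x commodity).
#' @param mrio The `mrio_system` supplying regional outputs.
#' @return An `asset_extension`: list with `e` (sector x asset-class value
#'   matrix, EUR), `allocation_report` (tibble per asset class: `total_eur`,
#'   `allocated_eur`, `unallocated_eur`, `allocated_fraction`) and the
#'   system `index`.
#' @examples
#' idx <- generate_sector_index(seed = 1)
#' sys <- generate_mrio(idx, seed = 1)
#' fa <- generate_farm_accounts(idx, seed = 1)
#' ext <- allocate_assets(fa$account, fa$concordance, sys)
#' ext$allocation_report
#' @export
allocate_assets <- function(account, conc, mrio) {
  assert_that(inherits(account, "farm_asset_account"),
              "`account` must be a farm_asset_account", "schema")
  vals <- account$values
  st <- sector_table(mrio$index)
  assert_that(all(vals$region %in% st$region),
              "account regions are not all present in the MRIO system", "schema")
  assert_that(all(colnames(conc) %in% st$commodity),
              "concordance commodities are not all present in the MRIO system",
              "schema")
  assert_that(all(vals$farm_type %in% rownames(conc)),
              "account farm types missing from the concordance", "schema")

  classes <- ASSET_CLASSES
  e <- matrix(0, nrow(st), length(classes),
              dimnames = list(st$sector, classes))
  unallocated <- setNames(numeric(length(classes)), classes)

  combos <- unique(vals[, c("farm_type", "region")])
  for (i in seq_len(nrow(combos))) {
    f <- combos$farm_type[i]
    r <- combos$region[i]
    sec_rows <- which(st$region == r)
    w <- conc[f, st$commodity[sec_rows]] * mrio$x[sec_rows]
    total_w <- sum(w)
    rows <- vals$farm_type == f & vals$region == r
    v <- tapply(vals$eur[rows], vals$asset_class[rows], sum)
    for (cl in names(v)) {
      if (total_w > 0) {
        e[sec_rows, cl] <- e[sec_rows, cl] + v[[cl]] * w / total_w
      } else {
        unallocated[cl] <- unallocated[cl] + v[[cl]]
      }
    }
  }

  total <- tapply(vals$eur, factor(vals$asset_class, levels = classes), sum,
                  default = 0)
  report <- tibble::tibble(
    asset_class = classes,
    total_eur = as.numeric(total),
    allocated_eur = as.numeric(colSums(e)),
    unallocated_eur = as.numeric(unallocated)
  ) |>
    dplyr::mutate(
      allocated_fraction = ifelse(.data$total_eur > 0,
                                  .data$allocated_eur / .data$total_eur, 1)
    )

  structure(
    list(e = e, allocation_report = report, index = mrio$index),
    class = "asset_extension"
  )
}

#' @export
print.asset_extension <- function(x, ...) {
  cat("<asset_extension> allocation coverage by class:\n")
  r <- x$allocation_report
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-20s %12.1f MEUR (%.1f%% allocated)\n",
                r$asset_class[i], r$total_eur[i],
                100 * r$allocated_fraction[i]))
  }
  invisible(x)
}

#' Classify each sector's output into value-chain tags
#'
#' Livestock sectors are tagged `livestock` outright. For a crop sector the
#' `feed` share is the fraction of its output absorbed by livestock sectors
#' as intermediate use (direct sales in `Z`); the remainder is `plant_food`.
#' Shares sum to one per sector. This is the first-order (direct-sales) tag;
#' full-chain feed attribution is carried by [embodied_assets()].
#'
#' @param ext An `asset_extension` aligned to `mrio` (alignment is checked;
#'   the tag itself depends only on the flow structure).
#' @param mrio The `mrio_system`.
#' @return Tibble `(sector, region, commodity, kind, livestock_share,
#'   feed_share, plant_food_share)`.
#' @export
classify_value_chain <- function(ext, mrio) {
  st <- sector_table(mrio$index)
  assert_that(identical(rownames(ext$e), st$sector),
              "extension and MRIO system are not aligned", "schema")
  lvst_cols <- which(st$kind == "livestock_product")
  to_lvst <- if (length(lvst_cols) > 0) {
    rowSums(mrio$Z[, lvst_cols, drop = FALSE])
  } else {
    numeric(nrow(st))
  }
  feed <- as.numeric(ifelse(st$kind == "crop" & mrio$x > 0, to_lvst / mrio$x, 0))
  tibble::tibble(
    sector = st$sector, region = st$region, commodity = st$commodity,
    kind = st$kind,
    livestock_share = as.numeric(st$kind == "livestock_product"),
    feed_share = feed,
    plant_food_share = ifelse(st$kind == "crop", 1 - feed, 0)
  )
}
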
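#' Generate a sector index for a synthetic physical MRIO system
#'
#' Builds the labelling backbone of a FABIO-like multi-regional input-output
#' system: ordered region codes, commodity codes tagged as `crop` or
#' `livestock_product`, final-demand category codes, and the subset of regions
#' forming the consuming bloc (the EU-like block whose diets are shocked).
#' Sectors are ordered region-major: all commodities of region 1, then all of
#' region 2, and so on.
#'
#' @param n_regions Number of regions (>= 1).
#' @param n_crops Number of crop commodities (>= 1).
#' @param n_livestock Number of livestock-product commodities (>= 1).
#' @param n_fd Number of final-demand categories (>= 1).
#' @param eu_fraction Fraction of regions flagged as the consuming bloc
#'   (0 < eu_fraction <= 1); the first `ceiling(eu_fraction * n_regions)`
#'   regions are flagged.
#' @param seed Integer seed; the index is deterministic given its arguments
#'   and the seed.
#' @return A `sector_index` object: a list with `regions`, `commodities`
#'   (tibble with `commodity`, `kind`), `fd_categories` and `eu_members`.
#' @examples
#' idx <- generate_sector_index(3, 4, 2, 2, eu_fraction = 2 / 3, seed = 1)
#' n_sectors(idx)
#' @export
generate_sector_index <- function(n_regions = 3, n_crops = 4, n_livestock = 2,
                                  n_fd = 2, eu_fraction = 2 / 3, seed = 1L) {
  assert_that(n_regions >= 1, "`n_regions` must be >= 1")
  assert_that(n_crops >= 1, "`n_crops` must be >= 1")
  assert_that(n_livestock >= 1, "`n_livestock` must be >= 1")
  assert_that(n_fd >= 1, "`n_fd` must be >= 1")
  assert_that(eu_fraction > 0 && eu_fraction <= 1,
              "`eu_fraction` must be in (0, 1]")

  regions <- sprintf("R%02d", seq_len(n_regions))
  commodities <- tibble::tibble(
    commodity = c(sprintf("CROP%02d", seq_len(n_crops)),
                  sprintf("LVST%02d", seq_len(n_livestock))),
    kind = c(rep("crop", n_crops), rep("livestock_product", n_livestock))
  )
  fd_categories <- sprintf("FD%d", seq_len(n_fd))
  eu_members <- regions[seq_len(ceiling(eu_fraction * n_regions))]

  structure(
    list(regions = regions, commodities = commodities,
         fd_categories = fd_categories, eu_members = eu_members,
         seed = as.integer(seed)),
    class = "sector_index"
  )
}

#' Number of sectors (region x commodity pairs) in an index
#' @param index A `sector_index`.
#' @return Integer count.
#' @export
n_sectors <- function(index) {
  length(index$regions) * nrow(index$commodities)
}

#' Sector labels and metadata for an index
#'
#' @param index A `sector_index`.
#' @return A tibble with one row per sector in system order: `sector`
#'   (`"<region>.<commodity>"`), `region`, `commodity`, `kind`, and
#'   `eu_member`.
#' @export
sector_table <- function(index) {
  tibble::tibble(
    region = rep(index$regions, each = nrow(index$commodities)),
    commodity = rep(index$commodities$commodity, length(index$regions)),
    kind = rep(index$commodities$kind, length(index$regions))
  ) |>
    dplyr::mutate(
      sector = paste(.data$region, .data$commodity, sep = "."),
      eu_member = .data$region %in% index$eu_members
    ) |>
    dplyr::select("sector", "region", "commodity", "kind", "eu_member")
}

sector_ids <- function(index) sector_table(index)$sector

# Final-demand column labels, region-major: "<region>.<fd_category>".
fd_col_table <- function(index) {
  tibble::tibble(
    region = rep(index$regions, each = length(index$fd_categories)),
    fd_category = rep(index$fd_categories, length(index$regions))
  ) |>
    dplyr::mutate(col = paste(.data$region, .data$fd_category, sep = "."))
}

fd_col_ids <- function(index) fd_col_table(index)$col

#' @export
print.sector_index <- function(x, ...) {
  kinds <- table(x$commodities$kind)
  cat(sprintf(
    "<sector_index> %d regions x %d commodities (%d crop, %d livestock) x %d fd categories; %d EU member(s)\n",
    length(x$regions), nrow(x$commodities),
    kinds[["crop"]], kinds[["livestock_product"]],
    length(x$fd_categories), length(x$eu_members)
  ))
  invisible(x)
}
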
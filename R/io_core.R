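#' Technical coefficients of a physical MRIO system
#'
#' Computes \eqn{A = Z \hat{x}^{-1}}: tonnes of each input required per tonne
#' of a sector's output. Columns of zero-output sectors are set to zero.
#'
#' @param mrio An `mrio_system`.
#' @return Numeric matrix `A` (sector x sector) with sector dimnames.
#' @examples
#' idx <- generate_sector_index(seed = 1)
#' A <- technical_coefficients(generate_mrio(idx, seed = 1))
#' @export
technical_coefficients <- function(mrio) {
  if (any(mrio$Z < 0)) {
    stop_agstrand("flow matrix Z contains negative entries", "invalid_input")
  }
  inv_x <- ifelse(mrio$x > 0, 1 / mrio$x, 0)
  sweep(mrio$Z, 2, inv_x, `*`)
}

#' Leontief inverse
#'
#' Computes \eqn{L = (I - A)^{-1}}, the total (direct plus indirect) output
#' required per unit of final demand. The spectral radius of `A` is checked
#' first; a non-productive system (radius >= 1) raises a classed error rather
#' than returning a meaningless inverse. The result is verified to satisfy
#' \eqn{(I - A) L = I} within `1e-8` in maximum absolute deviation.
#'
#' @param A Technical-coefficient matrix from [technical_coefficients()].
#' @return Numeric matrix `L` with the dimnames of `A`.
#' @export
leontief_inverse <- function(A) {
  assert_that(is.matrix(A) && nrow(A) == ncol(A), "`A` must be square")
  rho <- spectral_radius(A)
  if (rho >= 1) {
    stop_agstrand(
      sprintf(paste0(
        "economy is not productive: spectral radius of A is %.6f >= 1. ",
        "Check the flow table for sectors requiring more input than they produce."
      ), rho),
      "nonproductive"
    )
  }
  I <- diag(nrow(A))
  L <- solve(I - A)
  resid <- max(abs((I - A) %*% L - I))
  if (resid > 1e-8) {
    stop_agstrand(
      sprintf("Leontief inverse failed numerical check (residual %.3g)", resid),
      "numerical"
    )
  }
  dimnames(L) <- dimnames(A)
  L
}

#' Asset intensity per sector
#'
#' \eqn{b' = e' \hat{x}^{-1}}: asset value per tonne of sector output (EUR
#' per tonne), per asset class. Sectors with zero output get zero intensity.
#'
#' @param ext An `asset_extension` from [allocate_assets()].
#' @param mrio The `mrio_system` the extension is aligned to.
#' @return Numeric matrix (sector x asset class) of intensities.
#' @export
asset_intensity <- function(ext, mrio) {
  e <- ext$e
  assert_that(identical(rownames(e), names(mrio$x)),
              "extension and MRIO system are not aligned", "schema")
  inv_x <- ifelse(mrio$x > 0, 1 / mrio$x, 0)
  e * inv_x
}

#' Embodied-asset contribution analysis
#'
#' Computes \eqn{R^c = \hat{b} L Y} per asset class: the asset value embodied
#' in the supply chain serving each final-demand column, with producing-sector
#' detail retained. Alongside the full contribution matrices, the result
#' caches a value-chain aggregation by food item: final demand for each
#' commodity is traced through the Leontief chain and the embodied value is
#' split into `livestock` (livestock-sector contributions), `feed` (crop
#' contributions upstream of an animal-sourced item) and `plant_food` (crop
#' contributions to a plant item).
#'
#' @param b Intensity matrix from [asset_intensity()] (sector x asset class).
#' @param L Leontief inverse.
#' @param Y Final-demand matrix (sector x region-category columns).
#' @param index The `sector_index` of the system.
#' @return An `embodied_result`: list with `detail` (per asset class, the
#'   sector x final-demand-column contribution matrix), `totals` (tibble
#'   `asset_class`, `value`), and `by_item` (tibble `commodity`, `kind`,
#'   `asset_class`, `chain`, `value`).
#' @export
embodied_assets <- function(b, L, Y, index) {
  assert_that(nrow(b) == nrow(L) && ncol(L) == nrow(Y),
              "`b`, `L` and `Y` have non-conformable dimensions", "schema")
  st <- sector_table(index)
  classes <- colnames(b)

  detail <- lapply(setNames(classes, classes), function(cl) b[, cl] * (L %*% Y))
  totals <- tibble::tibble(
    asset_class = classes,
    value = vapply(detail, sum, numeric(1))
  )

  # value-chain split: route each commodity's final demand through L
  items <- index$commodities$commodity
  M <- matrix(0, nrow(st), length(items),
              dimnames = list(st$sector, items))
  ytot <- rowSums(Y)
  M[cbind(seq_len(nrow(st)), match(st$commodity, items))] <- ytot
  LM <- L %*% M
  item_kind <- setNames(index$commodities$kind, items)

  by_item <- lapply(classes, function(cl) {
    contrib <- b[, cl] * LM   # producing sector x item
    chain_of <- function(prod_kind, item) {
      ifelse(prod_kind == "livestock_product", "livestock",
             ifelse(item_kind[item] == "livestock_product", "feed", "plant_food"))
    }
    out <- tibble::tibble(
      commodity = rep(items, each = nrow(st)),
      kind = item_kind[rep(items, each = nrow(st))],
      asset_class = cl,
      chain = chain_of(rep(st$kind, length(items)), rep(items, each = nrow(st))),
      value = as.numeric(contrib)
    )
    dplyr::summarise(out, value = sum(.data$value),
                     .by = c("commodity", "kind", "asset_class", "chain"))
  })
  by_item <- dplyr::bind_rows(by_item)

  structure(
    list(detail = detail, totals = totals, by_item = by_item, index = index),
    class = "embodied_result"
  )
}

#' @export
print.embodied_result <- function(x, ...) {
  cat("<embodied_result> total embodied assets by class (MEUR):\n")
  for (i in seq_len(nrow(x$totals))) {
    cat(sprintf("  %-20s %12.1f\n", x$totals$asset_class[i], x$totals$value[i]))
  }
  invisible(x)
}

#' Share of embodied fixed assets linked to animal-sourced food
#'
#' Sum of `livestock` and `feed` chain contributions over the fixed-asset
#' classes, as a fraction of all embodied fixed assets.
#'
#' @param emb An `embodied_result`.
#' @return A single fraction in `[0, 1]`.
#' @export
asf_asset_share <- function(emb) {
  fixed <- dplyr::filter(emb$by_item, .data$asset_class %in% FIXED_ASSET_CLASSES)
  sum(fixed$value[fixed$chain %in% c("livestock", "feed")]) / sum(fixed$value)
}

#' Asset intensity per unit of food produced
#'
#' Total embodied value of an item's value chain (own plus upstream
#' contributions, fixed-asset classes by default) divided by the item's
#' production mass. Items with zero production are omitted with a warning.
#'
#' @param emb An `embodied_result`.
#' @param mrio The `mrio_system` (supplies production masses, summed over
#'   regions per commodity).
#' @param classes Asset classes to include.
#' @return Tibble `(commodity, kind, embodied_eur, production_t,
#'   intensity_eur_per_t)`.
#' @export
asset_intensity_per_unit_food <- function(emb, mrio,
                                          classes = FIXED_ASSET_CLASSES) {
  st <- sector_table(mrio$index)
  prod <- tapply(mrio$x, st$commodity, sum)
  tab <- emb$by_item |>
    dplyr::filter(.data$asset_class %in% classes) |>
    dplyr::summarise(embodied_eur = sum(.data$value), .by = c("commodity", "kind")) |>
    dplyr::mutate(production_t = as.numeric(prod[.data$commodity]))
  zero <- tab$production_t <= 0
  if (any(zero)) {
    warning(sprintf("omitting %d item(s) with zero production: %s",
                    sum(zero), paste(tab$commodity[zero], collapse = ", ")))
    tab <- tab[!zero, ]
  }
  dplyr::mutate(tab, intensity_eur_per_t = .data$embodied_eur / .data$production_t)
}
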
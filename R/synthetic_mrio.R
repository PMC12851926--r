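#' Generate a balanced synthetic physical MRIO system
#'
#' Emulates the structure of a FABIO-like physical input-output table in
#' tonnes per year. Crop sectors route a fixed share of their output to
#' livestock sectors as feed and a small share to other crop sectors in the
#' same region (seed and planting material); the remainder goes to final
#' demand. Livestock output is exogenous (roughage and pasture inputs are
#' outside the table) and is delivered entirely to final demand, so livestock
#' sectors draw intermediate inputs only from crop sectors. Total output is
#' defined as \eqn{x = Z\mathbf{1} + Y\mathbf{1}}, so the row balance holds
#' bit-exactly, and the technical-coefficient matrix is productive by
#' construction (its spectral radius equals that of the crop-to-crop block,
#' bounded by `crop_use_share`).
#'
#' @param index A [generate_sector_index()] object.
#' @param feed_share Fraction of each crop sector's output routed to livestock
#'   sectors as feed (0 <= feed_share < 1).
#' @param crop_use_share Fraction of crop output used as seed/planting input
#'   by crop sectors of the same region; `feed_share + crop_use_share` must be
#'   < 1.
#' @param fd_scale Output scale in tonnes per year; sector outputs are drawn
#'   around this magnitude.
#' @param seed Integer seed; generation is deterministic given `(args, seed)`.
#' @return An `mrio_system`: list with flow matrix `Z` (sector x sector,
#'   tonnes), final demand `Y` (sector x region-category, tonnes), output
#'   vector `x`, and the `index`.
#' @examples
#' idx <- generate_sector_index(seed = 1)
#' sys <- generate_mrio(idx, feed_share = 0.4, seed = 7)
#' max(abs(sys$x - rowSums(sys$Z) - rowSums(sys$Y)))
#' @export
generate_mrio <- function(index, feed_share = 0.4, crop_use_share = 0.05,
                          fd_scale = 1000, seed = 1L) {
  assert_that(inherits(index, "sector_index"), "`index` must be a sector_index")
  assert_that(feed_share >= 0 && feed_share < 1,
              "`feed_share` must satisfy 0 <= feed_share < 1")
  assert_that(crop_use_share >= 0 && feed_share + crop_use_share < 1,
              "`feed_share + crop_use_share` must be < 1")
  assert_that(fd_scale > 0, "`fd_scale` must be > 0")

  set.seed(as.integer(seed))
  st <- sector_table(index)
  n <- nrow(st)
  sectors <- st$sector
  crop_rows <- which(st$kind == "crop")
  lvst_rows <- which(st$kind == "livestock_product")
  fd_cols <- fd_col_ids(index)
  m <- length(fd_cols)

  Z <- matrix(0, n, n, dimnames = list(sectors, sectors))
  Y <- matrix(0, n, m, dimnames = list(sectors, fd_cols))

  x0 <- numeric(n)
  x0[crop_rows] <- runif(length(crop_rows), 0.5, 1.5) * fd_scale
  x0[lvst_rows] <- runif(length(lvst_rows), 0.2, 0.6) * fd_scale

  for (i in crop_rows) {
    r <- st$region[i]
    same_region_crops <- crop_rows[st$region[crop_rows] == r]
    if (crop_use_share > 0) {
      Z[i, same_region_crops] <- crop_use_share * x0[i] *
        rand_shares(length(same_region_crops))
    }
    if (feed_share > 0) {
      Z[i, lvst_rows] <- feed_share * x0[i] * rand_shares(length(lvst_rows))
    }
    residual <- x0[i] * (1 - feed_share - crop_use_share)
    Y[i, ] <- residual * rand_shares(m)
  }
  for (i in lvst_rows) {
    Y[i, ] <- x0[i] * rand_shares(m)
  }

  x <- rowSums(Z) + rowSums(Y)
  names(x) <- sectors

  sys <- structure(list(Z = Z, Y = Y, x = x, index = index),
                   class = "mrio_system")
  rho <- spectral_radius(technical_coefficients(sys))
  if (rho >= 1 - 1e-9) {
    stop_agstrand(
      sprintf("generated system is not productive (spectral radius %.6f >= 1)", rho),
      "generation"
    )
  }
  sys
}

#' @export
print.mrio_system <- function(x, ...) {
  cat(sprintf(
    "<mrio_system> %d sectors, %d final-demand columns; total output %.4g t\n",
    length(x$x), ncol(x$Y), sum(x$x)
  ))
  invisible(x)
}
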
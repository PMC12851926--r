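# Independent truncated Neumann-series oracle for (I - A)^-1: a plain loop,
# deliberately sharing no code with leontief_inverse(). Returns the partial
# sum and an analytic tail bound max|A^(K+1)| / (1 - rho).
neumann_oracle <- function(A, K = 200L) {
  S <- diag(nrow(A))
  P <- diag(nrow(A))
  for (k in seq_len(K)) {
    P <- P %*% A
    S <- S + P
  }
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  list(S = S, tail_bound = max(abs(P %*% A)) / (1 - rho), rho = rho)
}

# Random productive coefficient matrix: nonnegative, columns rescaled to a
# column-sum norm below `norm`, which bounds the spectral radius.
random_productive_A <- function(n, norm = 0.6) {
  A <- matrix(runif(n * n), n, n)
  sweep(A, 2, colSums(A) / norm, `/`)
}

# Hand-built single-region crop -> livestock chain: crop output 100 t,
# 5 t sold as feed for 10 t of livestock output (0.5 t feed per t),
# everything else to final demand.
make_chain_system <- function(feed = 5, x_crop = 100, x_lvst = 10) {
  index <- generate_sector_index(1, 1, 1, 1, eu_fraction = 1, seed = 1)
  st <- sector_table(index)
  Z <- matrix(0, 2, 2, dimnames = list(st$sector, st$sector))
  Z[1, 2] <- feed
  Y <- matrix(c(x_crop - feed, x_lvst), 2, 1,
              dimnames = list(st$sector, fd_col_ids(index)))
  x <- setNames(c(x_crop, x_lvst), st$sector)
  structure(list(Z = Z, Y = Y, x = x, index = index), class = "mrio_system")
}

# Minimal farm account with explicit values, for allocation oracles.
make_account <- function(values, year = 2020, rate = 0.09) {
  ft <- unique(values$farm_type)
  structure(
    list(values = values, year = year,
         orientation = setNames(rep("crop", length(ft)), ft),
         depreciation_total = rate *
           sum(values$eur[values$asset_class %in%
                            c("buildings", "machinery_equipment",
                              "breeding_livestock")]),
         planted_depreciation_rate = rate),
    class = "farm_asset_account"
  )
}

make_concordance <- function(weights) {
  class(weights) <- c("concordance", class(weights))
  weights
}

# Minimal diet table with explicit items, for scenario-rule oracles.
make_diet_table <- function(items, population = NULL, kcal_target = 2500) {
  structure(
    list(items = items,
         population = population %||%
           tibble::tibble(region = "R01", population = 1e7),
         kcal_target = kcal_target),
    class = "diet_table"
  )
}

default_study <- function(seed = 1, ...) {
  idx <- generate_sector_index(seed = seed)
  sys <- generate_mrio(idx, seed = seed, ...)
  fa <- generate_farm_accounts(idx, seed = seed)
  list(index = idx, mrio = sys, account = fa$account, conc = fa$concordance)
}
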
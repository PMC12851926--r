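#' @importFrom rlang abort %||% .data
#' @importFrom stats runif setNames
#' @importFrom utils head
NULL

# Classed error helper so callers can condition on failure modes
# (e.g. "agstrand_error_nonproductive") rather than on message text.
stop_agstrand <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("agstrand_error_", class), "agstrand_error"), ...)
}

assert_that <- function(cond, message, class = "invalid_argument") {
  if (!isTRUE(cond)) stop_agstrand(message, class)
  invisible(TRUE)
}

# The four FADN-style asset classes; land is carried through the pipeline but
# always reported separately from the three fixed-asset classes.
ASSET_CLASSES <- c("buildings", "machinery_equipment", "breeding_livestock", "land")
FIXED_ASSET_CLASSES <- c("buildings", "machinery_equipment", "breeding_livestock")

#' Asset classes used throughout the pipeline
#'
#' @return Character vector of the four asset classes; the first three are the
#'   fixed-asset classes, `"land"` is analysed separately.
#' @export
asset_classes <- function() ASSET_CLASSES

# Spectral radius of a square matrix. eigen() is exact enough for the
# desk-scale systems used here; for large systems fall back to power
# iteration, which is all that is needed for a productivity check.
spectral_radius <- function(A, max_iter = 1000L, tol = 1e-12) {
  n <- nrow(A)
  if (n <= 500L) {
    return(max(Mod(eigen(A, only.values = TRUE)$values)))
  }
  v <- rep(1 / sqrt(n), n)
  lambda <- 0
  for (i in seq_len(max_iter)) {
    w <- abs(A) %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    w <- as.numeric(w) / nw
    if (abs(nw - lambda) < tol * max(1, nw)) break
    lambda <- nw
    v <- w
  }
  # power iteration on |A| upper-bounds rho(A) for nonnegative A it is exact
  lambda
}

# Draw weights summing to 1 (uniform spacings construction).
rand_shares <- function(n) {
  w <- runif(n)
  w / sum(w)
}
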
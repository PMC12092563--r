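# Internal numerical utilities shared across modules.

.quad_cache <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [-1, 1], cached per order.
gauss_legendre <- function(order) {
  key <- paste0("gl", order)
  if (is.null(.quad_cache[[key]])) {
    gl <- pracma::gaussLegendre(order, -1, 1)
    .quad_cache[[key]] <- list(nodes = gl$x, weights = gl$w)
  }
  .quad_cache[[key]]
}

# Gauss-Hermite nodes/weights (physicists' convention: weight exp(-x^2)).
gauss_hermite <- function(order) {
  key <- paste0("gh", order)
  if (is.null(.quad_cache[[key]])) {
    gh <- pracma::gaussHermite(order)
    .quad_cache[[key]] <- list(nodes = gh$x, weights = gh$w)
  }
  .quad_cache[[key]]
}

#' Package-wide quantile rule
#'
#' All quantiles in the package (inclusion criteria, drift bounds,
#' absolute-deviation intervals) use linear interpolation (type 7), the
#' default continuous rule in R.
#'
#' @param x numeric vector.
#' @param probs probabilities.
#' @return numeric vector of quantiles.
#' @export
eam_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

# Deterministic fan-out of per-dataset seeds from a master seed.  Kept
# below 2^31 - 1 so the result is always a valid integer seed.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + as.double(index) * 7919) %%
               2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
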
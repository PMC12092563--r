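#' Gelman-Rubin convergence diagnostics
#'
#' Per-parameter potential-scale-reduction factors from between- and
#' within-chain variances, plus the Brooks-Gelman multivariate version
#' based on the largest eigenvalue of `W^-1 B / n`.
#'
#' @param samples numeric array `iterations x chains x parameters` (with
#'   parameter dimnames), or a `posterior_samples` object.
#' @return list with `per_parameter` (named vector) and `multivariate`
#'   (scalar).
#' @export
compute_rhat <- function(samples) {
  x <- .as_sample_array(samples)
  n <- dim(x)[1]; m <- dim(x)[2]; k <- dim(x)[3]
  stopifnot(m >= 2, n >= 4)
  per <- vapply(seq_len(k), function(j) {
    ch <- x[, , j, drop = FALSE][, , 1]
    mu <- colMeans(ch)
    W <- mean(apply(ch, 2, stats::var))
    B <- n * stats::var(mu)
    if (W <= 0) stop("R-hat undefined: zero within-chain variance for ",
                     dimnames(x)[[3]][j], call. = FALSE)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  names(per) <- dimnames(x)[[3]]
  # multivariate: pooled within-chain covariance W and between-chain
  # covariance B/n; MPSRF from the top eigenvalue of W^-1 B / n
  Wm <- matrix(0, k, k); mu_ch <- matrix(0, m, k)
  for (c in seq_len(m)) {
    ch <- matrix(x[, c, ], n, k)
    Wm <- Wm + stats::cov(ch)
    mu_ch[c, ] <- colMeans(ch)
  }
  Wm <- Wm / m
  Bn <- stats::cov(mu_ch)    # = B / n
  lam <- tryCatch(max(Re(eigen(solve(Wm, Bn),
                               only.values = TRUE)$values)),
                  error = function(e) NA_real_)
  mpsrf <- sqrt((n - 1) / n + (m + 1) / m * lam)
  list(per_parameter = per, multivariate = mpsrf)
}

# Spectral density at frequency zero via an AR fit (Yule-Walker, AIC
# order selection) -- the classic time-series ESS estimator.
.spectrum0 <- function(y) {
  v <- stats::var(y)
  if (v == 0) return(0)
  fit <- tryCatch(stats::ar(y, aic = TRUE,
                            order.max = min(length(y) - 1, 40),
                            method = "yule-walker"),
                  error = function(e) NULL)
  if (is.null(fit)) return(v)
  if (fit$order == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Effective sample size
#'
#' Per-parameter effective sample size of the pooled chains, computed per
#' chain as `n * var / spectrum0` (spectral density of the chain at
#' frequency zero, AR-fit estimator) and summed over chains.
#'
#' @inheritParams compute_rhat
#' @return named numeric vector of ESS per parameter.
#' @export
compute_ess <- function(samples) {
  x <- .as_sample_array(samples)
  n <- dim(x)[1]; m <- dim(x)[2]; k <- dim(x)[3]
  ess <- vapply(seq_len(k), function(j) {
    sum(vapply(seq_len(m), function(c) {
      y <- x[, c, j]
      s0 <- .spectrum0(y)
      if (s0 <= 0) 0 else n * stats::var(y) / s0
    }, numeric(1)))
  }, numeric(1))
  names(ess) <- dimnames(x)[[3]]
  ess
}

.as_sample_array <- function(samples) {
  if (inherits(samples, "posterior_samples")) samples <- samples$draws
  stopifnot(is.array(samples), length(dim(samples)) == 3)
  samples
}
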
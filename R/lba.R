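#' Linear ballistic accumulator parameters
#'
#' Parameter set for the two-accumulator LBA in the `B = b - A`
#' parameterization.  The rate SD of the mismatching accumulator is fixed
#' at `s_v_false = 1`, the conventional scaling constraint; construction
#' rejects other values.  Start-point range `A` and threshold gap `B` are
#' shared across accumulators.
#'
#' @param A start-point uniform range (>= 0); starts drawn from `U(0, A)`.
#' @param B threshold gap above the start-point range; threshold
#'   `b = A + B` (> A requires B > 0).
#' @param v_true mean accumulation rate of the matching (correct)
#'   accumulator.
#' @param v_false mean rate of the mismatching accumulator.
#' @param s_v_true rate SD of the matching accumulator (> 0).
#' @param t0 non-decision time in seconds (>= 0).
#' @param s_v_false rate SD of the mismatching accumulator; must be 1.
#' @return an object of class `lba_params`.
#' @examples
#' p <- lba_params(A = 0.5, B = 0.8, v_true = 2.5, v_false = 1,
#'                 s_v_true = 1.2, t0 = 0.25)
#' lba_error_rate(p)
#' @export
lba_params <- function(A, B, v_true, v_false, s_v_true, t0,
                       s_v_false = 1) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(v_true),
            is.numeric(v_false), is.numeric(s_v_true), is.numeric(t0))
  if (s_v_false != 1)
    stop("the mismatching rate SD is fixed at s_v_false = 1", call. = FALSE)
  if (A < 0) stop("'A' must be non-negative", call. = FALSE)
  if (B <= 0) stop("'B' must be positive (threshold b = A + B > A)",
                   call. = FALSE)
  if (s_v_true <= 0) stop("'s_v_true' must be positive", call. = FALSE)
  if (t0 < 0) stop("'t0' must be non-negative", call. = FALSE)
  structure(list(A = A, B = B, b = A + B, v_true = v_true,
                 v_false = v_false, s_v_true = s_v_true, s_v_false = 1,
                 t0 = t0),
            class = "lba_params")
}

#' @export
print.lba_params <- function(x, ...) {
  cat("LBA parameters (s_v_false = 1, b = A + B):\n")
  print(unlist(x[c("A", "B", "v_true", "v_false", "s_v_true", "t0")]))
  invisible(x)
}

# Single-accumulator first-passage density/CDF of decision time t (> 0)
# for threshold b, start U(0, A), rate N(v, s).  Closed-form guards:
# A below 1e-10 collapses the start distribution to a point; s below 1e-6
# uses the deterministic-rate limit.
.lba_acc_pdf <- function(t, b, A, v, s) {
  out <- numeric(length(t))
  pos <- t > 0
  t <- t[pos]
  if (s < 1e-6) {            # deterministic rate: uniform finishing time
    f <- if (v <= 0) {
      rep(0, length(t))
    } else if (A < 1e-10) {
      rep(0, length(t))      # point mass at b/v; density zero elsewhere
    } else {
      ifelse(t >= (b - A) / v & t <= b / v, v / A, 0)
    }
  } else if (A < 1e-10) {    # point start: T = b/d, d ~ N(v, s) (d > 0)
    f <- b / (s * t^2) * stats::dnorm((b / t - v) / s)
  } else {
    zs <- (b - A - t * v) / (t * s)
    zb <- (b - t * v) / (t * s)
    f <- (-v * stats::pnorm(zs) + s * stats::dnorm(zs) +
            v * stats::pnorm(zb) - s * stats::dnorm(zb)) / A
  }
  out[pos] <- pmax(f, 0)
  out
}

.lba_acc_cdf <- function(t, b, A, v, s) {
  out <- numeric(length(t))
  pos <- t > 0
  t <- t[pos]
  if (s < 1e-6) {
    F <- if (v <= 0) {
      rep(0, length(t))
    } else if (A < 1e-10) {
      as.numeric(t >= b / v)
    } else {
      pmin(pmax((A - (b - t * v)) / A, 0), 1)
    }
  } else if (A < 1e-10) {
    F <- stats::pnorm((v - b / t) / s)
  } else {
    zs <- (b - A - t * v) / (t * s)
    zb <- (b - t * v) / (t * s)
    F <- 1 + ((b - A - t * v) / A) * stats::pnorm(zs) -
      ((b - t * v) / A) * stats::pnorm(zb) +
      (t * s / A) * (stats::dnorm(zs) - stats::dnorm(zb))
  }
  out[pos] <- pmin(pmax(F, 0), 1)
  out
}

# Probability that both accumulators draw non-positive rates (no response).
.lba_p_no_response <- function(params) {
  stats::pnorm(-params$v_true / params$s_v_true) *
    stats::pnorm(-params$v_false / params$s_v_false)
}

#' Defective response-time density of the LBA
#'
#' Density that the given accumulator wins at observed time `rt`:
#' `f_i(rt - t0) * (1 - F_j(rt - t0))` with `f`, `F` the
#' single-accumulator first-passage density/CDF under a uniform start
#' point and normally distributed rate.  Zero for `rt <= t0`.
#'
#' Under the default truncated convention, trials on which both
#' accumulators draw non-positive rates (and hence never finish) are
#' excluded by renormalizing with `1 - P(both rates <= 0)`, so the two
#' defective densities integrate to 1; the simulator matches this by
#' redrawing such trials.  `convention = "none"` leaves the raw
#' (unnormalized) defective density, for cross-checks.
#'
#' @param params an [lba_params()] object.
#' @param rt numeric vector of response times (seconds).
#' @param accumulator `"matching"` (correct response) or `"mismatching"`.
#' @param convention `"truncated"` (default) or `"none"`.
#' @return numeric vector of densities (1/s).
#' @export
lba_defective_density <- function(params, rt,
                                  accumulator = c("matching", "mismatching"),
                                  convention = c("truncated", "none")) {
  stopifnot(inherits(params, "lba_params"), is.numeric(rt))
  accumulator <- match.arg(accumulator)
  convention <- match.arg(convention)
  t <- rt - params$t0
  if (accumulator == "matching") {
    f <- .lba_acc_pdf(t, params$b, params$A, params$v_true, params$s_v_true) *
      (1 - .lba_acc_cdf(t, params$b, params$A, params$v_false,
                        params$s_v_false))
  } else {
    f <- .lba_acc_pdf(t, params$b, params$A, params$v_false,
                      params$s_v_false) *
      (1 - .lba_acc_cdf(t, params$b, params$A, params$v_true,
                        params$s_v_true))
  }
  if (convention == "truncated") f <- f / (1 - .lba_p_no_response(params))
  # 0 * Inf underflow (decision times within machine precision of zero)
  f[!is.finite(f)] <- 0
  f
}

#' Predicted error rate of an LBA parameter set
#'
#' Probability that the mismatching accumulator wins, by quadrature over
#' its defective density (truncated convention).
#'
#' @param params an [lba_params()] object.
#' @return scalar probability.
#' @export
lba_error_rate <- function(params) {
  stopifnot(inherits(params, "lba_params"))
  stats::integrate(function(t) lba_defective_density(params, t + params$t0,
                                                     "mismatching"),
                   lower = 0, upper = Inf, rel.tol = 1e-8,
                   stop.on.error = FALSE)$value
}

#' Simulate trials from the LBA
#'
#' Per trial and accumulator, a start point `k ~ U(0, A)` and rate
#' `d ~ N(mean, SD)` are drawn; the finishing time is `(b - k)/d` for
#' `d > 0` (infinite otherwise) and the faster accumulator determines the
#' response; `rt` = winning time + `t0`.  Trials on which both rates are
#' non-positive are redrawn, matching the truncated density convention.
#' Seeded runs are bit-reproducible.
#'
#' @param params an [lba_params()] object.
#' @param n number of trials (>= 1).
#' @param seed optional integer seed.
#' @param condition condition label attached to all trials.
#' @return a `choice_rt_dataset`.
#' @export
lba_simulate <- function(params, n, seed = NULL, condition = "stimulus") {
  stopifnot(inherits(params, "lba_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  rt <- numeric(n); correct <- logical(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    d1 <- stats::rnorm(m, params$v_true, params$s_v_true)
    d2 <- stats::rnorm(m, params$v_false, params$s_v_false)
    k1 <- stats::runif(m, 0, params$A)
    k2 <- stats::runif(m, 0, params$A)
    t1 <- ifelse(d1 > 0, (params$b - k1) / d1, Inf)
    t2 <- ifelse(d2 > 0, (params$b - k2) / d2, Inf)
    ok <- is.finite(pmin(t1, t2))
    idx <- need[ok]
    rt[idx] <- pmin(t1, t2)[ok] + params$t0
    correct[idx] <- (t1 < t2)[ok]
    need <- need[!ok]
  }
  choice_rt_dataset(
    condition = rep(condition, n),
    response = ifelse(correct, "correct", "error"),
    rt = rt,
    model = "lba", params = list(params), seed = seed
  )
}

#' Log-likelihood of an LBA parameter set
#'
#' Sum over trials of the log defective density of the responding
#' accumulator (correct responses map to the matching accumulator).  A
#' named list of parameter sets maps conditions to their own parameters
#' (e.g. separate rates per difficulty, separate `B` per instruction).
#' Returns `-Inf` when any trial has zero density.
#'
#' @param params an [lba_params()] object or named list keyed by condition.
#' @param data a `choice_rt_dataset`.
#' @return scalar log-likelihood.
#' @export
lba_log_likelihood <- function(params, data) {
  by_cond <- .params_by_condition(params, data, "lba_params")
  ll <- 0
  for (cond in names(by_cond)) {
    p <- by_cond[[cond]]
    idx <- data$condition == cond
    if (!any(idx)) next
    corr <- idx & data$response == "correct"
    errs <- idx & data$response == "error"
    f <- c(lba_defective_density(p, data$rt[corr], "matching"),
           lba_defective_density(p, data$rt[errs], "mismatching"))
    if (any(f <= 0)) return(-Inf)
    ll <- ll + sum(log(f))
  }
  ll
}
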
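#' Diffusion decision model parameters
#'
#' Constructs a validated parameter set for the diffusion decision model
#' (DDM) with across-trial variability in drift rate and starting point.
#' The diffusion coefficient is fixed at `s = 1` and non-decision-time
#' variability at `s_t0 = 0`, the conventional scaling for this model;
#' construction rejects other values.
#'
#' Start point `z` and its uniform range `s_z` are stored in absolute
#' evidence units; the relative view `z/a` is available via
#' [ddm_relative_start()].
#'
#' @param a boundary separation (> 0).
#' @param v mean drift rate (evidence/s); positive drift favours the upper
#'   (correct) boundary.
#' @param z mean starting point, `0 < z < a`; defaults to `a/2`.
#' @param s_v across-trial drift-rate SD (>= 0).
#' @param s_z across-trial starting-point uniform range (>= 0); the
#'   start-point support `(z - s_z/2, z + s_z/2)` must lie strictly inside
#'   `(0, a)`.
#' @param t0 non-decision time in seconds (>= 0).
#' @param s diffusion coefficient; must be 1.
#' @param s_t0 non-decision-time range; must be 0.
#' @return an object of class `ddm_params`.
#' @examples
#' p <- ddm_params(a = 1.5, v = 2, s_v = 1, s_z = 0.2, t0 = 0.3)
#' ddm_error_rate(p)
#' @export
ddm_params <- function(a, v, z = a / 2, s_v = 0, s_z = 0, t0 = 0.3,
                       s = 1, s_t0 = 0) {
  stopifnot(is.numeric(a), is.numeric(v), is.numeric(z), is.numeric(s_v),
            is.numeric(s_z), is.numeric(t0))
  if (s != 1) stop("the diffusion coefficient is fixed at s = 1", call. = FALSE)
  if (s_t0 != 0) stop("non-decision-time variability is fixed at s_t0 = 0",
                      call. = FALSE)
  if (!is.finite(a) || a <= 0) stop("'a' must be positive", call. = FALSE)
  if (s_v < 0) stop("'s_v' must be non-negative", call. = FALSE)
  if (s_z < 0) stop("'s_z' must be non-negative", call. = FALSE)
  if (t0 < 0) stop("'t0' must be non-negative", call. = FALSE)
  if (z - s_z / 2 <= 0 || z + s_z / 2 >= a)
    stop("start-point support (z - s_z/2, z + s_z/2) must lie inside (0, a)",
         call. = FALSE)
  structure(list(a = a, v = v, z = z, s_v = s_v, s_z = s_z, t0 = t0,
                 s = 1, s_t0 = 0),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("DDM parameters (s = 1, s_t0 = 0):\n")
  print(unlist(x[c("a", "v", "z", "s_v", "s_z", "t0")]))
  invisible(x)
}

#' Relative start point of a DDM parameter set
#'
#' Reporting view of the start point as a fraction of boundary separation:
#' `z/a` and relative range `s_z/a`.
#'
#' @param params a [ddm_params()] object.
#' @return named numeric vector with elements `z_rel` and `s_z_rel`.
#' @export
ddm_relative_start <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  c(z_rel = params$z / params$a, s_z_rel = params$s_z / params$a)
}

#' First-passage-time density of the DDM
#'
#' Defective density of absorption at the given boundary at observed time
#' `rt` (seconds), integrating over across-trial drift variability
#' (analytically) and start-point variability (Gauss-Legendre quadrature).
#' Zero for `rt <= t0`.  The underlying Wiener density uses small-time and
#' large-time series representations with an automatic switch chosen so
#' the truncation error is below `eps` on the unit scale.
#'
#' @param params a [ddm_params()] object.
#' @param rt numeric vector of response times in seconds.
#' @param boundary `"upper"` (correct) or `"lower"` (error).
#' @param sz_order Gauss-Legendre order for start-point integration.
#' @param eps series truncation tolerance.
#' @return numeric vector of densities (1/s).
#' @export
ddm_fpt_density <- function(params, rt, boundary = c("upper", "lower"),
                            sz_order = 16, eps = 1e-10) {
  stopifnot(inherits(params, "ddm_params"), is.numeric(rt))
  boundary <- match.arg(boundary)
  gl <- gauss_legendre(sz_order)
  .ddm_density_cpp(rt, params$a, params$v, params$z, params$s_v, params$s_z,
                   params$t0, boundary == "upper", gl$nodes, gl$weights, eps)
}

# Absorption probability at the lower boundary for a constant-drift Wiener
# process (s = 1) started at z in (0, a).  Stable for large |v * a|.
.wiener_p_lower <- function(v, a, z) {
  out <- numeric(length(v))
  small <- abs(v) < 1e-10
  out[small] <- 1 - z / a
  vv <- v[!small]
  # P(upper) = (1 - exp(-2 v z)) / (1 - exp(-2 v a))
  out[!small] <- 1 - expm1(-2 * vv * z) / expm1(-2 * vv * a)
  pmin(pmax(out, 0), 1)
}

#' Predicted error rate of a DDM parameter set
#'
#' Probability of absorbing at the lower (error) boundary, integrating the
#' closed-form constant-drift absorption probability over the normal drift
#' distribution (Gauss-Hermite) and the uniform start-point distribution
#' (Gauss-Legendre).
#'
#' @param params a [ddm_params()] object.
#' @param gh_order Gauss-Hermite order for drift integration.
#' @param gl_order Gauss-Legendre order for start-point integration.
#' @return scalar probability.
#' @export
ddm_error_rate <- function(params, gh_order = 48, gl_order = 16) {
  stopifnot(inherits(params, "ddm_params"))
  a <- params$a
  zs <- params$z
  ws <- 1
  if (params$s_z > 0) {
    gl <- gauss_legendre(gl_order)
    zs <- params$z + params$s_z / 2 * gl$nodes
    ws <- gl$weights / 2
  }
  p_for_z <- function(z) {
    if (params$s_v > 0) {
      gh <- gauss_hermite(gh_order)
      vs <- params$v + sqrt(2) * params$s_v * gh$nodes
      sum(gh$weights * .wiener_p_lower(vs, a, z)) / sqrt(pi)
    } else {
      .wiener_p_lower(params$v, a, z)
    }
  }
  sum(ws * vapply(zs, p_for_z, numeric(1)))
}

#' Simulate trials from the DDM
#'
#' Euler-Maruyama simulation of the diffusion path (default step 1e-4 s,
#' absorption cap 30 s).  Per trial, drift is drawn from
#' `Normal(v, s_v^2)` and the start point from
#' `Uniform(z - s_z/2, z + s_z/2)`.  The upper boundary is mapped to the
#' correct response.  Seeded runs are bit-reproducible.
#'
#' @param params a [ddm_params()] object.
#' @param n number of trials (>= 1).
#' @param seed optional integer seed.
#' @param dt Euler step size in seconds.
#' @param tmax absorption time cap in seconds; paths still unabsorbed at
#'   `tmax` raise an error.
#' @param condition condition label attached to all trials.
#' @return a `choice_rt_dataset` data frame with columns `condition`,
#'   `response` (`"correct"`/`"error"`) and `rt` (seconds).
#' @export
ddm_simulate <- function(params, n, seed = NULL, dt = 1e-4, tmax = 30,
                         condition = "stimulus") {
  stopifnot(inherits(params, "ddm_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sim <- .ddm_simulate_cpp(as.integer(n), params$a, params$v, params$z,
                           params$s_v, params$s_z, params$t0, dt, tmax)
  if (anyNA(sim$boundary))
    stop(sum(is.na(sim$boundary)),
         " simulated path(s) not absorbed within tmax = ", tmax, " s",
         call. = FALSE)
  choice_rt_dataset(
    condition = rep(condition, n),
    response = ifelse(sim$boundary == 1L, "correct", "error"),
    rt = sim$rt,
    model = "ddm", params = list(params), seed = seed
  )
}

#' Log-likelihood of a DDM parameter set
#'
#' Sum over trials of the log defective first-passage density at the
#' trial's boundary (correct responses map to the upper boundary).  With a
#' named list of parameter sets, each condition in the data uses its own
#' parameters; a condition without an entry is a configuration error.
#' Returns `-Inf` when any trial has zero density (e.g. `rt <= t0`).
#'
#' @param params a [ddm_params()] object, or a named list of them keyed by
#'   condition label.
#' @param data a `choice_rt_dataset` (or data frame with columns
#'   `condition`, `response`, `rt`).
#' @param sz_order,eps see [ddm_fpt_density()].
#' @return scalar log-likelihood.
#' @export
ddm_log_likelihood <- function(params, data, sz_order = 16, eps = 1e-10) {
  by_cond <- .params_by_condition(params, data, "ddm_params")
  gl <- gauss_legendre(sz_order)
  ll <- 0
  for (cond in names(by_cond)) {
    p <- by_cond[[cond]]
    idx <- data$condition == cond
    ll <- ll + .ddm_loglik_cpp(data$rt[idx], data$response[idx] == "correct",
                               p$a, p$v, p$z, p$s_v, p$s_z, p$t0,
                               gl$nodes, gl$weights, eps)
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

# Resolve single-or-per-condition parameters against the data.
.params_by_condition <- function(params, data, cls) {
  stopifnot(is.data.frame(data),
            all(c("condition", "response", "rt") %in% names(data)))
  conds <- unique(data$condition)
  if (inherits(params, cls)) {
    stats::setNames(rep(list(params), length(conds)), conds)
  } else {
    stopifnot(is.list(params))
    missing <- setdiff(conds, names(params))
    if (length(missing))
      stop("no parameters supplied for condition(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    lapply(params, function(p) {
      if (!inherits(p, cls)) stop("all parameter entries must be ", cls,
                                  call. = FALSE)
      p
    })[conds]
  }
}
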
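#' Truncated multivariate normal specification
#'
#' Describes the distribution from which data-generating parameter vectors
#' are sampled: a multivariate normal on a transformed scale (per-parameter
#' monotone transforms), truncated by per-parameter bounds on the natural
#' scale.  Draws violating bounds (or ordering constraints, see
#' [constraint_set()]) are rejected.
#'
#' @param names ordered character vector of parameter names.
#' @param transforms named character vector, one of `"identity"`, `"log"`,
#'   `"logit"` per parameter (the transform mapping natural to normal
#'   scale).
#' @param means,sds named numeric vectors on the transformed scale
#'   (`sds > 0`).
#' @param corr symmetric positive-definite correlation matrix with unit
#'   diagonal, dimnames matching `names`.
#' @param lower,upper named numeric vectors of truncation bounds on the
#'   natural scale (may be infinite).
#' @return an object of class `tmvn_spec`.
#' @export
tmvn_spec <- function(names, transforms, means, sds, corr, lower, upper) {
  k <- length(names)
  transforms <- transforms[names]; means <- means[names]; sds <- sds[names]
  lower <- lower[names]; upper <- upper[names]
  stopifnot(all(transforms %in% c("identity", "log", "logit")),
            all(is.finite(means)), all(sds > 0),
            is.matrix(corr), nrow(corr) == k, ncol(corr) == k,
            all(lower < upper))
  if (!isTRUE(all.equal(corr, t(corr))))
    stop("correlation matrix must be symmetric", call. = FALSE)
  if (!isTRUE(all.equal(unname(diag(corr)), rep(1, k))))
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("correlation matrix must be positive definite", call. = FALSE)
  dimnames(corr) <- list(names, names)
  structure(list(names = names, transforms = transforms, means = means,
                 sds = sds, corr = corr, lower = lower, upper = upper),
            class = "tmvn_spec")
}

#' Ordering constraints on sampled parameter vectors
#'
#' @param ordering list of length-2 character vectors `c(a, b)` meaning
#'   the constraint `a > b` on the natural scale.  The slow-error regimes
#'   use `s_v > s_z` (DDM) and `s_v_true > s_v_false` (LBA).
#' @param slow_error flag recording that the constraint set encodes the
#'   slow-error regime.
#' @return an object of class `constraint_set`.
#' @export
constraint_set <- function(ordering = list(), slow_error = FALSE) {
  stopifnot(is.list(ordering),
            all(vapply(ordering, length, 1L) == 2L))
  structure(list(ordering = ordering, slow_error = slow_error),
            class = "constraint_set")
}

.transform_fun <- function(kind) {
  switch(kind,
         identity = list(to = identity, from = identity),
         log = list(to = log, from = exp),
         logit = list(to = function(p) log(p / (1 - p)),
                      from = stats::plogis))
}

.to_transformed <- function(spec, x) {
  vapply(spec$names, function(nm)
    .transform_fun(spec$transforms[[nm]])$to(x[[nm]]), numeric(1))
}

.from_transformed <- function(spec, y) {
  out <- vapply(seq_along(spec$names), function(i)
    .transform_fun(spec$transforms[[i]])$from(y[, i]),
    numeric(nrow(y)))
  out <- matrix(out, nrow = nrow(y))
  colnames(out) <- spec$names
  out
}

# Evaluate bounds + ordering constraints on a natural-scale matrix;
# returns a logical matrix of per-criterion passes (columns) used both for
# filtering and for naming the binding constraint on failure.
.constraint_checks <- function(spec, x, constraints) {
  checks <- list()
  for (nm in spec$names) {
    checks[[paste0("lower:", nm)]] <- x[, nm] >= spec$lower[[nm]]
    checks[[paste0("upper:", nm)]] <- x[, nm] <= spec$upper[[nm]]
  }
  if (!is.null(constraints)) {
    for (cn in constraints$ordering) {
      if (!cn[1] %in% spec$names)
        stop("constraint references unknown parameter: ", cn[1],
             call. = FALSE)
      # right-hand side may be a parameter name or a numeric constant
      # (used when the comparison parameter is a fixed scaling constant)
      rhs <- if (cn[2] %in% spec$names) x[, cn[2]] else {
        val <- suppressWarnings(as.numeric(cn[2]))
        if (is.na(val))
          stop("constraint references unknown parameter: ", cn[2],
               call. = FALSE)
        val
      }
      checks[[paste0(cn[1], ">", cn[2])]] <- x[, cn[1]] > rhs
    }
  }
  do.call(cbind, checks)
}

# Shared rejection loop: `propose(m)` returns an m x k transformed-scale
# matrix.  Errors out (naming the most-binding criterion) if acceptance
# falls below `min_accept` after a probe of proposals.
.rejection_sample <- function(spec, constraints, n, propose,
                              min_accept = 1e-4, probe = 20000) {
  accepted <- NULL
  proposed <- 0L
  fail_counts <- NULL
  while (is.null(accepted) || nrow(accepted) < n) {
    m <- max(1000L, 2L * (n - if (is.null(accepted)) 0L else nrow(accepted)))
    y <- propose(m)
    x <- .from_transformed(spec, y)
    chk <- .constraint_checks(spec, x, constraints)
    ok <- rowSums(!chk) == 0L
    fails <- colSums(!chk)
    fail_counts <- if (is.null(fail_counts)) fails else fail_counts + fails
    proposed <- proposed + m
    accepted <- rbind(accepted, x[ok, , drop = FALSE])
    if (proposed >= probe && nrow(accepted) / proposed < min_accept) {
      worst <- names(which.max(fail_counts))
      stop("truncated-MVN sampling infeasible: acceptance rate ",
           signif(nrow(accepted) / proposed, 3),
           " below ", min_accept, "; most binding criterion: ", worst,
           call. = FALSE)
    }
  }
  out <- as.data.frame(accepted[seq_len(n), , drop = FALSE])
  names(out) <- spec$names
  attr(out, "acceptance_rate") <- nrow(accepted) / proposed
  out
}

#' Sample data-generating parameter vectors
#'
#' Draws from the truncated multivariate normal on the transformed scale,
#' inverse-transforms to the natural scale, and rejects draws violating
#' the truncation bounds or ordering constraints.
#'
#' @param spec a [tmvn_spec()].
#' @param constraints a [constraint_set()] or `NULL`.
#' @param n number of accepted draws.
#' @param seed optional integer seed.
#' @return data frame of `n` natural-scale parameter vectors (columns in
#'   spec order), with the realized acceptance rate as an attribute.
#' @export
sample_params <- function(spec, constraints = NULL, n, seed = NULL) {
  stopifnot(inherits(spec, "tmvn_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sigma <- diag(spec$sds) %*% spec$corr %*% diag(spec$sds)
  .rejection_sample(spec, constraints, n, function(m)
    MASS::mvrnorm(m, mu = spec$means, Sigma = sigma))
}

#' Sample conditionally on fixed parameter values
#'
#' Gaussian conditioning on the transformed scale: the free parameters are
#' drawn from the conditional multivariate normal given the fixed values,
#' then truncation bounds and ordering constraints are enforced by
#' rejection (evaluated on the full vector, fixed values included).
#' Conditioning on nothing reduces to [sample_params()].
#'
#' @param spec a [tmvn_spec()].
#' @param fixed named numeric vector of natural-scale values for a subset
#'   of the spec's parameters.
#' @param constraints a [constraint_set()] or `NULL`.
#' @param n number of accepted draws.
#' @param seed optional integer seed.
#' @return data frame of `n` full natural-scale parameter vectors.
#' @export
conditional_sample <- function(spec, fixed, constraints = NULL, n,
                               seed = NULL) {
  stopifnot(inherits(spec, "tmvn_spec"))
  if (length(fixed) == 0) return(sample_params(spec, constraints, n, seed))
  stopifnot(all(names(fixed) %in% spec$names))
  if (!is.null(seed)) set.seed(seed)
  fx <- names(fixed)
  fr <- setdiff(spec$names, fx)
  sigma <- diag(spec$sds) %*% spec$corr %*% diag(spec$sds)
  dimnames(sigma) <- list(spec$names, spec$names)
  yfix <- vapply(fx, function(nm)
    .transform_fun(spec$transforms[[nm]])$to(fixed[[nm]]), numeric(1))
  s_cc_inv <- solve(sigma[fx, fx, drop = FALSE])
  mu_cond <- spec$means[fr] +
    drop(sigma[fr, fx, drop = FALSE] %*% s_cc_inv %*%
           (yfix - spec$means[fx]))
  sig_cond <- sigma[fr, fr, drop = FALSE] -
    sigma[fr, fx, drop = FALSE] %*% s_cc_inv %*% sigma[fx, fr, drop = FALSE]
  propose <- function(m) {
    yf <- MASS::mvrnorm(m, mu = mu_cond, Sigma = sig_cond)
    yf <- matrix(yf, nrow = m, dimnames = list(NULL, fr))
    y <- matrix(NA_real_, m, length(spec$names),
                dimnames = list(NULL, spec$names))
    y[, fr] <- yf
    y[, fx] <- matrix(yfix, m, length(fx), byrow = TRUE)
    y
  }
  .rejection_sample(spec, constraints, n, propose)
}

#' Drift-rate bounds from Study-1 quantiles
#'
#' For the difficulty and speed-accuracy designs, new drift rates are
#' drawn uniformly between the 25th and 75th quantiles of the
#' data-generating drift rates observed at the matching Study-1 error
#' rate.  Quantiles use the package-wide linear-interpolation rule
#' ([eam_quantile()]).
#'
#' @param drifts_by_rate named list mapping Study-1 target error rates
#'   (as formatted by `format()`, e.g. `"0.05"`) to numeric vectors of
#'   data-generating drift values.
#' @param target_error_rate the error rate to match.
#' @return numeric `c(lower, upper)` drift bounds.
#' @export
drift_bounds_from_quantiles <- function(drifts_by_rate, target_error_rate) {
  key <- format(target_error_rate)
  if (!key %in% names(drifts_by_rate))
    stop("no Study-1 drift rates recorded for target error rate ",
         key, call. = FALSE)
  d <- drifts_by_rate[[key]]
  if (!length(d)) stop("empty drift-rate set for error rate ", key,
                       call. = FALSE)
  q <- eam_quantile(d, c(0.25, 0.75))
  c(lower = q[1], upper = q[2])
}

#' Sample a speed-condition threshold
#'
#' One conditional draw of the decision threshold (DDM `a`, LBA `B`) given
#' all other parameters of the accuracy condition, with ordinal
#' consistency (speed threshold below the accuracy threshold) enforced by
#' rejection.
#'
#' @param spec a [tmvn_spec()].
#' @param accuracy_params named numeric vector: the full natural-scale
#'   accuracy-condition parameter vector (spec names).
#' @param threshold_name name of the threshold parameter in the spec.
#' @param seed optional integer seed.
#' @param max_draws rejection cap.
#' @return scalar speed-condition threshold.
#' @export
sample_speed_threshold <- function(spec, accuracy_params, threshold_name,
                                   seed = NULL, max_draws = 10000) {
  stopifnot(inherits(spec, "tmvn_spec"),
            threshold_name %in% spec$names,
            all(spec$names %in% names(accuracy_params)))
  if (!is.null(seed)) set.seed(seed)
  fixed <- accuracy_params[setdiff(spec$names, threshold_name)]
  acc_thr <- accuracy_params[[threshold_name]]
  drawn <- 0L
  while (drawn < max_draws) {
    batch <- conditional_sample(spec, fixed, constraints = NULL,
                                n = 32, seed = NULL)
    drawn <- drawn + 32L
    cand <- batch[[threshold_name]]
    hit <- cand[cand < acc_thr]
    if (length(hit)) return(hit[1])
  }
  stop("could not draw a speed threshold below the accuracy threshold (",
       signif(acc_thr, 4), ") in ", max_draws, " draws", call. = FALSE)
}

#' Empirically calibrated sampling distributions
#'
#' Default truncated multivariate normal specifications for the DDM and
#' LBA data-generating parameter distributions.  The correlation matrices
#' are the empirically calibrated between-subject correlations (estimated
#' from maximum-likelihood fits to 17 published 2AFC experiments) and are
#' shipped verbatim; marginal means, SDs and truncation bounds are package
#' defaults chosen to reproduce parameter ranges typical of the empirical
#' DDM/LBA literature, and are fully editable via the arguments.
#'
#' The DDM spec samples the start point and its range on the relative
#' scale (`z_rel = z/a`, logit transform; `s_z_rel = s_z/a`, log
#' transform); [ddm_params_from_draw()] converts a sampled row to absolute
#' units.  Strictly positive parameters use a log transform, unbounded
#' rate means an identity transform.
#'
#' @param means,sds,lower,upper optional named overrides (transformed
#'   scale for `means`/`sds`, natural scale for bounds).
#' @return a [tmvn_spec()].
#' @export
ddm_calibration_spec <- function(means = NULL, sds = NULL, lower = NULL,
                                 upper = NULL) {
  nm <- c("a", "v", "s_v", "z_rel", "s_z_rel", "t0")
  corr <- diag(6)
  dimnames(corr) <- list(nm, nm)
  corr["v", "a"] <- 0.09
  corr["s_v", "a"] <- 0.49; corr["s_v", "v"] <- 0.67
  corr["z_rel", "a"] <- 0.01; corr["z_rel", "v"] <- 0.01
  corr["z_rel", "s_v"] <- 0.01
  corr["s_z_rel", "a"] <- 0.01; corr["s_z_rel", "v"] <- 0.41
  corr["s_z_rel", "s_v"] <- 0.44; corr["s_z_rel", "z_rel"] <- 0.00
  corr["t0", "a"] <- 0.23; corr["t0", "v"] <- -0.03
  corr["t0", "s_v"] <- -0.05; corr["t0", "z_rel"] <- 0.00
  corr["t0", "s_z_rel"] <- -0.15
  corr[upper.tri(corr)] <- t(corr)[upper.tri(corr)]
  def_means <- c(a = log(1.25), v = 2.2, s_v = log(0.9),
                 z_rel = 0, s_z_rel = log(0.18), t0 = log(0.32))
  def_sds <- c(a = 0.35, v = 1.3, s_v = 0.45, z_rel = 0.25,
               s_z_rel = 0.55, t0 = 0.35)
  def_lower <- c(a = 0.4, v = 0.02, s_v = 0.05, z_rel = 0.25,
                 s_z_rel = 0.01, t0 = 0.1)
  def_upper <- c(a = 4.5, v = 7, s_v = 3, z_rel = 0.75,
                 s_z_rel = 0.85, t0 = 0.8)
  .override <- function(def, ov) { if (!is.null(ov)) def[names(ov)] <- ov; def }
  tmvn_spec(nm,
            transforms = c(a = "log", v = "identity", s_v = "log",
                           z_rel = "logit", s_z_rel = "log", t0 = "log"),
            means = .override(def_means, means),
            sds = .override(def_sds, sds),
            corr = corr,
            lower = .override(def_lower, lower),
            upper = .override(def_upper, upper))
}

#' @rdname ddm_calibration_spec
#' @export
lba_calibration_spec <- function(means = NULL, sds = NULL, lower = NULL,
                                 upper = NULL) {
  nm <- c("A", "t0", "B", "s_v_true", "v_true", "v_false")
  corr <- diag(6)
  dimnames(corr) <- list(nm, nm)
  corr["t0", "A"] <- 0.59
  corr["B", "A"] <- -0.21; corr["B", "t0"] <- -0.50
  corr["s_v_true", "A"] <- 0.61; corr["s_v_true", "t0"] <- 0.43
  corr["s_v_true", "B"] <- 0.29
  corr["v_true", "A"] <- 0.54; corr["v_true", "t0"] <- 0.33
  corr["v_true", "B"] <- 0.30; corr["v_true", "s_v_true"] <- 0.87
  corr["v_false", "A"] <- 0.38; corr["v_false", "t0"] <- 0.09
  corr["v_false", "B"] <- 0.26; corr["v_false", "s_v_true"] <- 0.50
  corr["v_false", "v_true"] <- 0.49
  corr[upper.tri(corr)] <- t(corr)[upper.tri(corr)]
  def_means <- c(A = log(0.55), t0 = log(0.26), B = log(0.55),
                 s_v_true = log(1.35), v_true = 3.2, v_false = 1.4)
  def_sds <- c(A = 0.45, t0 = 0.35, B = 0.5, s_v_true = 0.3,
               v_true = 1.2, v_false = 1.1)
  # v_false is bounded below at 0: empirical LBA fits give the
  # mismatching accumulator a non-negative mean rate, and allowing
  # strongly negative values lets near-zero error rates arise from a
  # never-finishing error accumulator instead of the threshold/rate
  # regime the calibration represents
  def_lower <- c(A = 0.05, t0 = 0.08, B = 0.08, s_v_true = 0.3,
                 v_true = 0.2, v_false = 0)
  def_upper <- c(A = 3, t0 = 0.8, B = 3.5, s_v_true = 4,
                 v_true = 8, v_false = 5.5)
  .override <- function(def, ov) { if (!is.null(ov)) def[names(ov)] <- ov; def }
  tmvn_spec(nm,
            transforms = c(A = "log", t0 = "log", B = "log",
                           s_v_true = "log", v_true = "identity",
                           v_false = "identity"),
            means = .override(def_means, means),
            sds = .override(def_sds, sds),
            corr = corr,
            lower = .override(def_lower, lower),
            upper = .override(def_upper, upper))
}

#' Default slow-error constraint sets
#'
#' The slow-error regime requires more drift-rate than start-point
#' variability: `s_v > s_z` for the DDM (evaluated on the sampled
#' relative-range scale) and `s_v_true > s_v_false = 1` for the LBA.
#'
#' @param model `"ddm"` or `"lba"`.
#' @return a [constraint_set()].
#' @export
slow_error_constraints <- function(model = c("ddm", "lba")) {
  model <- match.arg(model)
  if (model == "ddm") {
    constraint_set(list(c("s_v", "s_z_rel")), slow_error = TRUE)
  } else {
    # s_v_false is fixed at 1, so the ordering reduces to a lower bound
    constraint_set(list(c("s_v_true", "1")), slow_error = TRUE)
  }
}

#' Convert sampled parameter rows to model parameter objects
#'
#' @param draw one row of a [sample_params()] data frame (or a named
#'   vector/list) on the sampled scale.
#' @return a [ddm_params()] or [lba_params()] object.
#' @export
ddm_params_from_draw <- function(draw) {
  draw <- as.list(draw)
  a <- draw$a
  z <- draw$z_rel * a
  s_z <- draw$s_z_rel * a
  # keep the start-point support strictly inside the boundaries
  s_z <- min(s_z, 2 * min(z, a - z) * 0.999)
  ddm_params(a = a, v = draw$v, z = z, s_v = draw$s_v, s_z = s_z,
             t0 = draw$t0)
}

#' @rdname ddm_params_from_draw
#' @export
lba_params_from_draw <- function(draw) {
  draw <- as.list(draw)
  lba_params(A = draw$A, B = draw$B, v_true = draw$v_true,
             v_false = draw$v_false, s_v_true = draw$s_v_true,
             t0 = draw$t0)
}
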
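#' Prior specification
#'
#' Independent truncated-normal priors, one per free parameter.
#'
#' @param params named list; each element a list with `mean`, `sd`, and
#'   support bounds `lower`, `upper` (may be infinite).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(params) {
  stopifnot(is.list(params), !is.null(names(params)))
  for (p in params) stopifnot(is.numeric(p$mean), p$sd > 0,
                              p$lower < p$upper)
  structure(list(params = params), class = "prior_spec")
}

# log density and sampler of the truncated-normal prior
.log_prior <- function(prior, theta) {
  lp <- 0
  for (nm in names(prior$params)) {
    p <- prior$params[[nm]]
    x <- theta[[nm]]
    if (is.na(x) || x < p$lower || x > p$upper) return(-Inf)
    z <- stats::pnorm(p$upper, p$mean, p$sd) -
      stats::pnorm(p$lower, p$mean, p$sd)
    lp <- lp + stats::dnorm(x, p$mean, p$sd, log = TRUE) - log(z)
  }
  lp
}

.sample_prior <- function(prior, n = 1) {
  out <- vapply(names(prior$params), function(nm) {
    p <- prior$params[[nm]]
    x <- stats::rnorm(n, p$mean, p$sd)
    bad <- x < p$lower | x > p$upper
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), p$mean, p$sd)
      bad <- x < p$lower | x > p$upper
    }
    x
  }, numeric(n))
  matrix(out, nrow = n, dimnames = list(NULL, names(prior$params)))
}

#' Widened prior presets
#'
#' Truncated-normal priors for the Study-1 parameterizations, centred on
#' values typical of the empirical DDM/LBA literature, with variances
#' inflated (default factor 4) so the priors are weakly informative.  For
#' designs with per-condition parameters, the affected entries are
#' replicated per condition (names like `v.easy`).
#'
#' The DDM preset (`"ddm-tran-widened"`) covers `a, v, z_rel, s_v, s_z,
#' t0` (the start point is estimated on the relative scale `z_rel = z/a`);
#' the LBA preset (`"lba-evans-widened"`) covers `A, B, v_true, v_false,
#' s_v_true, t0`.
#'
#' The default inflation (16, i.e. base SDs multiplied by 4) widens each
#' prior until its SD spans the empirically plausible range of the
#' parameter, so the priors are genuinely weakly informative: posteriors
#' in the weakly identified low-error regimes are then shaped by the
#' likelihood ridge rather than by the prior.  Smaller factors leave the
#' priors influential enough to mask the parameter trade-offs this
#' package exists to measure.
#'
#' @param preset `"ddm-tran-widened"` or `"lba-evans-widened"`.
#' @param inflate variance-inflation factor applied to the base variances.
#' @return a [prior_spec()].
#' @export
prior_preset <- function(preset = c("ddm-tran-widened",
                                    "lba-evans-widened"),
                         inflate = 16) {
  preset <- match.arg(preset)
  f <- sqrt(inflate)
  base <- if (preset == "ddm-tran-widened") {
    list(a = list(mean = 1.3, sd = 0.4, lower = 0.01, upper = 10),
         v = list(mean = 2.0, sd = 1.2, lower = -10, upper = 15),
         z_rel = list(mean = 0.5, sd = 0.1, lower = 0.02, upper = 0.98),
         s_v = list(mean = 1.0, sd = 0.5, lower = 0, upper = 10),
         s_z = list(mean = 0.2, sd = 0.15, lower = 0, upper = 5),
         t0 = list(mean = 0.3, sd = 0.15, lower = 0.01, upper = 2))
  } else {
    list(A = list(mean = 0.7, sd = 0.4, lower = 0.001, upper = 10),
         B = list(mean = 0.7, sd = 0.4, lower = 0.001, upper = 10),
         v_true = list(mean = 2.5, sd = 1.5, lower = -10, upper = 15),
         v_false = list(mean = 1.0, sd = 1.5, lower = -10, upper = 15),
         s_v_true = list(mean = 1.2, sd = 0.6, lower = 0.01, upper = 10),
         t0 = list(mean = 0.3, sd = 0.15, lower = 0.01, upper = 2))
  }
  prior_spec(lapply(base, function(p) {
    p$sd <- p$sd * f
    p
  }))
}

#' Sampler settings for DE-MCMC
#'
#' The chain count is tied to the number of free parameters: `3k` chains.
#' Chains are initialized with `init` samples; while unconverged, rounds
#' add `step` samples (discarding the earliest `step` until the R-hat
#' criterion is met, then growing) until all R-hat values (including the
#' multivariate one) fall below `rhat_threshold` and every parameter's
#' effective sample size reaches `ess_threshold`.
#'
#' @param k number of free parameters.
#' @param n_chains number of chains; must equal `3 * k`.
#' @param init initial samples per chain.
#' @param step samples added (and, pre-R-hat, removed) per round.
#' @param rhat_threshold convergence bound on R-hat.
#' @param ess_threshold minimum effective sample size per parameter.
#' @param max_rounds cap on add/remove rounds.
#' @param gamma crossover scale; default `2.38 / sqrt(2 k)`.
#' @param jitter half-width of the uniform proposal jitter.
#' @param p_migrate probability, per burn-in sweep, of a
#'   Metropolis-accepted migration sweep (cyclic state copying among a
#'   random chain subset).  Migration collapses outlier chains onto the
#'   posterior ridge, which dominates burn-in time in the
#'   weakly identified low-error regimes; it is disabled (0) after the
#'   R-hat criterion is met, and can be disabled entirely.
#' @param seed optional integer seed.
#' @return an object of class `sampler_settings`.
#' @export
sampler_settings <- function(k, n_chains = 3 * k, init = 120, step = 40,
                             rhat_threshold = 1.1, ess_threshold = 1000,
                             max_rounds = 250,
                             gamma = 2.38 / sqrt(2 * k), jitter = 1e-3,
                             p_migrate = 0.05, seed = NULL) {
  stopifnot(k >= 1, init >= 8, step >= 1, p_migrate >= 0, p_migrate <= 1)
  if (n_chains != 3 * k)
    stop("the sampler runs 3k chains: n_chains must equal 3 * k = ",
         3 * k, call. = FALSE)
  structure(list(k = k, n_chains = n_chains, init = init, step = step,
                 rhat_threshold = rhat_threshold,
                 ess_threshold = ess_threshold, max_rounds = max_rounds,
                 gamma = gamma, jitter = jitter, p_migrate = p_migrate,
                 seed = seed),
            class = "sampler_settings")
}

# Migration sweep: a random subset of chains proposes a cyclic copy of
# the previous selected chain's state (plus jitter), accepted per chain
# by a Metropolis step, so detailed balance is preserved.
.migrate_step <- function(state, logdens, logpost, jitter) {
  m <- nrow(state)
  L <- sample(2:max(2, ceiling(m / 2)), 1)
  sel <- sample.int(m, L)
  donors <- c(sel[L], sel[-L])        # cyclic: i takes i-1's state
  for (j in seq_len(L)) {
    i <- sel[j]
    prop <- state[donors[j], ] +
      stats::runif(ncol(state), -jitter, jitter)
    lp <- logpost(prop)
    if (is.nan(lp)) lp <- -Inf
    if (lp - logdens[i] >= log(stats::runif(1))) {
      state[i, ] <- prop
      logdens[i] <- lp
    }
  }
  list(state = state, logdens = logdens)
}

#' One differential-evolution MCMC sweep
#'
#' For each chain, a proposal `current + gamma * (x_r1 - x_r2) + U(-e, e)`
#' is formed from two distinct other chains and accepted by a Metropolis
#' step on the target log density.  With `gamma = 0` and zero jitter the
#' proposal is the identity and the chain never moves to a new point.
#'
#' @param state numeric matrix `chains x parameters` of current positions.
#' @param logdens numeric vector of current target log densities.
#' @param logpost function mapping a named parameter vector to the target
#'   log density (`-Inf` allowed; an error raised by the evaluator is
#'   surfaced together with the offending parameter vector).
#' @param gamma crossover scale.
#' @param jitter uniform jitter half-width.
#' @return list with updated `state`, `logdens`, and `accepted` count.
#' @export
de_mcmc_step <- function(state, logdens, logpost, gamma, jitter) {
  m <- nrow(state)
  stopifnot(m >= 4, length(logdens) == m)
  accepted <- 0L
  for (i in seq_len(m)) {
    rs <- sample.int(m - 1L, 2L)              # distinct, != i
    rs <- ifelse(rs >= i, rs + 1L, rs)
    prop <- state[i, ] + gamma * (state[rs[1], ] - state[rs[2], ]) +
      stats::runif(ncol(state), -jitter, jitter)
    lp <- tryCatch(logpost(prop), error = function(e)
      stop("log-posterior evaluation failed at (",
           paste(signif(prop, 4), collapse = ", "), "): ",
           conditionMessage(e), call. = FALSE))
    if (is.nan(lp)) lp <- -Inf
    if (lp - logdens[i] >= log(stats::runif(1))) {
      state[i, ] <- prop
      logdens[i] <- lp
      accepted <- accepted + 1L
    }
  }
  list(state = state, logdens = logdens, accepted = accepted)
}

# Run the DE-MCMC engine against a generic log posterior.
# init: matrix n_chains x k (named columns).  Returns posterior_samples.
run_de_mcmc <- function(logpost, init, settings) {
  m <- settings$n_chains; k <- settings$k
  par_names <- colnames(init)
  stopifnot(nrow(init) == m, ncol(init) == k)
  state <- init
  logdens <- apply(state, 1, logpost)
  if (any(!is.finite(logdens)))
    stop("initial chain states must have finite posterior density",
         call. = FALSE)
  draws <- array(NA_real_, c(0, m, k))
  total_acc <- 0L; total_prop <- 0L
  run_block <- function(n_iter, migrate = FALSE) {
    block <- array(NA_real_, c(n_iter, m, k))
    for (it in seq_len(n_iter)) {
      if (migrate && settings$p_migrate > 0 &&
          stats::runif(1) < settings$p_migrate) {
        mig <- .migrate_step(state, logdens, logpost, settings$jitter)
        state <<- mig$state; logdens <<- mig$logdens
      }
      stp <- de_mcmc_step(state, logdens, logpost,
                          settings$gamma, settings$jitter)
      state <<- stp$state; logdens <<- stp$logdens
      total_acc <<- total_acc + stp$accepted
      total_prop <<- total_prop + m
      block[it, , ] <- state
    }
    block
  }
  draws <- run_block(settings$init, migrate = TRUE)
  dimnames(draws) <- list(NULL, NULL, par_names)
  rounds <- 0L
  converged <- FALSE
  repeat {
    diag_ok <- tryCatch({
      rh <- compute_rhat(draws)
      ess <- compute_ess(draws)
      rhat_ok <- all(rh$per_parameter < settings$rhat_threshold) &&
        is.finite(rh$multivariate) &&
        rh$multivariate < settings$rhat_threshold
      ess_ok <- all(ess >= settings$ess_threshold)
      list(rh = rh, ess = ess, rhat_ok = rhat_ok, ess_ok = ess_ok)
    }, error = function(e) list(rh = NULL, ess = NULL, rhat_ok = FALSE,
                                ess_ok = FALSE))
    if (diag_ok$rhat_ok && diag_ok$ess_ok) { converged <- TRUE; break }
    if (rounds >= settings$max_rounds) break
    rounds <- rounds + 1L
    if (!diag_ok$rhat_ok) {
      # still burning in: add two steps of samples, discard the earliest
      # step, so the retained window both sheds transients and grows
      block <- run_block(2L * settings$step, migrate = TRUE)
      draws <- abind3(draws[-seq_len(min(settings$step, dim(draws)[1] - 8)),
                            , , drop = FALSE], block)
    } else {
      # mixed but short: grow the chains
      block <- run_block(settings$step)
      draws <- abind3(draws, block)
    }
    dimnames(draws) <- list(NULL, NULL, par_names)
  }
  rh <- tryCatch(compute_rhat(draws),
                 error = function(e) list(per_parameter =
                                            stats::setNames(rep(NA_real_, k),
                                                            par_names),
                                          multivariate = NA_real_))
  ess <- tryCatch(compute_ess(draws),
                  error = function(e) stats::setNames(rep(NA_real_, k),
                                                      par_names))
  structure(list(draws = draws, par_names = par_names,
                 rhat = rh$per_parameter, multivariate_rhat = rh$multivariate,
                 ess = ess, converged = converged, rounds = rounds,
                 acceptance_rate = total_acc / total_prop,
                 settings = settings),
            class = "posterior_samples")
}

abind3 <- function(a, b) {
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("DE-MCMC posterior samples:", dim(x$draws)[1], "iterations x",
      dim(x$draws)[2], "chains x", dim(x$draws)[3], "parameters\n")
  cat("converged:", x$converged, "| max R-hat:",
      signif(max(x$rhat, x$multivariate_rhat), 4),
      "| min ESS:", signif(min(x$ess), 4),
      "| acceptance:", signif(x$acceptance_rate, 3), "\n")
  invisible(x)
}

# --- model binding -------------------------------------------------------

# Free-parameter layout for a design: base parameters plus per-condition
# copies of the manipulated ones (Study 2: rates; Study 3: threshold).
.fit_par_names <- function(model, design) {
  conds <- design$conditions$condition
  if (model == "ddm") {
    base <- c("a", "v", "z_rel", "s_v", "s_z", "t0")
    if (design$study == 2)
      base <- c(setdiff(base, "v"), paste0("v.", conds))
    if (design$study == 3)
      base <- c(setdiff(base, "a"), paste0("a.", conds))
  } else {
    base <- c("A", "B", "v_true", "v_false", "s_v_true", "t0")
    if (design$study == 2)
      base <- c(setdiff(base, c("v_true", "v_false")),
                paste0("v_true.", conds), paste0("v_false.", conds))
    if (design$study == 3)
      base <- c(setdiff(base, "B"), paste0("B.", conds))
  }
  base
}

# Expand a base prior_spec to the per-condition layout.
.expand_prior <- function(prior, par_names) {
  out <- lapply(par_names, function(nm) {
    base_nm <- sub("\\..*$", "", nm)
    p <- prior$params[[base_nm]]
    if (is.null(p)) stop("no prior for parameter ", nm, call. = FALSE)
    p
  })
  names(out) <- par_names
  prior_spec(out)
}

# Build per-condition model parameter objects from a theta vector;
# returns NULL if theta violates model invariants.
.theta_to_params <- function(theta, model, design) {
  conds <- design$conditions$condition
  get <- function(base, cond) {
    nm <- paste0(base, ".", cond)
    if (nm %in% names(theta)) theta[[nm]] else theta[[base]]
  }
  out <- lapply(conds, function(cond) {
    tryCatch({
      if (model == "ddm") {
        a <- get("a", cond)
        ddm_params(a = a, v = get("v", cond), z = theta[["z_rel"]] * a,
                   s_v = theta[["s_v"]], s_z = theta[["s_z"]],
                   t0 = theta[["t0"]])
      } else {
        lba_params(A = theta[["A"]], B = get("B", cond),
                   v_true = get("v_true", cond),
                   v_false = get("v_false", cond),
                   s_v_true = theta[["s_v_true"]], t0 = theta[["t0"]])
      }
    }, error = function(e) NULL)
  })
  if (any(vapply(out, is.null, logical(1)))) return(NULL)
  names(out) <- conds
  out
}

#' Fit a model to a dataset with the convergence loop
#'
#' Estimates the joint posterior of the model parameters by
#' differential-evolution MCMC.  Chains (3 per free parameter) start from
#' over-dispersed prior draws (redrawn, up to a cap, until the posterior
#' density is finite), run `init` samples, then add samples in steps of
#' `step` -- discarding the earliest `step` while the R-hat criterion is
#' unmet, growing afterwards -- until all R-hat values are below 1.1 and
#' every parameter's ESS is at least 1000.  Non-convergence within
#' `max_rounds` returns a result flagged `converged = FALSE` (with a
#' warning), never a silent failure.
#'
#' @param data a `choice_rt_dataset`.
#' @param model `"ddm"` or `"lba"`.
#' @param design a [study_design()] describing the condition-to-parameter
#'   mapping; defaults to a Study-1 design inferred from the data.
#' @param prior a [prior_spec()] over the base parameters; defaults to the
#'   model's widened preset.
#' @param settings a [sampler_settings()]; defaults to the standard
#'   configuration for the design's parameter count.
#' @param init_redraw_cap redraws allowed per chain when searching for a
#'   finite-density initial state.
#' @param sz_order Gauss-Legendre order for the DDM start-point
#'   integration inside the likelihood (see [ddm_fpt_density()]).
#' @return a `posterior_samples` object.
#' @export
run_until_converged <- function(data, model = c("ddm", "lba"),
                                design = NULL, prior = NULL,
                                settings = NULL, init_redraw_cap = 10000,
                                sz_order = 16) {
  model <- match.arg(model)
  if (is.null(design)) {
    design <- study_design(1, model, error_rate = mean(
      data$response == "error"), n_trials = nrow(data), n_datasets = 1)
  }
  par_names <- .fit_par_names(model, design)
  k <- length(par_names)
  prior <- prior %||% prior_preset(if (model == "ddm") "ddm-tran-widened"
                                   else "lba-evans-widened")
  prior_full <- .expand_prior(prior, par_names)
  settings <- settings %||% sampler_settings(k)
  if (settings$k != k)
    stop("settings$k = ", settings$k, " but the design has ", k,
         " free parameters", call. = FALSE)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  loglik <- function(theta) {
    ps <- .theta_to_params(theta, model, design)
    if (is.null(ps)) return(-Inf)
    if (model == "ddm") ddm_log_likelihood(ps, data, sz_order = sz_order)
    else lba_log_likelihood(ps, data)
  }
  logpost <- function(theta) {
    theta <- stats::setNames(as.numeric(theta), par_names)
    lp <- .log_prior(prior_full, theta)
    if (!is.finite(lp)) return(-Inf)
    ll <- loglik(theta)
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }
  init <- matrix(NA_real_, settings$n_chains, k,
                 dimnames = list(NULL, par_names))
  for (c in seq_len(settings$n_chains)) {
    ok <- FALSE
    for (tries in seq_len(init_redraw_cap)) {
      cand <- .sample_prior(prior_full, 1)[1, ]
      if (is.finite(logpost(cand))) { init[c, ] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("could not initialize chain ", c,
                  " with finite posterior density within ",
                  init_redraw_cap, " prior draws", call. = FALSE)
  }
  fit <- run_de_mcmc(logpost, init, settings)
  if (!fit$converged)
    warning("sampler did not meet the convergence criteria within ",
            settings$max_rounds, " rounds", call. = FALSE)
  fit$model <- model
  fit$design <- design
  fit
}

#' Persist posterior samples
#'
#' Draws are written as long-format CSV (`iteration, chain, parameter,
#' value`) and a per-parameter summary CSV (median, 2.5%/97.5% quantiles,
#' R-hat, ESS) -- plain-text formats chosen for portability.
#'
#' @param fit a `posterior_samples` object.
#' @param draws_path,summary_path output CSV paths (`NULL` to skip one).
#' @return `summary_path` (or `draws_path`), invisibly.
#' @export
write_posterior_csv <- function(fit, draws_path = NULL,
                                summary_path = NULL) {
  stopifnot(inherits(fit, "posterior_samples"))
  if (!is.null(draws_path)) {
    d <- dim(fit$draws)
    long <- data.frame(
      iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
      chain = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      parameter = rep(fit$par_names, each = d[1] * d[2]),
      value = as.vector(fit$draws))
    utils::write.csv(long, draws_path, row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    med <- point_estimates(fit, warn_unconverged = FALSE)
    qs <- t(apply(matrix(fit$draws, prod(dim(fit$draws)[1:2]),
                         dim(fit$draws)[3]), 2,
                  eam_quantile, probs = c(0.025, 0.975)))
    utils::write.csv(data.frame(parameter = fit$par_names, median = med,
                                q2.5 = qs[, 1], q97.5 = qs[, 2],
                                rhat = fit$rhat, ess = fit$ess,
                                converged = fit$converged),
                     summary_path, row.names = FALSE)
  }
  invisible(summary_path %||% draws_path)
}
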
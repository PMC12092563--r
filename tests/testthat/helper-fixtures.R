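# Shared fixtures and small oracles used across test files.

fix_ddm <- function(...) {
  args <- utils::modifyList(list(a = 1.4, v = 2, z = 0.7, s_v = 1,
                                 s_z = 0.25, t0 = 0.3), list(...))
  do.call(ddm_params, args)
}

fix_lba <- function(...) {
  args <- utils::modifyList(list(A = 0.5, B = 0.8, v_true = 2.5,
                                 v_false = 1, s_v_true = 1.2, t0 = 0.25),
                            list(...))
  do.call(lba_params, args)
}

# numeric integral of a defective density over observed time; infinite
# upper limit so heavy finishing-time tails are fully captured
integrate_density <- function(f, t0, upper = Inf) {
  stats::integrate(f, lower = t0, upper = upper, rel.tol = 1e-9,
                   subdivisions = 1000L)$value
}

# Kolmogorov-Smirnov distance between simulated RTs for one response and
# the numerically integrated conditional CDF of the model density
# (cumulative trapezoid on a fine grid).
ks_distance <- function(rts, dens_fun, t0, p_response) {
  rts <- sort(rts)
  # dense linear grid over the bulk, log-spaced tail (LBA finishing
  # times are heavy-tailed, so a uniform grid to max(rt) is too coarse)
  bulk_end <- stats::quantile(rts, 0.995, names = FALSE)
  grid <- c(seq(t0, bulk_end, length.out = 8001),
            exp(seq(log(bulk_end), log(max(rts) + 0.5),
                    length.out = 2001))[-1])
  f <- dens_fun(grid)
  h <- diff(grid)
  cdf <- c(0, cumsum(h * (f[-1] + f[-length(f)]) / 2)) / p_response
  cdf_at <- stats::approx(grid, cdf, xout = rts, rule = 2)$y
  n <- length(rts)
  max(abs(cdf_at - seq_len(n) / n), abs(cdf_at - (seq_len(n) - 1) / n))
}

# one KS check of simulator against defective density for a model
expect_sim_density_agreement <- function(model, params, n_sim, seed) {
  if (model == "ddm") {
    sim <- ddm_simulate(params, n_sim, seed = seed)
    p_corr <- 1 - ddm_error_rate(params)
    dens_c <- function(t) ddm_fpt_density(params, t, "upper")
    dens_e <- function(t) ddm_fpt_density(params, t, "lower")
  } else {
    sim <- lba_simulate(params, n_sim, seed = seed)
    p_corr <- 1 - lba_error_rate(params)
    dens_c <- function(t) lba_defective_density(params, t, "matching")
    dens_e <- function(t) lba_defective_density(params, t, "mismatching")
  }
  for (resp in c("correct", "error")) {
    rts <- sim$rt[sim$response == resp]
    if (length(rts) < 100) next   # too few draws for a stable KS check
    p <- if (resp == "correct") p_corr else 1 - p_corr
    d <- ks_distance(rts, if (resp == "correct") dens_c else dens_e,
                     params$t0, p)
    crit <- 1.358 / sqrt(length(rts))   # 5% critical value
    expect_lt(d, 3 * crit)
  }
}

# fan a reproducible sub-seed out of a test-level seed
sub_seed <- function(seed, i) (seed * 131 + i * 7) %% 100000
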
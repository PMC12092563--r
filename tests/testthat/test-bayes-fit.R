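test_that("the chain count is tied to the number of free parameters", {
  expect_equal(sampler_settings(6)$n_chains, 18)
  expect_equal(sampler_settings(7)$n_chains, 21)
  expect_error(sampler_settings(6, n_chains = 10), "3k")
})

test_that("DE-MCMC recovers the moments of a standard normal target", {
  set.seed(1)
  logpost <- function(theta) -0.5 * sum(theta^2)
  state <- matrix(rnorm(12, sd = 3), 12, 1)
  logdens <- apply(state, 1, logpost)
  draws <- matrix(NA_real_, 5000, 12)
  g <- 2.38 / sqrt(2)
  for (it in 1:5000) {
    s <- de_mcmc_step(state, logdens, logpost, g, 1e-3)
    state <- s$state; logdens <- s$logdens
    draws[it, ] <- state[, 1]
  }
  kept <- draws[-(1:500), ]
  expect_lt(abs(mean(kept)), 0.05)
  expect_lt(abs(stats::sd(kept) - 1), 0.05)
})

test_that("DE-MCMC recovers the correlation of a bivariate normal target", {
  set.seed(2)
  rho <- 0.7
  prec <- solve(matrix(c(1, rho, rho, 1), 2))
  logpost <- function(theta) -0.5 * drop(theta %*% prec %*% theta)
  m <- 12
  state <- matrix(rnorm(2 * m, sd = 2), m, 2)
  logdens <- apply(state, 1, logpost)
  draws <- array(NA_real_, c(4000, m, 2))
  g <- 2.38 / sqrt(4)
  for (it in 1:4000) {
    s <- de_mcmc_step(state, logdens, logpost, g, 1e-3)
    state <- s$state; logdens <- s$logdens
    draws[it, , ] <- state
  }
  kept <- draws[-(1:500), , ]
  pooled <- matrix(kept, ncol = 2)
  expect_lt(abs(stats::cor(pooled)[1, 2] - rho), 0.03)
})

test_that("a degenerate proposal (gamma 0, no jitter) never moves", {
  set.seed(3)
  logpost <- function(theta) -0.5 * sum(theta^2)
  state <- matrix(rnorm(8), 8, 1)
  logdens <- apply(state, 1, logpost)
  s <- state
  for (it in 1:50) {
    out <- de_mcmc_step(s, logdens, logpost, gamma = 0, jitter = 0)
    s <- out$state; logdens <- out$logdens
  }
  expect_equal(s, state)
})

test_that("an error in the likelihood evaluator is surfaced with the
          parameter vector", {
  state <- matrix(1:8 / 8, 8, 1)
  expect_error(
    de_mcmc_step(state, rep(0, 8), function(theta) stop("boom"),
                 0.5, 1e-3),
    "log-posterior evaluation failed")
})

test_that("R-hat is near 1 for replicated chains and large for disjoint
          chains; degenerate input errors", {
  set.seed(4)
  one <- rnorm(200)
  same <- array(rep(one, 4), c(200, 4, 1), dimnames = list(NULL, NULL, "x"))
  rh <- compute_rhat(same)
  expect_lt(abs(rh$per_parameter[["x"]] - 1), 0.01)
  expect_lt(abs(rh$multivariate - 1), 0.01)
  far <- array(c(rnorm(200, 0, 0.1), rnorm(200, 50, 0.1)),
               c(200, 2, 1), dimnames = list(NULL, NULL, "x"))
  expect_gt(compute_rhat(far)$per_parameter[["x"]], 5)
  flat <- array(1, c(50, 3, 1), dimnames = list(NULL, NULL, "x"))
  expect_error(compute_rhat(flat), "zero within-chain variance")
})

test_that("ESS of white-noise chains approaches the draw count", {
  set.seed(5)
  L <- 2000
  x <- array(rnorm(L * 4), c(L, 4, 1), dimnames = list(NULL, NULL, "x"))
  ess <- compute_ess(x)
  expect_lt(abs(ess[["x"]] - 4 * L) / (4 * L), 0.1)
})

test_that("priors are proper over the support and widened by the stated
          inflation factor", {
  pr <- prior_preset("ddm-tran-widened", inflate = 4)
  base <- prior_preset("ddm-tran-widened", inflate = 1)
  expect_equal(pr$params$a$sd, 2 * base$params$a$sd)
  th <- c(a = 1.3, v = 2, z_rel = 0.5, s_v = 1, s_z = 0.2, t0 = 0.3)
  expect_true(is.finite(eamrec:::.log_prior(pr, as.list(th))))
  th_bad <- th; th_bad[["a"]] <- -1
  expect_identical(eamrec:::.log_prior(pr, as.list(th_bad)), -Inf)
})

test_that("the convergence loop honours its own thresholds and flags", {
  des <- study_design(1, "lba", 0.25, n_trials = 150, n_datasets = 1)
  d <- generate_dataset(des, seed = 111)
  st <- sampler_settings(6, ess_threshold = 150, max_rounds = 60,
                         seed = 7)
  fit <- run_until_converged(d, "lba", des, settings = st)
  expect_s3_class(fit, "posterior_samples")
  expect_equal(dim(fit$draws)[2], 18)        # 3k chains for k = 6
  if (fit$converged) {
    expect_true(all(fit$rhat < st$rhat_threshold))
    expect_lt(fit$multivariate_rhat, st$rhat_threshold)
    expect_true(all(fit$ess >= st$ess_threshold))
  }
  # end-to-end reproducibility under a fixed seed
  fit2 <- run_until_converged(d, "lba", des, settings = st)
  expect_equal(fit$draws, fit2$draws)
})

test_that("posterior medians recover LBA generating values at a high error
          rate with many trials", {
  # fixed generating parameters with ~27% errors, five seeded replicates
  p <- lba_params(A = 0.5, B = 0.8, v_true = 2.8, v_false = 1.8,
                  s_v_true = 1.2, t0 = 0.25)
  rel_err <- vapply(1:5, function(i) {
    d <- lba_simulate(p, 1200, seed = 700 + i)
    st <- sampler_settings(6, ess_threshold = 300, max_rounds = 80,
                           seed = i)
    fit <- suppressWarnings(run_until_converged(d, "lba", settings = st))
    med <- point_estimates(fit, warn_unconverged = FALSE)
    c(abs(med[["v_true"]] - p$v_true) / p$v_true,
      abs(med[["B"]] - p$B) / p$B)
  }, numeric(2))
  expect_lt(mean(rel_err[1, ]), 0.15)   # v_true
  expect_lt(mean(rel_err[2, ]), 0.15)   # B
})

test_that("condition-manipulation designs estimate per-condition
          parameters with 3k chains", {
  des <- study_design(3, "lba", 0.25, n_trials = 200, n_datasets = 1,
                      drift_bounds = c(2, 3.2))
  d <- generate_dataset(des, seed = 77)
  k <- 7   # A, v_true, v_false, s_v_true, t0, B.accuracy, B.speed
  st <- sampler_settings(k, ess_threshold = 40, max_rounds = 10, seed = 2)
  fit <- suppressWarnings(run_until_converged(d, "lba", des,
                                              settings = st))
  expect_equal(dim(fit$draws)[2], 21)
  expect_setequal(fit$par_names,
                  c("A", "v_true", "v_false", "s_v_true", "t0",
                    "B.accuracy", "B.speed"))
})

test_that("posterior draws persist to CSV with summaries", {
  des <- study_design(1, "lba", 0.25, n_trials = 150, n_datasets = 1)
  d <- generate_dataset(des, seed = 113)
  st <- sampler_settings(6, ess_threshold = 50, max_rounds = 10, seed = 1)
  fit <- suppressWarnings(run_until_converged(d, "lba", des,
                                              settings = st))
  dp <- file.path(tempdir(), "draws.csv")
  sp <- file.path(tempdir(), "summary.csv")
  write_posterior_csv(fit, dp, sp)
  draws <- utils::read.csv(dp)
  expect_identical(names(draws),
                   c("iteration", "chain", "parameter", "value"))
  expect_equal(nrow(draws), prod(dim(fit$draws)))
  summ <- utils::read.csv(sp)
  expect_setequal(summ$parameter, fit$par_names)
  unlink(c(dp, sp))
})
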
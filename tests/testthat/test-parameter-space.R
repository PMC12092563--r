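wide <- function(spec) {
  # lift truncation so the transformed-scale draws are exactly MVN
  spec$lower[] <- -Inf
  spec$lower[spec$transforms %in% c("log", "logit")] <- 0
  spec$upper[] <- Inf
  spec$upper[spec$transforms == "logit"] <- 1
  spec
}

to_transformed_df <- function(spec, draws) {
  out <- draws
  for (nm in spec$names) {
    out[[nm]] <- switch(spec$transforms[[nm]],
                        identity = draws[[nm]],
                        log = log(draws[[nm]]),
                        logit = stats::qlogis(draws[[nm]]))
  }
  out
}

test_that("sampled correlation structure reproduces the calibration
          matrices on the transformed scale", {
  for (model in c("ddm", "lba")) {
    spec <- wide(if (model == "ddm") ddm_calibration_spec()
                 else lba_calibration_spec())
    draws <- sample_params(spec, NULL, n = 1e5, seed = 101)
    emp <- stats::cor(as.matrix(to_transformed_df(spec, draws)))
    expect_lt(max(abs(emp - spec$corr)), 0.03)
    if (model == "ddm")
      expect_equal(emp["a", "t0"], 0.23, tolerance = 0.02)
    else
      expect_equal(emp["A", "t0"], 0.59, tolerance = 0.02)
  }
})

test_that("ordering constraints hold in every accepted draw", {
  draws <- sample_params(ddm_calibration_spec(),
                         slow_error_constraints("ddm"), n = 2000,
                         seed = 5)
  expect_true(all(draws$s_v > draws$s_z_rel))
  lb <- sample_params(lba_calibration_spec(),
                      slow_error_constraints("lba"), n = 2000, seed = 6)
  expect_true(all(lb$s_v_true > 1))
})

test_that("an infeasible constraint raises an error naming the binding
          criterion", {
  spec <- tmvn_spec(c("p1", "p2"),
                    transforms = c(p1 = "identity", p2 = "identity"),
                    means = c(p1 = 0, p2 = 12), sds = c(p1 = 1, p2 = 1),
                    corr = diag(2), lower = c(p1 = -Inf, p2 = -Inf),
                    upper = c(p1 = Inf, p2 = Inf))
  expect_error(sample_params(spec, constraint_set(list(c("p1", "p2"))),
                             n = 10, seed = 1),
               "p1>p2")
})

test_that("marginal means and SDs are recovered for an identity-correlation
          spec with wide bounds", {
  spec <- tmvn_spec(c("x", "y"),
                    transforms = c(x = "identity", y = "identity"),
                    means = c(x = 1, y = -2), sds = c(x = 0.5, y = 2),
                    corr = diag(2), lower = c(x = -Inf, y = -Inf),
                    upper = c(x = Inf, y = Inf))
  n <- 4e4
  draws <- sample_params(spec, NULL, n = n, seed = 11)
  expect_lt(abs(mean(draws$x) - 1), 3 * 0.5 / sqrt(n))
  expect_lt(abs(stats::sd(draws$y) - 2), 3 * 2 / sqrt(n))
})

test_that("conditioning on nothing reproduces the unconditional sampler", {
  spec <- ddm_calibration_spec()
  a <- sample_params(spec, NULL, n = 1e4, seed = 21)
  b <- conditional_sample(spec, fixed = numeric(0), NULL, n = 1e4,
                          seed = 22)
  ks <- suppressWarnings(stats::ks.test(a$a, b$a))
  expect_gt(ks$p.value, 0.01)
})

test_that("conditional sampling follows the Gaussian conditioning formula", {
  rho <- 0.8
  corr <- matrix(c(1, rho, rho, 1), 2,
                 dimnames = list(c("x", "y"), c("x", "y")))
  spec <- tmvn_spec(c("x", "y"),
                    transforms = c(x = "identity", y = "identity"),
                    means = c(x = 2, y = -1), sds = c(x = 1, y = 3),
                    corr = corr, lower = c(x = -Inf, y = -Inf),
                    upper = c(x = Inf, y = Inf))
  fixed <- c(x = 3.5)
  n <- 4e4
  draws <- conditional_sample(spec, fixed, NULL, n = n, seed = 31)
  mu_oracle <- -1 + rho * 3 / 1 * (3.5 - 2)
  sd_oracle <- 3 * sqrt(1 - rho^2)
  expect_equal(mean(draws$y), mu_oracle,
               tolerance = 4 * sd_oracle / sqrt(n) / abs(mu_oracle))
  expect_equal(stats::sd(draws$y), sd_oracle, tolerance = 0.02)
  expect_true(all(draws$x == 3.5))
})

test_that("conditioning at the mean under identity correlation leaves free
          marginals unchanged", {
  spec <- tmvn_spec(c("x", "y"),
                    transforms = c(x = "identity", y = "identity"),
                    means = c(x = 0, y = 1), sds = c(x = 1, y = 2),
                    corr = diag(2), lower = c(x = -Inf, y = -Inf),
                    upper = c(x = Inf, y = Inf))
  draws <- conditional_sample(spec, c(x = 0), NULL, n = 3e4, seed = 41)
  expect_equal(mean(draws$y), 1, tolerance = 3 * 2 / sqrt(3e4))
  expect_equal(stats::sd(draws$y), 2, tolerance = 0.05)
})

test_that("drift bounds follow the linear-interpolation quantile rule", {
  by_rate <- list("0.05" = c(1, 2, 3, 4), "0.25" = rep(2.5, 10))
  expect_equal(unname(drift_bounds_from_quantiles(by_rate, 0.05)),
               c(1.75, 3.25))
  expect_equal(unname(drift_bounds_from_quantiles(by_rate, 0.25)),
               c(2.5, 2.5))
  b <- drift_bounds_from_quantiles(by_rate, 0.05)
  expect_lte(b[["lower"]], b[["upper"]])
  expect_error(drift_bounds_from_quantiles(by_rate, 0.45), "0.45")
})

test_that("speed thresholds respect ordinal consistency and the
          conditional distribution", {
  spec <- lba_calibration_spec()
  acc <- unlist(sample_params(spec, NULL, n = 1, seed = 51)[1, ])
  set.seed(52)
  draws <- replicate(50, sample_speed_threshold(spec, acc, "B"))
  expect_true(all(draws < acc[["B"]]))
  # joint-rejection oracle on a correlated 2-parameter toy spec
  rho <- 0.7
  corr <- matrix(c(1, rho, rho, 1), 2,
                 dimnames = list(c("thr", "x"), c("thr", "x")))
  toy <- tmvn_spec(c("thr", "x"),
                   transforms = c(thr = "identity", x = "identity"),
                   means = c(thr = 2, x = 0), sds = c(thr = 0.5, x = 1),
                   corr = corr, lower = c(thr = -Inf, x = -Inf),
                   upper = c(thr = Inf, x = Inf))
  acc_toy <- c(thr = 2.6, x = 1.2)
  set.seed(53)
  cond_draws <- replicate(400, sample_speed_threshold(toy, acc_toy, "thr"))
  # brute force: joint draws with x in a narrow window around 1.2,
  # thresholded below the accuracy value
  joint <- MASS::mvrnorm(4e5, mu = c(2, 0),
                         Sigma = diag(c(0.5, 1)) %*% corr %*%
                           diag(c(0.5, 1)))
  sel <- joint[abs(joint[, 2] - 1.2) < 0.02 & joint[, 1] < 2.6, 1]
  expect_gt(length(sel), 500)
  expect_equal(mean(cond_draws), mean(sel), tolerance = 0.05)
  expect_equal(stats::sd(cond_draws), stats::sd(sel), tolerance = 0.08)
})

test_that("sampling is reproducible under a seed", {
  a <- sample_params(ddm_calibration_spec(), NULL, n = 50, seed = 99)
  b <- sample_params(ddm_calibration_spec(), NULL, n = 50, seed = 99)
  expect_identical(a, b)
})

test_that("sampled draws convert to valid model parameter objects", {
  dd <- sample_params(ddm_calibration_spec(), slow_error_constraints("ddm"),
                      n = 200, seed = 61)
  for (i in seq_len(50)) {
    p <- ddm_params_from_draw(dd[i, ])
    expect_s3_class(p, "ddm_params")
    expect_true(p$z - p$s_z / 2 > 0 && p$z + p$s_z / 2 < p$a)
  }
  lb <- sample_params(lba_calibration_spec(), slow_error_constraints("lba"),
                      n = 50, seed = 62)
  expect_s3_class(lba_params_from_draw(lb[1, ]), "lba_params")
})
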
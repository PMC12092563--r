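make_draws <- function(mat, chains = 2) {
  # split a draws matrix (rows = samples, cols = parameters) into a
  # chains x iterations x parameters array container
  n <- nrow(mat) / chains
  arr <- array(NA_real_, c(n, chains, ncol(mat)),
               dimnames = list(NULL, NULL, colnames(mat)))
  for (c in seq_len(chains))
    arr[, c, ] <- mat[(c - 1) * n + seq_len(n), ]
  arr
}

test_that("posterior medians follow the documented midpoint rule", {
  two <- array(c(-1, 1, -1, 1), c(2, 2, 1),
               dimnames = list(NULL, NULL, "x"))
  expect_equal(point_estimates(two)[["x"]], 0)
  const <- array(3.5, c(10, 3, 1), dimnames = list(NULL, NULL, "x"))
  expect_equal(point_estimates(const)[["x"]], 3.5)
  set.seed(1)
  n <- 1e4
  big <- array(rnorm(n, mean = 2, sd = 1), c(n / 2, 2, 1),
               dimnames = list(NULL, NULL, "x"))
  expect_lt(abs(point_estimates(big)[["x"]] - 2), 3 / sqrt(n))
})

test_that("RMSD matches the formula and is scale-equivariant", {
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsd(c(0, 0), c(1, 1)), 1)
  expect_equal(rmsd(c(0, 4), c(0, 0)), sqrt(8))
  expect_error(rmsd(1:3, 1:4), "equal length")
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(rmsd(3 * x, 3 * y), 3 * rmsd(x, y))
})

test_that("recovery correlation is affine-invariant, null-calibrated, and
          sentinels on zero variance", {
  x <- rnorm(50)
  expect_equal(recovery_correlation(x, 2 * x + 1), 1)
  set.seed(2)
  r <- recovery_correlation(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(r), 0.05)
  s <- recovery_correlation(rep(1, 10), rnorm(10))
  expect_true(is.na(s))
  expect_equal(attr(s, "reason"), "zero variance")
})

test_that("absolute-deviation intervals use linear-interpolation quantiles", {
  iv <- abs_dev_interval(0:100, rep(0, 101))
  expect_equal(unname(iv), c(2.5, 97.5))
})

test_that("pairwise posterior correlations and partials match analytic
          oracles", {
  # two parameters: partial equals Pearson
  set.seed(3)
  a <- rnorm(2000); b <- 0.6 * a + rnorm(2000)
  d2 <- make_draws(cbind(p1 = a, p2 = b))
  tr <- posterior_pairwise(d2)
  expect_equal(tr$partial[1, 2], tr$pearson[1, 2], tolerance = 1e-12)
  # exact linear dependence
  d_lin <- make_draws(cbind(p1 = a, p2 = 2 * a))
  tr_lin <- posterior_pairwise(d_lin)
  expect_equal(tr_lin$pearson[1, 2], 1, tolerance = 1e-12)
  expect_true(tr_lin$singular)
  # three-variable Gaussian with known precision matrix
  prec <- matrix(c(2, -1, 0, -1, 2, -1, 0, -1, 2), 3)
  sig <- solve(prec)
  set.seed(4)
  x <- MASS::mvrnorm(1e5, mu = rep(0, 3), Sigma = sig)
  colnames(x) <- c("p1", "p2", "p3")
  tr3 <- posterior_pairwise(make_draws(x))
  partial_oracle <- -prec / sqrt(outer(diag(prec), diag(prec)))
  diag(partial_oracle) <- 1
  expect_lt(max(abs(tr3$partial - partial_oracle)), 0.02)
  # matrices are symmetric with unit diagonal and entries in [-1, 1]
  expect_equal(tr3$partial, t(tr3$partial))
  expect_true(all(abs(tr3$pearson) <= 1 + 1e-12))
})

test_that("partial correlations equal brute-force residual-regression
          partials", {
  set.seed(5)
  x <- matrix(rnorm(400 * 4), 400, 4)
  x[, 2] <- x[, 2] + 0.5 * x[, 1]
  x[, 4] <- x[, 4] - 0.3 * x[, 3] + 0.2 * x[, 1]
  colnames(x) <- paste0("p", 1:4)
  tr <- posterior_pairwise(make_draws(x))
  for (i in 1:3) for (j in (i + 1):4) {
    others <- setdiff(1:4, c(i, j))
    ri <- stats::lm.fit(cbind(1, x[, others]), x[, i])$residuals
    rj <- stats::lm.fit(cbind(1, x[, others]), x[, j])$residuals
    expect_equal(tr$partial[i, j], stats::cor(ri, rj), tolerance = 1e-10)
  }
})

test_that("ratio recovery cancels a shared multiplicative bias", {
  set.seed(6)
  n_ds <- 12
  true_num <- runif(n_ds, 1, 3)
  true_den <- runif(n_ds, 0.5, 2)
  # posteriors concentrated at a per-dataset multiple of the truth:
  # components are badly biased, the ratio is exact
  fits <- lapply(seq_len(n_ds), function(i) {
    f <- runif(1, 1.2, 2.5)
    make_draws(cbind(v = true_num[i] * f + rnorm(400, sd = 1e-8),
                     a = true_den[i] * f + rnorm(400, sd = 1e-8)))
  })
  rr <- ratio_recovery(true_num, true_den, fits, "v", "a")
  expect_equal(rr$r, 1, tolerance = 1e-6)
  expect_lt(rr$rmsd, 1e-6)
  # perfect component recovery implies perfect ratio recovery
  fits_perfect <- lapply(seq_len(n_ds), function(i)
    make_draws(cbind(v = rep(true_num[i], 400),
                     a = rep(true_den[i], 400))))
  rr2 <- ratio_recovery(true_num, true_den, fits_perfect, "v", "a")
  expect_equal(rr2$r, 1, tolerance = 1e-12)
  expect_equal(rr2$rmsd, 0, tolerance = 1e-12)
})

test_that("median-of-ratio and ratio-of-medians diverge on skewed
          posteriors exactly as brute force says", {
  set.seed(7)
  draws <- cbind(v = exp(rnorm(4000, 0, 1)), a = exp(rnorm(4000, 0, 1.5)))
  fits <- list(make_draws(draws), make_draws(draws))
  m1 <- ratio_recovery(c(1, 1), c(1, 1), fits, "v", "a",
                       method = "median_of_ratio")
  m2 <- ratio_recovery(c(1, 1), c(1, 1), fits, "v", "a",
                       method = "ratio_of_medians")
  est1 <- attr(m1, "estimates")$ratio[1]
  est2 <- attr(m2, "estimates")$ratio[1]
  expect_equal(est1, stats::median(draws[, "v"] / draws[, "a"]),
               tolerance = 1e-12)
  expect_equal(est2, stats::median(draws[, "v"]) /
                 stats::median(draws[, "a"]), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(est1, est2)))
})

test_that("near-zero denominators are excluded with a count", {
  fits <- list(make_draws(cbind(v = rnorm(100, 2), a = rnorm(100, 1))),
               make_draws(cbind(v = rnorm(100, 2), a = rnorm(100, 1))),
               make_draws(cbind(v = rnorm(100, 2), a = rnorm(100, 1))))
  rr <- ratio_recovery(c(2, 2, 2), c(1, 0, 1), fits, "v", "a")
  expect_equal(attr(rr, "n_excluded"), 1)
  expect_equal(rr$n, 2)
})

test_that("group differences compare estimated and true means", {
  tru <- data.frame(v = c(1, 2, 3), a = c(1, 1, 1))
  gd0 <- group_difference(tru, tru, tru, tru)
  expect_equal(gd0$est_diff, c(0, 0))
  expect_equal(gd0$true_diff, c(0, 0))
  # drift offset delta with unbiased estimation noise
  set.seed(8)
  delta <- 0.8
  n <- 200
  gA <- data.frame(v = rnorm(n, 2 + delta, 0.3))
  gB <- data.frame(v = rnorm(n, 2, 0.3))
  estA <- data.frame(v = gA$v + rnorm(n, 0, 0.2))
  estB <- data.frame(v = gB$v + rnorm(n, 0, 0.2))
  gd <- group_difference(gA, estA, gB, estB)
  expect_equal(gd$est_diff, delta, tolerance = 4 * 0.5 / sqrt(n))
  # sign agreement across replicates
  signs <- vapply(1:40, function(i) {
    gA <- data.frame(v = rnorm(12, 2.5, 0.3))
    gB <- data.frame(v = rnorm(12, 2, 0.3))
    gd <- group_difference(gA, data.frame(v = gA$v + rnorm(12, 0, 0.1)),
                           gB, data.frame(v = gB$v + rnorm(12, 0, 0.1)))
    sign(gd$est_diff) == sign(gd$true_diff)
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("recovery reports export as tidy CSV", {
  tru <- data.frame(a = c(1, 1.5, 2), v = c(2, 2.5, 3))
  est <- data.frame(a = c(1.1, 1.4, 2.2), v = c(2.1, 2.4, 3.2))
  rep_ <- recovery_report(tru, est)
  expect_equal(rep_$n, c(3, 3))
  path <- file.path(tempdir(), "rec.csv")
  write_recovery_csv(list(cell1 = rep_), path)
  out <- utils::read.csv(path)
  expect_setequal(unique(out$statistic),
                  c("r", "rmsd", "adev_q2.5", "adev_q97.5"))
  expect_equal(nrow(out), 8)
  unlink(path)
})
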
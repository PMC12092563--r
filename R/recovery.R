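#' Posterior point estimates
#'
#' Marginal posterior medians per parameter, pooled over chains.  For an
#' even number of draws the median is the usual midpoint of the two
#' central order statistics.
#'
#' @param samples a `posterior_samples` object (or 3-d array).
#' @param warn_unconverged warn when the input is flagged unconverged.
#' @return named numeric vector of medians.
#' @export
point_estimates <- function(samples, warn_unconverged = TRUE) {
  if (inherits(samples, "posterior_samples") && warn_unconverged &&
      !isTRUE(samples$converged))
    warning("point estimates from an unconverged fit", call. = FALSE)
  x <- .as_sample_array(samples)
  k <- dim(x)[3]
  stats::setNames(vapply(seq_len(k), function(j)
    stats::median(x[, , j]), numeric(1)), dimnames(x)[[3]])
}

#' Root mean squared deviation
#'
#' `RMSD = sqrt(mean((x_true - x_est)^2))`, comparable across error-rate
#' scenarios but not across parameters or models (scale differences).
#'
#' @param x_true,x_est numeric vectors of equal length.
#' @return scalar RMSD.
#' @export
rmsd <- function(x_true, x_est) {
  if (length(x_true) != length(x_est))
    stop("'x_true' and 'x_est' must have equal length", call. = FALSE)
  sqrt(mean((x_true - x_est)^2))
}

#' Recovery correlation between true and estimated values
#'
#' Pearson correlation; with zero variance in either vector the
#' correlation is undefined and reported as an `NA` sentinel with a
#' `reason` attribute (never an error), mirroring scenarios where the
#' true values have essentially no spread.
#'
#' @param x_true,x_est numeric vectors (length >= 3).
#' @return scalar correlation, or `NA` with a `reason` attribute.
#' @export
recovery_correlation <- function(x_true, x_est) {
  stopifnot(length(x_true) == length(x_est), length(x_true) >= 3)
  if (stats::sd(x_true) == 0 || stats::sd(x_est) == 0)
    return(structure(NA_real_, reason = "zero variance"))
  stats::cor(x_true, x_est)
}

#' 95% interval of absolute deviations
#'
#' 2.5th and 97.5th quantiles of `|x_true - x_est|` under the package-wide
#' linear-interpolation quantile rule.
#'
#' @param x_true,x_est numeric vectors of equal length.
#' @return numeric `c(q2.5, q97.5)`.
#' @export
abs_dev_interval <- function(x_true, x_est) {
  if (length(x_true) != length(x_est))
    stop("'x_true' and 'x_est' must have equal length", call. = FALSE)
  stats::setNames(eam_quantile(abs(x_true - x_est), c(0.025, 0.975)),
                  c("q2.5", "q97.5"))
}

#' Posterior pairwise and partial correlations
#'
#' Pairwise Pearson correlations between the marginal posterior sample
#' vectors (pooled over chains), and the corresponding partial
#' correlations obtained from the inverse of the Pearson correlation
#' matrix (negated, scaled off-diagonal elements).  With only two
#' parameters the partial correlation equals the Pearson correlation.  A
#' numerically singular correlation matrix falls back to the
#' Moore-Penrose pseudo-inverse and flags the report.
#'
#' @param samples a `posterior_samples` object (or 3-d array).
#' @return a `tradeoff_report`: list with `pearson` and `partial`
#'   correlation matrices and a `singular` flag.
#' @export
posterior_pairwise <- function(samples) {
  x <- .as_sample_array(samples)
  k <- dim(x)[3]
  pooled <- matrix(x, nrow = dim(x)[1] * dim(x)[2], ncol = k)
  colnames(pooled) <- dimnames(x)[[3]]
  pearson <- stats::cor(pooled)
  singular <- FALSE
  inv <- tryCatch(solve(pearson), error = function(e) {
    singular <<- TRUE
    MASS::ginv(pearson)
  })
  if (!singular && rcond(pearson) < 1e-12) singular <- TRUE
  d <- sqrt(diag(inv))
  partial <- -inv / outer(d, d)
  diag(partial) <- 1
  dimnames(partial) <- dimnames(pearson)
  structure(list(pearson = pearson, partial = partial,
                 singular = singular),
            class = "tradeoff_report")
}

#' Per-parameter recovery report
#'
#' Collects, for each parameter, the true data-generating values and
#' point estimates across datasets, and computes the recovery statistics:
#' Pearson correlation, RMSD, and the 95% absolute-deviation interval.
#'
#' @param x_true named list (or data frame) of true-value vectors, one
#'   per parameter.
#' @param x_est matching estimates (posterior medians).
#' @return a `recovery_report` data frame: one row per parameter with
#'   columns `parameter, n, r, rmsd, adev_q2.5, adev_q97.5`, carrying the
#'   raw vectors as an attribute.
#' @export
recovery_report <- function(x_true, x_est) {
  x_true <- as.data.frame(x_true); x_est <- as.data.frame(x_est)
  stopifnot(nrow(x_true) == nrow(x_est), nrow(x_true) >= 2,
            all(names(x_true) %in% names(x_est)))
  rows <- lapply(names(x_true), function(nm) {
    tv <- x_true[[nm]]; ev <- x_est[[nm]]
    iv <- abs_dev_interval(tv, ev)
    data.frame(parameter = nm, n = length(tv),
               r = if (length(tv) >= 3)
                 as.numeric(recovery_correlation(tv, ev)) else NA_real_,
               rmsd = rmsd(tv, ev),
               adev_q2.5 = iv[1], adev_q97.5 = iv[2],
               row.names = NULL)
  })
  structure(do.call(rbind, rows),
            truth = x_true, estimates = x_est,
            class = c("recovery_report", "data.frame"))
}

#' Recovery of a parameter ratio
#'
#' Recovery statistics for a ratio of two parameters (drift/threshold:
#' DDM `v/a`, LBA `v_true/B`) across datasets.  The true ratio comes from
#' the generating values; the estimated ratio is, by default, the
#' posterior median of the per-draw ratio (`method = "median_of_ratio"`;
#' `"ratio_of_medians"` is available for comparison).  Datasets whose
#' true or estimated denominator is within `eps` of zero are excluded,
#' with the exclusion count reported.
#'
#' @param true_num,true_den numeric vectors of generating values.
#' @param fits list of `posterior_samples` objects (one per dataset).
#' @param numerator,denominator parameter names in the fits.
#' @param method ratio point-estimate rule.
#' @param eps near-zero denominator guard.
#' @return one-row `recovery_report` for the ratio, with an
#'   `n_excluded` attribute.
#' @export
ratio_recovery <- function(true_num, true_den, fits, numerator,
                           denominator,
                           method = c("median_of_ratio",
                                      "ratio_of_medians"),
                           eps = 1e-8) {
  method <- match.arg(method)
  stopifnot(length(true_num) == length(true_den),
            length(fits) == length(true_num))
  est <- vapply(fits, function(f) {
    x <- .as_sample_array(f)
    num <- as.vector(x[, , match(numerator, dimnames(x)[[3]])])
    den <- as.vector(x[, , match(denominator, dimnames(x)[[3]])])
    if (method == "median_of_ratio") {
      if (min(abs(den)) < eps) return(NA_real_)
      stats::median(num / den)
    } else {
      md <- stats::median(den)
      if (abs(md) < eps) return(NA_real_)
      stats::median(num) / md
    }
  }, numeric(1))
  keep <- abs(true_den) >= eps & !is.na(est)
  out <- recovery_report(
    stats::setNames(list((true_num / true_den)[keep]), "ratio"),
    stats::setNames(list(est[keep]), "ratio"))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Recovery of a group difference
#'
#' Post hoc check of how well a between-group difference is recovered:
#' for each parameter, the difference of group means of posterior medians
#' is compared with the difference of group means of true values.
#'
#' @param groupA_true,groupB_true data frames of true values (datasets x
#'   parameters), >= 2 rows each.
#' @param groupA_est,groupB_est matching data frames of posterior
#'   medians.
#' @return data frame with columns `parameter, est_diff, true_diff`.
#' @export
group_difference <- function(groupA_true, groupA_est,
                             groupB_true, groupB_est) {
  groupA_true <- as.data.frame(groupA_true)
  groupB_true <- as.data.frame(groupB_true)
  groupA_est <- as.data.frame(groupA_est)
  groupB_est <- as.data.frame(groupB_est)
  stopifnot(nrow(groupA_true) >= 2, nrow(groupB_true) >= 2,
            identical(names(groupA_true), names(groupB_true)))
  data.frame(
    parameter = names(groupA_true),
    est_diff = colMeans(groupA_est[names(groupA_true)]) -
      colMeans(groupB_est[names(groupA_true)]),
    true_diff = colMeans(groupA_true) - colMeans(groupB_true),
    row.names = NULL)
}

#' Export recovery reports as tidy CSV
#'
#' One row per scenario x parameter x statistic, ready for plotting
#' (true-vs-estimate scatter, RMSD against error rate, correlation
#' boxplots).
#'
#' @param reports named list of `recovery_report`s (names = scenario
#'   labels).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recovery_csv <- function(reports, path) {
  long <- do.call(rbind, lapply(names(reports), function(sc) {
    r <- as.data.frame(reports[[sc]])
    stats_long <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
      data.frame(scenario = sc, parameter = r$parameter[i],
                 statistic = c("r", "rmsd", "adev_q2.5", "adev_q97.5"),
                 value = as.numeric(r[i, c("r", "rmsd", "adev_q2.5",
                                           "adev_q97.5")]))
    }))
    stats_long
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
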
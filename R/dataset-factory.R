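#' Study design for targeted dataset generation
#'
#' Encodes the three simulation designs: Study 1 (single stimulus
#' condition at one target error rate), Study 2 (easy/medium/difficult
#' conditions at target -/+ 2.5%), and Study 3 (accuracy/speed
#' instruction conditions at target -/+ 2.5%).  Trials are split equally
#' across conditions.  The error-rate acceptance margin is 1% around the
#' target for Study 1 and 2% on the sum of absolute per-condition
#' deviations for Studies 2 and 3.
#'
#' @param study 1, 2, or 3.
#' @param model `"ddm"` or `"lba"`.
#' @param error_rate scenario target error rate in `[0, 0.5]`.  Study 1
#'   scenarios used 0, 1, 5, 7.5, 10, 12.5, 15, 25, 35 and 50%;
#'   Studies 2 and 3 used 5, 25 and 45%.
#' @param n_trials total trials per dataset (divisible by the number of
#'   conditions); defaults 150 (Studies 1-2) / 200 (Study 3), with 1200
#'   as the large-trial variant.
#' @param n_datasets number of datasets per cell.
#' @param drift_bounds for Studies 2-3: numeric `c(lower, upper)` bounds
#'   for uniform drift sampling (see [drift_bounds_from_quantiles()]).
#' @param rt_pooled evaluate the RT inclusion criteria on the pooled
#'   dataset (default) or per condition.
#' @return an object of class `study_design`.
#' @export
study_design <- function(study, model = c("ddm", "lba"), error_rate,
                         n_trials = if (study == 3) 200 else 150,
                         n_datasets = 100, drift_bounds = NULL,
                         rt_pooled = TRUE) {
  model <- match.arg(model)
  stopifnot(study %in% 1:3, error_rate >= 0, error_rate <= 0.5)
  conditions <- switch(as.character(study),
    "1" = data.frame(condition = "stimulus", target = error_rate),
    "2" = data.frame(condition = c("easy", "medium", "difficult"),
                     target = error_rate + c(-0.025, 0, 0.025)),
    "3" = data.frame(condition = c("accuracy", "speed"),
                     target = error_rate + c(-0.025, 0.025)))
  if (any(conditions$target < 0 | conditions$target > 1))
    stop("per-condition target error rates must lie in [0, 1]",
         call. = FALSE)
  if (n_trials %% nrow(conditions) != 0)
    stop("'n_trials' must be divisible by the number of conditions",
         call. = FALSE)
  if (study %in% 2:3 && !is.null(drift_bounds))
    stopifnot(length(drift_bounds) == 2, drift_bounds[1] <= drift_bounds[2])
  structure(list(study = study, model = model, error_rate = error_rate,
                 conditions = conditions,
                 n_per_condition = n_trials / nrow(conditions),
                 n_trials = n_trials, n_datasets = n_datasets,
                 margin = if (study == 1) 0.01 else 0.02,
                 drift_bounds = drift_bounds, rt_pooled = rt_pooled),
            class = "study_design")
}

#' Inclusion criteria for a generated dataset
#'
#' Evaluates the acceptance criteria for a candidate dataset:
#' \itemize{
#'   \item error-rate margin: Study 1, absolute deviation from the target
#'     at most 1% (boundaries inclusive); Studies 2-3, sum over conditions
#'     of absolute deviations at most 2%;
#'   \item RT-distribution criteria (seconds): `0.4 <= mean <= 2.5`,
#'     `0.4 <= median <= 2.5`, `0.1 <= IQR <= 2`, `max >= 1.5`,
#'     `min <= 0.5`;
#'   \item slow-error constraint on the generating parameters
#'     (`s_v > s_z` for the DDM, `s_v_true > s_v_false` for the LBA),
#'     checked from provenance when available.
#' }
#' RT criteria are evaluated on the pooled dataset by default
#' (configurable via the design).
#'
#' @param dataset a `choice_rt_dataset`.
#' @param design a [study_design()].
#' @return an `inclusion_report`: named logical criteria plus an
#'   `accepted` flag that is true iff all criteria pass.
#' @export
check_inclusion <- function(dataset, design) {
  stopifnot(is.data.frame(dataset), inherits(design, "study_design"),
            nrow(dataset) > 0)
  emp <- vapply(design$conditions$condition, function(cond) {
    mean(dataset$response[dataset$condition == cond] == "error")
  }, numeric(1))
  dev <- abs(emp - design$conditions$target)
  # boundaries inclusive; small epsilon absorbs binary-fraction rounding
  error_rate_ok <- if (design$study == 1) dev[1] <= design$margin + 1e-9
                   else sum(dev) <= design$margin + 1e-9
  rt_crit <- function(rt) {
    q <- eam_quantile(rt, c(0.25, 0.5, 0.75))
    c(rt_mean = mean(rt) >= 0.4 && mean(rt) <= 2.5,
      rt_median = q[2] >= 0.4 && q[2] <= 2.5,
      rt_iqr = (q[3] - q[1]) >= 0.1 && (q[3] - q[1]) <= 2,
      rt_max = max(rt) >= 1.5,
      rt_min = min(rt) <= 0.5)
  }
  rt_ok <- if (isTRUE(design$rt_pooled)) rt_crit(dataset$rt) else {
    per <- vapply(design$conditions$condition, function(cond)
      rt_crit(dataset$rt[dataset$condition == cond]), logical(5))
    apply(per, 1, all)
  }
  slow_ok <- TRUE
  prov <- attr(dataset, "params")
  if (!is.null(prov)) {
    ps <- if (inherits(prov, "ddm_params") || inherits(prov, "lba_params"))
      list(prov) else prov
    slow_ok <- all(vapply(ps, function(p) {
      if (inherits(p, "ddm_params")) p$s_v > p$s_z
      else if (inherits(p, "lba_params")) p$s_v_true > p$s_v_false
      else TRUE
    }, logical(1)))
  }
  report <- c(error_rate = unname(error_rate_ok), rt_ok,
              slow_error = slow_ok)
  structure(list(criteria = report, empirical_error_rates = emp,
                 accepted = all(report)),
            class = "inclusion_report")
}

#' @export
print.inclusion_report <- function(x, ...) {
  cat("Inclusion report (accepted:", x$accepted, ")\n")
  print(x$criteria)
  invisible(x)
}

# Draw one candidate set of per-condition model parameters for a design.
# Returns list(params = named list per condition, draw = sampled row).
.draw_candidate <- function(design, spec, constraints) {
  model <- design$model
  from_draw <- if (model == "ddm") ddm_params_from_draw else
    lba_params_from_draw
  drift_name <- if (model == "ddm") "v" else "v_true"
  thr_name <- if (model == "ddm") "a" else "B"
  if (design$study == 1) {
    row <- sample_params(spec, constraints, 1)
    if (model == "ddm" && design$error_rate == 0.5) {
      # the empirical calibration cannot produce near-chance drift rates;
      # replace the drift with a uniform draw on (0.005, 0.05)
      row$v <- stats::runif(1, 0.005, 0.05)
    }
    params <- list(stimulus = from_draw(row[1, ]))
    return(list(params = params, rows = row))
  }
  bounds <- design$drift_bounds
  if (is.null(bounds))
    stop("Studies 2 and 3 need 'drift_bounds' in the design ",
         "(see drift_bounds_from_quantiles)", call. = FALSE)
  if (design$study == 2) {
    # one drift per difficulty, sorted so easier conditions get higher
    # drift; remaining parameters conditional on the mean new drift
    drifts <- sort(stats::runif(3, bounds[1], bounds[2]), decreasing = TRUE)
    fixed <- stats::setNames(mean(drifts), drift_name)
    base <- conditional_sample(spec, fixed, constraints, 1)
    rows <- base[rep(1, 3), ]
    rows[[drift_name]] <- drifts
    params <- stats::setNames(
      lapply(1:3, function(i) from_draw(rows[i, ])),
      design$conditions$condition)
    return(list(params = params, rows = rows))
  }
  # Study 3: accuracy-condition parameters conditional on one new drift;
  # the speed threshold is drawn conditional on all other parameters and
  # must fall below the accuracy threshold
  drift <- stats::runif(1, bounds[1], bounds[2])
  base <- conditional_sample(spec, stats::setNames(drift, drift_name),
                             constraints, 1)
  acc <- unlist(base[1, ])
  speed_thr <- sample_speed_threshold(spec, acc, thr_name)
  rows <- base[c(1, 1), ]
  rows[[thr_name]][2] <- speed_thr
  params <- stats::setNames(lapply(1:2, function(i) from_draw(rows[i, ])),
                            design$conditions$condition)
  list(params = params, rows = rows)
}

#' Generate a dataset hitting a target error rate
#'
#' Repeatedly samples data-generating parameters, simulates a dataset and
#' applies [check_inclusion()] until a candidate is accepted, up to
#' `max_replacements` rejected candidates (then a generation-failure error
#' carrying the per-criterion failure histogram).  The sampling scheme
#' depends on the study: Study 1 draws full vectors from the calibration
#' distribution (with the uniform near-zero drift fallback for the DDM
#' 50% scenario); Study 2 draws per-difficulty drifts uniformly between
#' the supplied bounds and samples the remaining parameters conditionally;
#' Study 3 additionally draws a speed-condition threshold conditional on
#' the other parameters.
#'
#' @param design a [study_design()] (for Studies 2-3 with `drift_bounds`
#'   set).
#' @param spec a [tmvn_spec()]; defaults to the model's calibration spec.
#' @param constraints a [constraint_set()]; defaults to the slow-error
#'   constraints.
#' @param seed optional integer seed.
#' @param max_replacements cap on rejected candidates.
#' @return an accepted `choice_rt_dataset` with provenance attributes.
#' @export
generate_dataset <- function(design, spec = NULL, constraints = NULL,
                             seed = NULL, max_replacements = 100000) {
  stopifnot(inherits(design, "study_design"))
  spec <- spec %||% if (design$model == "ddm") ddm_calibration_spec() else
    lba_calibration_spec()
  constraints <- constraints %||% slow_error_constraints(design$model)
  if (!is.null(seed)) set.seed(seed)
  fail_hist <- integer(0)
  bump <- function(h, keys) {
    for (k in keys) h[k] <- (if (k %in% names(h)) h[[k]] else 0L) + 1L
    h
  }
  replacements <- 0L
  repeat {
    cand <- .draw_candidate(design, spec, constraints)
    sim <- tryCatch({
      parts <- lapply(seq_len(nrow(design$conditions)), function(i) {
        cond <- design$conditions$condition[i]
        p <- cand$params[[cond]]
        if (design$model == "ddm")
          ddm_simulate(p, design$n_per_condition, condition = cond)
        else
          lba_simulate(p, design$n_per_condition, condition = cond)
      })
      d <- do.call(rbind, lapply(parts, as.data.frame))
      choice_rt_dataset(d$condition, d$response, d$rt,
                        model = design$model,
                        params = cand$params, seed = seed)
    }, error = function(e) e)
    if (inherits(sim, "error")) {
      fail_hist <- bump(fail_hist, "simulation")
    } else {
      rep_ <- check_inclusion(sim, design)
      if (rep_$accepted) {
        attr(sim, "replacements") <- replacements
        attr(sim, "generating_rows") <- cand$rows
        return(sim)
      }
      fail_hist <- bump(fail_hist,
                        names(rep_$criteria)[!rep_$criteria])
    }
    replacements <- replacements + 1L
    if (replacements >= max_replacements) {
      stop(structure(class = c("generation_failure", "error", "condition"),
                     list(message = paste0(
                       "no dataset met the inclusion criteria within ",
                       max_replacements, " replacements; failures: ",
                       paste(names(fail_hist), fail_hist, sep = "=",
                             collapse = ", ")),
                       call = sys.call(-1),
                       failure_histogram = fail_hist)))
    }
  }
}

#' Exclude DDM datasets with atypically large generating parameters
#'
#' Partitions datasets by the data-generating parameter thresholds
#' `a > 3` or `v > 5` (strict inequalities; any condition's drift counts).
#' Identity for the LBA.
#'
#' @param datasets list of `choice_rt_dataset`s.
#' @param model `"ddm"` or `"lba"`.
#' @return list with elements `kept` and `excluded`.
#' @export
apply_exclusion <- function(datasets, model = c("ddm", "lba")) {
  model <- match.arg(model)
  if (inherits(datasets, "choice_rt_dataset")) datasets <- list(datasets)
  if (model == "lba")
    return(list(kept = datasets, excluded = list()))
  flag <- vapply(datasets, function(d) {
    ps <- attr(d, "params")
    if (is.null(ps)) return(FALSE)
    if (inherits(ps, "ddm_params")) ps <- list(ps)
    any(vapply(ps, function(p) p$a > 3 || p$v > 5, logical(1)))
  }, logical(1))
  list(kept = datasets[!flag], excluded = datasets[flag])
}
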
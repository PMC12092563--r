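#' Study configuration
#'
#' Bundles everything needed to run one simulation cell end-to-end:
#' design, model, sampling distribution and prior presets, sampler
#' settings, output directory, master seed and worker count.  Per-dataset
#' seeds are a pure function of the master seed and dataset index, so
#' results are independent of the worker count and runs are resumable.
#'
#' @param study 1, 2 or 3.
#' @param model `"ddm"` or `"lba"`.
#' @param error_rate scenario target error rate.
#' @param n_trials trials per dataset.
#' @param n_datasets datasets in the cell.
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param drift_bounds for Studies 2-3: `c(lower, upper)` drift bounds
#'   from the matched Study-1 scenario.
#' @param spec,constraints optional sampling-distribution overrides.
#' @param prior optional [prior_spec()] override.
#' @param sampler_overrides named list of [sampler_settings()] overrides
#'   (e.g. `list(ess_threshold = 500)`).
#' @param sz_order DDM likelihood start-point quadrature order.
#' @param workers parallel workers at the dataset level.
#' @return an object of class `study_config`.
#' @export
study_config <- function(study, model, error_rate, n_trials,
                         n_datasets, out_dir, seed = 1L,
                         drift_bounds = NULL, spec = NULL,
                         constraints = NULL, prior = NULL,
                         sampler_overrides = list(), sz_order = 16,
                         workers = 1L) {
  design <- study_design(study, model, error_rate, n_trials, n_datasets,
                         drift_bounds = drift_bounds)
  stopifnot(n_datasets >= 1, workers >= 1)
  structure(list(design = design, model = design$model,
                 error_rate = error_rate, n_datasets = n_datasets,
                 out_dir = out_dir, seed = as.integer(seed),
                 spec = spec, constraints = constraints, prior = prior,
                 sampler_overrides = sampler_overrides,
                 sz_order = sz_order,
                 workers = as.integer(workers)),
            class = "study_config")
}

.cell_label <- function(config) {
  sprintf("study%d_%s_err%s_n%d", config$design$study, config$model,
          format(config$error_rate * 100), config$design$n_trials)
}

.fit_settings <- function(config, k) {
  args <- c(list(k = k), config$sampler_overrides)
  do.call(sampler_settings, args)
}

# True values of the fit-layout parameters from generation provenance.
.true_fit_values <- function(dataset, model, design) {
  ps <- attr(dataset, "params")
  conds <- design$conditions$condition
  out <- list()
  if (model == "ddm") {
    p1 <- ps[[1]]
    out$z_rel <- p1$z / p1$a
    out$s_v <- p1$s_v; out$s_z <- p1$s_z; out$t0 <- p1$t0
    if (design$study == 3) {
      for (cond in conds) out[[paste0("a.", cond)]] <- ps[[cond]]$a
      out$v <- p1$v
    } else {
      out$a <- p1$a
      if (design$study == 2) {
        for (cond in conds) out[[paste0("v.", cond)]] <- ps[[cond]]$v
      } else out$v <- p1$v
    }
  } else {
    p1 <- ps[[1]]
    out$A <- p1$A; out$s_v_true <- p1$s_v_true; out$t0 <- p1$t0
    if (design$study == 3) {
      for (cond in conds) out[[paste0("B.", cond)]] <- ps[[cond]]$B
      out$v_true <- p1$v_true; out$v_false <- p1$v_false
    } else {
      out$B <- p1$B
      if (design$study == 2) {
        for (cond in conds) {
          out[[paste0("v_true.", cond)]] <- ps[[cond]]$v_true
          out[[paste0("v_false.", cond)]] <- ps[[cond]]$v_false
        }
      } else { out$v_true <- p1$v_true; out$v_false <- p1$v_false }
    }
  }
  unlist(out)
}

#' Run a simulation cell end-to-end
#'
#' Executes generate -> (exclusion for the DDM) -> fit -> recover for one
#' study cell, with per-dataset provenance, a JSON manifest, and
#' idempotent resumption: datasets and fits already recorded in the
#' manifest are not recomputed.  Any per-dataset stage failure is
#' recorded in the manifest's failure ledger; the study completes rather
#' than aborting.
#'
#' Outputs under `out_dir`: `datasets/<id>.csv` (+ provenance JSON),
#' `fits/<id>_summary.csv` and `fits/<id>.rds`, `report_recovery.csv`,
#' `report_tradeoff.csv`, `manifest.json`.
#'
#' @param config a [study_config()].
#' @param verbose print per-stage progress and timing.
#' @return the study manifest (list), invisibly.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  out <- config$out_dir
  dir.create(file.path(out, "datasets"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out, "fits"), recursive = TRUE,
             showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    list(cell = .cell_label(config), seed = config$seed,
         datasets = list(), failures = list())
  }
  design <- config$design
  model <- config$model

  one_dataset <- function(i) {
    id <- sprintf("%s_d%03d", .cell_label(config), i)
    entry <- manifest$datasets[[id]]
    ds_path <- file.path(out, "datasets", paste0(id, ".csv"))
    fit_path <- file.path(out, "fits", paste0(id, ".rds"))
    if (!is.null(entry) && isTRUE(entry$complete) &&
        file.exists(ds_path) && file.exists(fit_path)) {
      return(list(id = id, entry = entry, fit = readRDS(fit_path),
                  dataset = read_choice_rt_csv(ds_path), reused = TRUE))
    }
    seed_i <- derive_seed(config$seed, i)
    t_gen <- system.time(
      ds <- tryCatch(generate_dataset(design, config$spec,
                                      config$constraints, seed = seed_i),
                     error = function(e) e))[["elapsed"]]
    if (inherits(ds, "error"))
      return(list(id = id, error = paste("generate:",
                                         conditionMessage(ds))))
    excluded <- FALSE
    if (model == "ddm") {
      part <- apply_exclusion(list(ds), "ddm")
      excluded <- length(part$excluded) == 1
    }
    if (excluded) {
      write_choice_rt_csv(ds, ds_path, dataset_id = id)
      return(list(id = id,
                  entry = list(complete = FALSE, excluded = TRUE,
                               seed = seed_i,
                               replacements = attr(ds, "replacements"),
                               t_generate = t_gen),
                  dataset = ds))
    }
    k <- length(.fit_par_names(model, design))
    t_fit <- system.time(
      fit <- tryCatch(
        suppressWarnings(run_until_converged(
          ds, model, design, prior = config$prior,
          settings = .fit_settings(config, k),
          sz_order = config$sz_order)),
        error = function(e) e))[["elapsed"]]
    if (inherits(fit, "error"))
      return(list(id = id, error = paste("fit:", conditionMessage(fit))))
    write_choice_rt_csv(ds, ds_path, dataset_id = id)
    saveRDS(fit, fit_path)
    write_posterior_csv(fit, summary_path = file.path(
      out, "fits", paste0(id, "_summary.csv")))
    list(id = id,
         entry = list(complete = TRUE, excluded = FALSE, seed = seed_i,
                      converged = fit$converged,
                      replacements = attr(ds, "replacements"),
                      t_generate = t_gen, t_fit = t_fit),
         fit = fit, dataset = ds)
  }

  idx <- seq_len(config$n_datasets)
  results <- if (config$workers > 1) {
    parallel::mclapply(idx, one_dataset, mc.cores = config$workers)
  } else {
    lapply(idx, one_dataset)
  }

  fits <- list(); truths <- list()
  for (res in results) {
    if (!is.null(res$error)) {
      manifest$failures[[res$id]] <- res$error
      next
    }
    manifest$datasets[[res$id]] <- res$entry
    if (isTRUE(res$entry$complete)) {
      fits[[res$id]] <- res$fit
      truths[[res$id]] <- .true_fit_values(res$dataset, model, design)
    }
    if (verbose)
      message(res$id, if (isTRUE(res$entry$excluded)) " [excluded]"
              else sprintf(" gen %.1fs fit %.1fs conv=%s",
                           res$entry$t_generate %||% NA,
                           res$entry$t_fit %||% NA,
                           res$entry$converged %||% NA))
  }

  report <- NULL
  if (length(fits) >= 2) {
    est <- as.data.frame(do.call(rbind, lapply(fits, function(f)
      point_estimates(f, warn_unconverged = FALSE))))
    tru <- as.data.frame(do.call(rbind, truths))
    common <- intersect(names(tru), names(est))
    report <- recovery_report(tru[common], est[common])
    num <- if (model == "ddm") "v" else "v_true"
    den <- if (model == "ddm") "a" else "B"
    if (all(c(num, den) %in% common)) {
      ratio <- ratio_recovery(tru[[num]], tru[[den]], fits, num, den)
      ratio$parameter <- paste0(num, "/", den)
      report <- structure(rbind(as.data.frame(report),
                                as.data.frame(ratio)),
                          truth = attr(report, "truth"),
                          estimates = attr(report, "estimates"),
                          class = class(report))
    }
    write_recovery_csv(stats::setNames(list(report), .cell_label(config)),
                       file.path(out, "report_recovery.csv"))
    tr <- lapply(fits, posterior_pairwise)
    pairs_long <- do.call(rbind, lapply(names(tr), function(id) {
      pm <- tr[[id]]$pearson; pp <- tr[[id]]$partial
      ut <- which(upper.tri(pm), arr.ind = TRUE)
      data.frame(dataset_id = id,
                 par1 = rownames(pm)[ut[, 1]], par2 = colnames(pm)[ut[, 2]],
                 pearson = pm[ut], partial = pp[ut])
    }))
    utils::write.csv(pairs_long, file.path(out, "report_tradeoff.csv"),
                     row.names = FALSE)
  }

  manifest$n_complete <- sum(vapply(manifest$datasets, function(e)
    isTRUE(e$complete), logical(1)))
  manifest$n_excluded <- sum(vapply(manifest$datasets, function(e)
    isTRUE(e$excluded), logical(1)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(manifest = manifest, report = report, fits = fits))
}
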
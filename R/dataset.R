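#' Choice-RT dataset container
#'
#' A data frame of two-alternative choice trials with columns `condition`
#' (label), `response` (`"correct"` or `"error"`) and `rt` (seconds),
#' carrying generation provenance (model, generating parameters, seed,
#' replacement count) as attributes.  Stimulus identity is collapsed into
#' correct/error coding, matching the response mapping used for
#' estimation.
#'
#' @param condition character vector of condition labels.
#' @param response character vector, `"correct"` or `"error"`.
#' @param rt numeric vector of response times in seconds (> 0).
#' @param model generating model label (`"ddm"`, `"lba"`, or `NA`).
#' @param params generating parameters (kept as provenance).
#' @param seed generating seed.
#' @param replacements number of rejected candidates before acceptance.
#' @return object of class `choice_rt_dataset` (a data frame).
#' @export
choice_rt_dataset <- function(condition, response, rt, model = NA_character_,
                              params = NULL, seed = NULL, replacements = 0L) {
  stopifnot(length(condition) == length(response),
            length(response) == length(rt),
            all(response %in% c("correct", "error")),
            all(rt > 0))
  structure(
    data.frame(condition = as.character(condition),
               response = as.character(response),
               rt = as.numeric(rt),
               stringsAsFactors = FALSE),
    model = model, params = params, seed = seed,
    replacements = replacements,
    class = c("choice_rt_dataset", "data.frame")
  )
}

#' Empirical error rates of a dataset
#'
#' @param data a `choice_rt_dataset`.
#' @param by_condition if `TRUE`, a named vector per condition; otherwise
#'   the pooled error rate.
#' @return numeric vector of error proportions.
#' @export
error_rates <- function(data, by_condition = FALSE) {
  err <- data$response == "error"
  if (!by_condition) return(mean(err))
  tapply(err, data$condition, mean)
}

#' Write / read choice-RT datasets as CSV
#'
#' Datasets are serialized with header `dataset_id,condition,response,rt`;
#' provenance (generating parameters, model, seed, replacement count) goes
#' to a JSON sidecar `<path>.provenance.json`.
#'
#' @param data a `choice_rt_dataset` or a list of them.
#' @param path output CSV path.
#' @param dataset_id id column value(s); defaults to list names or index.
#' @return `path`, invisibly.
#' @export
write_choice_rt_csv <- function(data, path, dataset_id = NULL) {
  if (inherits(data, "choice_rt_dataset")) data <- list(data)
  ids <- dataset_id %||% (names(data) %||% as.character(seq_along(data)))
  rows <- do.call(rbind, lapply(seq_along(data), function(i) {
    cbind(dataset_id = ids[[i]], as.data.frame(data[[i]]))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  prov <- lapply(seq_along(data), function(i) {
    d <- data[[i]]
    list(dataset_id = ids[[i]],
         model = attr(d, "model"),
         seed = attr(d, "seed"),
         replacements = attr(d, "replacements"),
         params = .params_to_list(attr(d, "params")))
  })
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_choice_rt_csv
#' @export
read_choice_rt_csv <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  prov_path <- paste0(path, ".provenance.json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path) else NULL
  out <- lapply(split(rows, rows$dataset_id), function(d) {
    p <- NULL
    if (!is.null(prov)) {
      hit <- Filter(function(x) identical(as.character(x$dataset_id),
                                          as.character(d$dataset_id[1])), prov)
      if (length(hit)) p <- hit[[1]]
    }
    choice_rt_dataset(d$condition, d$response, d$rt,
                      model = p$model %||% NA_character_,
                      params = .params_from_list(p$params, p$model),
                      seed = p$seed,
                      replacements = p$replacements %||% 0L)
  })
  if (length(out) == 1) out[[1]] else out
}

.params_to_list <- function(params) {
  if (is.null(params)) return(NULL)
  if (inherits(params, "ddm_params") || inherits(params, "lba_params"))
    return(unclass(params))
  lapply(params, .params_to_list)
}

.params_from_list <- function(x, model) {
  if (is.null(x)) return(NULL)
  build <- function(el) {
    el <- lapply(el, as.numeric)
    if (identical(model, "ddm"))
      ddm_params(a = el$a, v = el$v, z = el$z, s_v = el$s_v, s_z = el$s_z,
                 t0 = el$t0)
    else if (identical(model, "lba"))
      lba_params(A = el$A, B = el$B, v_true = el$v_true,
                 v_false = el$v_false, s_v_true = el$s_v_true, t0 = el$t0)
    else el
  }
  if (!is.null(x[[1]]) && is.list(x[[1]])) lapply(x, build) else build(x)
}

#' JSON round-trip of model parameter sets
#'
#' DDM parameter sets serialize with field names `a, v, z, s_v, s_z, t0`;
#' LBA sets with `A, B, v_true, v_false, s_v_true, t0`.
#'
#' @param params a `ddm_params` or `lba_params` object.
#' @param path optional file; if omitted the JSON string is returned.
#' @return JSON string (or `path` invisibly).
#' @export
params_to_json <- function(params, path = NULL) {
  keep <- if (inherits(params, "ddm_params")) {
    c("a", "v", "z", "s_v", "s_z", "t0")
  } else if (inherits(params, "lba_params")) {
    c("A", "B", "v_true", "v_false", "s_v_true", "t0")
  } else stop("unsupported parameter class", call. = FALSE)
  x <- unclass(params)[keep]
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname params_to_json
#' @param json JSON string or file path.
#' @param model `"ddm"` or `"lba"`.
#' @export
params_from_json <- function(json, model = c("ddm", "lba")) {
  model <- match.arg(model)
  x <- jsonlite::fromJSON(json)
  .params_from_list(x, model)
}
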
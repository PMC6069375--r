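#' Read / write signal matrices as CSV
#'
#' Signal matrices are stored as plain numeric CSV, rows = channels,
#' columns = samples, no header. A JSON sidecar (`<path>.json`), when
#' present, supplies `sampling_rate` and grid geometry; otherwise defaults
#' apply. Non-numeric or missing cells raise a parse error naming the cell.
#'
#' @param path CSV file path.
#' @param sampling_rate Fallback sampling rate when no sidecar exists.
#' @return `read_signal_csv()`: channels x samples numeric matrix with
#'   attributes `sampling_rate` and (if sidecar present) `grid`.
#' @export
read_signal_csv <- function(path, sampling_rate = 1000) {
  if (!file.exists(path)) stop_invalid(sprintf("file '%s' does not exist.", path))
  df <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "numeric"),
    error = function(e) {
      rlang::abort(sprintf("failed to parse '%s': %s", path, conditionMessage(e)),
                   class = "fosemg_parse_error")
    },
    warning = function(w) {
      rlang::abort(sprintf("failed to parse '%s': %s", path, conditionMessage(w)),
                   class = "fosemg_parse_error")
    }
  )
  m <- as.matrix(df)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rlang::abort(sprintf("non-finite value at row %d, column %d of '%s'.",
                         bad[1, 1], bad[1, 2], path),
                 class = "fosemg_parse_error")
  }
  dimnames(m) <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$sampling_rate)) sampling_rate <- meta$sampling_rate
    if (!is.null(meta$grid)) {
      attr(m, "grid") <- grid_spec(meta$grid$n_rows, meta$grid$n_cols,
                                   meta$grid$inter_electrode_distance %||% 10)
    }
  }
  attr(m, "sampling_rate") <- sampling_rate
  m
}

#' @rdname read_signal_csv
#' @param s Channels x samples numeric matrix.
#' @param grid Optional [grid_spec()] recorded in the JSON sidecar.
#' @export
write_signal_csv <- function(s, path, sampling_rate = NULL, grid = NULL) {
  sr <- sampling_rate %||% attr(s, "sampling_rate") %||% 1000
  utils::write.table(format(s, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(sampling_rate = sr)
  if (!is.null(grid)) meta$grid <- unclass(grid)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

MODEL_SCHEMA_VERSION <- 1L

#' Serialize / restore a fitted FOS model as JSON
#'
#' The JSON holds the selected basis names, coefficients `a` and `g`, the
#' Gram-Schmidt coefficients `alpha`, and the training RMSD path at full
#' floating-point precision, so predictions from a reloaded model match the
#' original bit for bit.
#'
#' @param model A fitted `fos_model`.
#' @param path JSON file path.
#' @return `read_model_json()`: the restored `fos_model`.
#' @export
write_model_json <- function(model, path) {
  if (!inherits(model, "fos_model")) stop_invalid("model must be a fos_model.")
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    pool_kind = model$pool_kind,
    selected = model$selected,
    a = model$a, g = model$g,
    alpha = model$alpha,
    training_rmsd_path = model$training_rmsd_path,
    n_samples = model$n_samples,
    max_functions = model$max_functions,
    rmsd_reduction_threshold = model$rmsd_reduction_threshold,
    diagnostics = model$diagnostics
  )
  # 17 significant digits: lossless decimal round trip for IEEE doubles
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       always_decimal = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    rlang::abort(sprintf("failed to parse model file '%s': %s",
                                         path, conditionMessage(e)),
                                 class = "fosemg_parse_error")
                  })
  if (is.null(obj$schema_version) || obj$schema_version != MODEL_SCHEMA_VERSION) {
    rlang::abort(sprintf("model schema version %s not supported (expected %d).",
                         obj$schema_version %||% "<missing>", MODEL_SCHEMA_VERSION),
                 class = "fosemg_version_error")
  }
  M <- length(obj$selected)
  alpha <- matrix(as.numeric(unlist(obj$alpha)), M, M)
  structure(
    list(selected = as.character(obj$selected), pool_kind = obj$pool_kind,
         g = as.numeric(obj$g), a = as.numeric(obj$a), alpha = alpha,
         training_rmsd_path = as.numeric(obj$training_rmsd_path),
         fitted = NULL, residual_mse = NULL,
         n_samples = obj$n_samples, max_functions = obj$max_functions,
         rmsd_reduction_threshold = obj$rmsd_reduction_threshold,
         diagnostics = obj$diagnostics),
    class = "fos_model"
  )
}

#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run. The configuration round-trips
#' losslessly through JSON, and `rlang::hash()` of the canonical list is
#' recorded with every artifact so re-runs are verifiable.
#'
#' @param method Processing method: `"avg"`, `"pca"`, `"ica"` or `"nmf"`.
#' @param seed Top-level seed driving every stochastic stage.
#' @param sampling_rate Hz.
#' @param cutoff,order Envelope filter settings.
#' @param n_agonist,n_antagonist Component counts per muscle.
#' @param max_functions,rmsd_reduction_threshold FOS settings.
#' @param target_level,n_repetitions Protocol settings for simulated runs.
#' @return A `run_config` list.
#' @export
run_config <- function(method = "nmf", seed = 1, sampling_rate = 1000,
                       cutoff = 5, order = 50, n_agonist = 2, n_antagonist = 3,
                       max_functions = 7, rmsd_reduction_threshold = 0.2,
                       target_level = 0.4, n_repetitions = 7) {
  if (!method %in% c("avg", "pca", "ica", "nmf")) {
    stop_invalid("method must be one of avg, pca, ica, nmf.")
  }
  num <- c(seed = seed, sampling_rate = sampling_rate, cutoff = cutoff,
           order = order, n_agonist = n_agonist, n_antagonist = n_antagonist,
           max_functions = max_functions,
           rmsd_reduction_threshold = rmsd_reduction_threshold,
           target_level = target_level, n_repetitions = n_repetitions)
  if (any(num <= 0)) stop_invalid("all numeric config fields must be positive.")
  structure(list(method = method, seed = seed, sampling_rate = sampling_rate,
                 cutoff = cutoff, order = order, n_agonist = n_agonist,
                 n_antagonist = n_antagonist, max_functions = max_functions,
                 rmsd_reduction_threshold = rmsd_reduction_threshold,
                 target_level = target_level, n_repetitions = n_repetitions),
            class = "run_config")
}

#' Run the full estimation pipeline on one trial set
#'
#' Preprocess, factorize, build activation signals, fit FOS models and
#' cross-validate, for one simulated (or externally loaded) trial set.
#' Deterministic given the configuration.
#'
#' @param config A [run_config()].
#' @param trials Optional `trial_set`; when `NULL`, one is simulated from
#'   the config's protocol settings and seed.
#' @return List with `folds`, `summary`, `config`, and `config_hash`.
#' @export
run_pipeline <- function(config, trials = NULL) {
  if (!inherits(config, "run_config")) stop_invalid("config must be a run_config.")
  protocol <- protocol_spec(sampling_rate = config$sampling_rate,
                            target_level = config$target_level,
                            n_repetitions = config$n_repetitions)
  if (is.null(trials)) {
    trials <- simulate_trial_set(protocol = protocol, seed = config$seed)
  }
  reps <- extract_activation_trials(trials, method = config$method,
                                    n_agonist = config$n_agonist,
                                    n_antagonist = config$n_antagonist,
                                    seed = config$seed)
  folds <- crossval(reps, config$max_functions, config$rmsd_reduction_threshold)
  list(folds = folds, summary = summarize_crossval(folds),
       config = config, config_hash = rlang::hash(unclass(config)))
}

#' Write a simulated trial set to a directory
#'
#' One CSV per grid per repetition (`agonist_rep<k>.csv`,
#' `antagonist_rep<k>.csv`), a one-column force CSV per repetition, and a
#' JSON sidecar with the protocol, grid and ground-truth patterns.
#'
#' @param trials A `trial_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_set <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- trials$protocol$sampling_rate
  for (r in seq_along(trials$repetitions)) {
    rep <- trials$repetitions[[r]]
    write_signal_csv(rep$agonist, file.path(dir, sprintf("agonist_rep%d.csv", r)),
                     sampling_rate = fs, grid = trials$grid)
    write_signal_csv(rep$antagonist, file.path(dir, sprintf("antagonist_rep%d.csv", r)),
                     sampling_rate = fs, grid = trials$grid)
    utils::write.table(rep$force, file.path(dir, sprintf("force_rep%d.csv", r)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(protocol = unclass(trials$protocol), grid = unclass(trials$grid),
               patterns_agonist = trials$truth$patterns_agonist,
               patterns_antagonist = trials$truth$patterns_antagonist)
  jsonlite::write_json(meta, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
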
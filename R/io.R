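#' Write a synergy dataset to disk
#'
#' Each trial is written as one delimited-text file (columns = muscles, with
#' a header of muscle names), alongside a JSON manifest listing participants,
#' tasks, trials, file paths, sampling rate and phase events. When the
#' dataset carries ground truth, its design (pool synergy vectors,
#' per-participant weights, shared map, noise parameters, seed) is
#' serialised to `ground_truth.json`.
#'
#' @param dataset a `"synergy_dataset"` (or a bare list of raw trials).
#' @param dir output directory, created if needed.
#' @param sep field separator for the signal files.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir, sep = ",") {
  trials <- if (inherits(dataset, "synergy_dataset")) dataset$trials else dataset
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    fname <- sprintf("%s_%s_trial%02d.csv", tr$participant_id, tr$task_id,
                     tr$trial_id)
    df <- as.data.frame(t(tr$signals))
    names(df) <- tr$muscle_names
    write.csv(df, file.path(dir, fname), row.names = FALSE)
    entries[[i]] <- list(
      participant = tr$participant_id, task = tr$task_id,
      trial = tr$trial_id, file = fname,
      start_sample = tr$events[1], end_sample = tr$events[2]
    )
  }
  manifest <- list(
    sampling_rate = trials[[1]]$sampling_rate,
    muscles = trials[[1]]$muscle_names,
    participants = unique(vapply(trials, `[[`, "", "participant_id")),
    tasks = unique(vapply(trials, `[[`, "", "task_id")),
    trials = entries
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (inherits(dataset, "synergy_dataset") &&
      !is.null(dataset$ground_truth)) {
    gt <- dataset$ground_truth
    gt_json <- list(
      seed = gt$seed,
      shared_map = gt$shared_map,
      W_pool = gt$W_pool,
      W_participant = gt$W_participant,
      centers_by_id = gt$centers_by_id,
      noise = list(noise_sd = gt$config$noise_sd,
                   jitter_sd = gt$config$jitter_sd,
                   participant_sd = gt$config$participant_sd,
                   amplitude_cv = gt$config$amplitude_cv),
      muscle_names = gt$muscle_names
    )
    jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(manifest_path)
}

#' Serialise a synergy decomposition to JSON
#'
#' Matrices are stored row-major with explicit shape metadata, alongside the
#' restart provenance (`restarts`, `best_restart_seed`, `converged`,
#' `iterations`) so a decomposition can be archived and reloaded exactly.
#'
#' @param decomposition a `"synergy_decomposition"`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_decomposition <- function(decomposition, path) {
  d <- decomposition
  obj <- list(
    k = d$k, tvaf = d$tvaf, restarts = d$restarts,
    best_restart_seed = d$best_restart_seed, converged = d$converged,
    iterations = d$iterations, method = d$method,
    W = list(dim = dim(d$W), data = as.numeric(t(d$W))),
    C = list(dim = dim(d$C), data = as.numeric(t(d$C)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a synergy decomposition written by [write_decomposition()]
#'
#' @param path JSON file path.
#' @return A `"synergy_decomposition"`.
#' @export
read_decomposition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(obj$W$data, nrow = obj$W$dim[1], byrow = TRUE)
  C <- matrix(obj$C$data, nrow = obj$C$dim[1], byrow = TRUE)
  structure(list(
    W = W, C = C, k = as.integer(obj$k), tvaf = obj$tvaf,
    restarts = obj$restarts, best_restart_seed = obj$best_restart_seed,
    converged = obj$converged, iterations = obj$iterations,
    residual_trace = numeric(0), dead_components = integer(0),
    method = obj$method
  ), class = "synergy_decomposition")
}

#' Read a synergy dataset from a manifest
#'
#' Reads the layout written by [write_dataset()]; the same reader serves any
#' real recordings exported to that layout (one delimited file per trial,
#' columns = muscles, plus a JSON manifest with per-trial phase events).
#'
#' @param manifest_path path to `manifest.json`.
#' @return A `"synergy_dataset"` whose `ground_truth` is `NULL`.
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  muscle_names <- manifest$muscles
  entries <- manifest$trials
  trials <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    path <- file.path(dir, e$file)
    if (!file.exists(path)) {
      stop("signal file missing: ", path, call. = FALSE)
    }
    df <- read.csv(path, check.names = FALSE)
    if (!identical(names(df), as.character(muscle_names))) {
      stop("muscle names in ", e$file, " do not match the manifest",
           call. = FALSE)
    }
    signals <- t(as.matrix(df))
    trials[[i]] <- structure(list(
      participant_id = e$participant, task_id = e$task,
      trial_id = e$trial, signals = signals,
      sampling_rate = manifest$sampling_rate,
      events = c(e$start_sample, e$end_sample),
      muscle_names = as.character(muscle_names)
    ), class = "raw_trial")
  }
  structure(list(trials = trials, ground_truth = NULL),
            class = "synergy_dataset")
}
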
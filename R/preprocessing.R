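#' EMG linear envelope
#'
#' Standard movement-science envelope chain: zero-lag 4th-order Butterworth
#' band-pass (default 10-400 Hz), demeaning, full-wave rectification, and a
#' zero-lag 4th-order Butterworth low-pass (default 6 Hz). Zero lag is
#' obtained by forward-backward application of each filter (effective order
#' 8, zero phase). Filter undershoot is clipped at zero so the envelope is
#' non-negative.
#'
#' @param x numeric vector, one raw EMG channel.
#' @param sampling_rate sampling rate in Hz (> 800).
#' @param band band-pass edges in Hz.
#' @param low_pass envelope low-pass cut-off in Hz.
#' @param order Butterworth design order (per pass).
#' @return Non-negative numeric vector, same length as `x`.
#' @export
emg_envelope <- function(x, sampling_rate, band = c(10, 400), low_pass = 6,
                         order = 4) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("raw signal contains non-finite samples", call. = FALSE)
  }
  stop_if_not_number(sampling_rate, "sampling_rate", min = 800)
  if (sampling_rate < 850) {
    warning("sampling rate below 850 Hz leaves little margin to the ",
            "band-pass upper edge", call. = FALSE)
  }
  nyq <- sampling_rate / 2
  if (band[2] >= nyq) {
    stop("band-pass upper edge must be below the Nyquist frequency",
         call. = FALSE)
  }
  # forward-backward filtering needs a stable warm-up length
  if (length(x) < 9 * order) {
    stop("signal too short for stable zero-lag filtering", call. = FALSE)
  }
  bp <- signal::butter(order, band / nyq, type = "pass")
  lp <- signal::butter(order, low_pass / nyq, type = "low")
  y <- signal::filtfilt(bp, x)
  y <- y - mean(y)
  env <- signal::filtfilt(lp, abs(y))
  pmax(env, 0)
}

#' Time-normalise a phase to a fixed number of points
#'
#' Linearly interpolates the segment between `events[1]` and `events[2]`
#' (1-based samples, inclusive) onto `points` uniformly spaced samples whose
#' endpoints coincide with the segment's endpoints.
#'
#' @param x numeric vector.
#' @param events integer pair (start, end) with `end - start >= 2`.
#' @param points output length (default 100).
#' @return Numeric vector of length `points`.
#' @export
time_normalize <- function(x, events, points = 100L) {
  if (length(events) != 2L) stop("`events` must be (start, end)", call. = FALSE)
  start <- events[1]; end <- events[2]
  if (start < 1 || end > length(x)) {
    stop("events outside signal bounds", call. = FALSE)
  }
  if (end - start < 2) stop("phase must span at least 3 samples", call. = FALSE)
  idx <- seq(start, end, length.out = points)
  approx(x = start:end, y = x[start:end], xout = idx)$y
}

#' Assemble per-task envelope matrices for one participant
#'
#' Concatenates each task's time-normalised trial envelopes along time and
#' applies the cross-task amplitude normalisation: every muscle row is
#' divided by that muscle's maximum over ALL of the participant's tasks, so
#' 1 marks the muscle's maximum activation anywhere in the session and a
#' single task's matrix may peak below 1.
#'
#' @param trial_envelopes nested list: `trial_envelopes[[task]][[trial]]` is
#'   a muscles x points matrix (identical muscle order throughout).
#' @param muscle_names character vector of muscle labels.
#' @param participant_id,task_ids identifiers carried into the result.
#' @return Named list of `"envelope_matrix"` objects, one per task, each
#'   with fields `E` (muscles x (trials * points), entries in \[0, 1\]),
#'   `muscle_names`, `trial_boundaries` (start column of each trial block)
#'   and `normalization_factors` (per-muscle divisor).
#' @export
assemble_envelopes <- function(trial_envelopes, muscle_names,
                               participant_id = "P1",
                               task_ids = NULL) {
  n_tasks <- length(trial_envelopes)
  if (n_tasks < 1L) stop("at least one task required", call. = FALSE)
  if (is.null(task_ids)) task_ids <- sprintf("T%d", seq_len(n_tasks))
  m <- length(muscle_names)

  raw_E <- vector("list", n_tasks)
  boundaries <- vector("list", n_tasks)
  for (t in seq_len(n_tasks)) {
    trs <- trial_envelopes[[t]]
    if (length(trs) < 1L) stop("every task needs at least one trial",
                               call. = FALSE)
    for (tr in trs) {
      if (nrow(tr) != m) {
        stop("muscle count mismatch across trials", call. = FALSE)
      }
    }
    pts <- ncol(trs[[1]])
    boundaries[[t]] <- seq(1L, by = pts, length.out = length(trs))
    raw_E[[t]] <- do.call(cbind, trs)
  }

  global_max <- apply(do.call(cbind, raw_E), 1, max)
  dead <- which(global_max <= 0)
  if (length(dead) > 0) {
    stop("muscle(s) with all-zero signal across all tasks: ",
         paste(muscle_names[dead], collapse = ", "), call. = FALSE)
  }

  out <- vector("list", n_tasks)
  names(out) <- task_ids
  for (t in seq_len(n_tasks)) {
    out[[t]] <- structure(list(
      participant_id = participant_id,
      task_id = task_ids[t],
      E = raw_E[[t]] / global_max,
      muscle_names = muscle_names,
      trial_boundaries = boundaries[[t]],
      normalization_factors = global_max
    ), class = "envelope_matrix")
  }
  out
}

#' Run the full preprocessing chain on a dataset
#'
#' For every trial: per-muscle envelope extraction ([emg_envelope()]), phase
#' time-normalisation to `points` samples ([time_normalize()]); then, per
#' participant, concatenation and cross-task amplitude normalisation
#' ([assemble_envelopes()]).
#'
#' @param dataset a `"synergy_dataset"` (from [generate_dataset()] or
#'   [read_dataset()]).
#' @param band,low_pass,order envelope parameters, see [emg_envelope()].
#' @param points phase length after time normalisation.
#' @return Nested named list: `result[[participant]][[task]]` is an
#'   `"envelope_matrix"`.
#' @export
process_dataset <- function(dataset, band = c(10, 400), low_pass = 6,
                            order = 4, points = 100L) {
  trials <- dataset$trials
  participants <- unique(vapply(trials, `[[`, "", "participant_id"))
  tasks <- unique(vapply(trials, `[[`, "", "task_id"))
  muscle_names <- trials[[1]]$muscle_names

  out <- vector("list", length(participants))
  names(out) <- participants
  for (p in participants) {
    per_task <- vector("list", length(tasks))
    for (ti in seq_along(tasks)) {
      trs <- Filter(function(tr) tr$participant_id == p &&
                      tr$task_id == tasks[ti], trials)
      trs <- trs[order(vapply(trs, `[[`, 0, "trial_id"))]
      per_task[[ti]] <- lapply(trs, function(tr) {
        env <- t(apply(tr$signals, 1, emg_envelope,
                       sampling_rate = tr$sampling_rate, band = band,
                       low_pass = low_pass, order = order))
        t(apply(env, 1, time_normalize, events = tr$events, points = points))
      })
    }
    out[[p]] <- assemble_envelopes(per_task, muscle_names,
                                   participant_id = p, task_ids = tasks)
  }
  out
}
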
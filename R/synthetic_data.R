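#' Configuration for the synthetic EMG generator
#'
#' Describes a synthetic multi-participant, multi-task EMG study with known
#' synergy structure. Defaults emulate the reference study design: 7
#' participants x 3 tasks x 6 trials, 16 muscles sampled at 1000 Hz, a
#' takeoff-like phase between samples 200 and 700 that is later
#' time-normalised to 100 points, 4 synergies per task of which one is
#' shared across all tasks.
#'
#' Each synergy is a non-negative muscle-weight vector (column maximum 1)
#' recruited by a Gaussian activation burst on the 100-point phase. Shared
#' synergies reuse the same weight vector (up to a per-participant
#' perturbation that is itself shared across tasks) in several tasks; the
#' shared synergy's burst sits in the first third of the phase, mimicking a
#' propulsive "jump" module. Raw signals are band-limited (20-380 Hz) white
#' carriers amplitude-modulated by the envelope, so the preprocessing chain
#' (band-pass, rectify, low-pass) has realistic work to do.
#'
#' @param participants,tasks,trials_per_task,muscles study dimensions.
#' @param k_per_task number of true synergies in every task.
#' @param n_shared_all how many synergies are shared across all tasks.
#' @param shared_map optional integer matrix (tasks x k_per_task) of synergy
#'   pool identifiers; equal identifiers across tasks mean a shared synergy.
#'   Overrides `n_shared_all`.
#' @param noise_sd envelope noise SD as a fraction of each muscle's peak
#'   envelope (0 = noiseless).
#' @param jitter_sd SD of the per-trial burst-centre jitter, in phase points
#'   (percent of the phase).
#' @param participant_sd SD of the log-normal per-participant perturbation of
#'   synergy weights (0 = identical participants).
#' @param amplitude_cv coefficient of variation of per-trial burst amplitudes.
#' @param sampling_rate,n_samples raw-signal sampling rate (Hz) and length.
#' @param events two samples (start, end) delimiting the analysed phase.
#' @param baseline_sd baseline carrier amplitude outside the phase, as a
#'   fraction of the muscle's peak envelope.
#' @param burst_width Gaussian burst SD in phase points.
#' @param points_per_phase number of points of the time-normalised phase.
#' @return A validated configuration list of class `"synergy_sim_config"`.
#' @export
synthetic_config <- function(participants = 7L, tasks = 3L,
                             trials_per_task = 6L, muscles = 16L,
                             k_per_task = 4L, n_shared_all = 1L,
                             shared_map = NULL,
                             noise_sd = 0.05, jitter_sd = 2,
                             participant_sd = 0.25, amplitude_cv = 0.1,
                             sampling_rate = 1000, n_samples = 1000L,
                             events = c(200L, 700L), baseline_sd = 0.01,
                             burst_width = 7, points_per_phase = 100L) {
  participants <- stop_if_not_count(participants, "participants")
  tasks <- stop_if_not_count(tasks, "tasks")
  trials_per_task <- stop_if_not_count(trials_per_task, "trials_per_task")
  muscles <- stop_if_not_count(muscles, "muscles", min = 2L)
  k_per_task <- stop_if_not_count(k_per_task, "k_per_task")
  if (k_per_task >= muscles) {
    stop("`k_per_task` must be smaller than `muscles`", call. = FALSE)
  }
  stop_if_not_number(noise_sd, "noise_sd", min = 0)
  stop_if_not_number(jitter_sd, "jitter_sd", min = 0)
  stop_if_not_number(participant_sd, "participant_sd", min = 0)
  stop_if_not_number(amplitude_cv, "amplitude_cv", min = 0)
  stop_if_not_number(sampling_rate, "sampling_rate", min = 1)
  n_samples <- stop_if_not_count(n_samples, "n_samples", min = 10L)
  points_per_phase <- stop_if_not_count(points_per_phase, "points_per_phase",
                                        min = 2L)
  if (length(events) != 2L || events[1] < 1L || events[2] <= events[1] ||
      events[2] > n_samples) {
    stop("`events` must satisfy 1 <= start < end <= n_samples", call. = FALSE)
  }

  if (is.null(shared_map)) {
    n_shared_all <- stop_if_not_count(n_shared_all, "n_shared_all", min = 0L)
    if (n_shared_all > k_per_task) {
      stop("`n_shared_all` cannot exceed `k_per_task`", call. = FALSE)
    }
    shared_map <- matrix(0L, nrow = tasks, ncol = k_per_task)
    if (n_shared_all > 0L) {
      shared_map[, seq_len(n_shared_all)] <-
        matrix(seq_len(n_shared_all), nrow = tasks, ncol = n_shared_all,
               byrow = TRUE)
    }
    next_id <- n_shared_all
    for (t in seq_len(tasks)) {
      n_specific <- k_per_task - n_shared_all
      if (n_specific > 0L) {
        shared_map[t, (n_shared_all + 1L):k_per_task] <-
          next_id + seq_len(n_specific)
        next_id <- next_id + n_specific
      }
    }
  } else {
    shared_map <- as.matrix(shared_map)
    if (!is.numeric(shared_map) || nrow(shared_map) != tasks ||
        ncol(shared_map) != k_per_task) {
      stop("`shared_map` must be a tasks x k_per_task integer matrix",
           call. = FALSE)
    }
    ids <- as.integer(shared_map)
    if (any(ids < 1L) || !setequal(ids, seq_len(max(ids))) ||
        any(apply(shared_map, 1, anyDuplicated) > 0)) {
      stop("`shared_map` identifiers must be 1..max without gaps and unique within a task",
           call. = FALSE)
    }
    storage.mode(shared_map) <- "integer"
  }

  structure(list(
    participants = participants, tasks = tasks,
    trials_per_task = trials_per_task, muscles = muscles,
    k_per_task = k_per_task, shared_map = shared_map,
    noise_sd = noise_sd, jitter_sd = jitter_sd,
    participant_sd = participant_sd, amplitude_cv = amplitude_cv,
    sampling_rate = sampling_rate, n_samples = n_samples,
    events = as.integer(events), baseline_sd = baseline_sd,
    burst_width = burst_width, points_per_phase = points_per_phase
  ), class = "synergy_sim_config")
}

#' Default muscle labels
#'
#' For 16 channels, the standard bilateral lower-limb montage (front and back
#' leg): vastus lateralis, semitendinosus, gastrocnemius lateralis, gluteus
#' medius, soleus, tibialis anterior, biceps femoris, rectus femoris.
#'
#' @param muscles number of channels.
#' @return Character vector of muscle names.
#' @export
default_muscle_names <- function(muscles = 16L) {
  base <- c("vast_lat", "sem_tend", "gastr_lat", "glut_med",
            "soleus", "tib_ant", "bic_fem", "rect_fem")
  if (muscles == 16L) {
    c(paste0(base, "_f"), paste0(base, "_b"))
  } else {
    sprintf("m%02d", seq_len(muscles))
  }
}

# one non-negative weight vector: a few dominant muscles over a small floor
random_synergy_vector <- function(muscles) {
  n_dom <- min(muscles, 4L)
  w <- runif(muscles, 0, 0.1)
  dom <- sample.int(muscles, n_dom)
  w[dom] <- runif(n_dom, 0.5, 1)
  w / max(w)
}

# pool of mutually dissimilar weight vectors (pairwise Pearson r < 0.5)
synergy_pool <- function(muscles, n_pool, max_r = 0.5, max_tries = 200L) {
  pool <- matrix(0, nrow = muscles, ncol = n_pool)
  for (j in seq_len(n_pool)) {
    for (try in seq_len(max_tries)) {
      cand <- random_synergy_vector(muscles)
      if (j == 1L ||
          max(abs(cor(cand, pool[, seq_len(j - 1L), drop = FALSE]))) < max_r) {
        pool[, j] <- cand
        break
      }
      if (try == max_tries) {
        pool[, j] <- cand  # accept the last candidate; near-duplicates rare
      }
    }
  }
  pool
}

#' Generate a synthetic EMG dataset with known synergy structure
#'
#' Builds raw EMG-like trials whose analysed phase, once envelope-processed,
#' approximates a known non-negative factorisation `W_true %*% C_true`. The
#' returned ground truth records every quantity needed to score recovery.
#'
#' @param config a [synthetic_config()] object.
#' @param seed integer seed; the dataset is bitwise reproducible given
#'   (config, seed).
#' @return A list of class `"synergy_dataset"` with elements `trials` (list
#'   of raw trials: `participant_id`, `task_id`, `trial_id`, `signals`
#'   (muscles x samples), `sampling_rate`, `events`, `muscle_names`) and
#'   `ground_truth` (class `"synergy_ground_truth"`).
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 1L) {
  if (!inherits(config, "synergy_sim_config")) {
    stop("`config` must come from synthetic_config()", call. = FALSE)
  }
  stop_if_not_count(seed, "seed", min = 0L)
  set.seed(as.integer(seed))

  cf <- config
  m <- cf$muscles
  k <- cf$k_per_task
  P <- cf$points_per_phase
  muscle_names <- default_muscle_names(m)
  n_pool <- max(cf$shared_map)

  W_pool <- synergy_pool(m, n_pool)

  # per-participant perturbation of each pool vector, reused across tasks so
  # a shared synergy stays identical within a participant
  W_participant <- lapply(seq_len(cf$participants), function(p) {
    Wp <- W_pool * exp(matrix(rnorm(m * n_pool, 0, cf$participant_sd),
                              m, n_pool))
    sweep(Wp, 2, apply(Wp, 2, max), "/")
  })

  # burst centres: shared-by-all synergies act early (first third of the
  # phase); task-specific ones are spread over the remainder
  id_tasks <- table(factor(as.integer(cf$shared_map), levels = seq_len(n_pool)))
  shared_ids <- which(id_tasks == cf$tasks & cf$tasks > 1L)
  centers_by_id <- numeric(n_pool)
  if (length(shared_ids) > 0) {
    centers_by_id[shared_ids] <- seq(0.15 * P, 0.3 * P,
                                     length.out = length(shared_ids))
  }
  other_ids <- setdiff(seq_len(n_pool), shared_ids)
  for (t in seq_len(cf$tasks)) {
    ids_t <- intersect(cf$shared_map[t, ], other_ids)
    if (length(ids_t) > 0) {
      centers_by_id[ids_t] <- seq(0.42 * P, 0.88 * P,
                                  length.out = length(ids_t))
    }
  }

  phase <- seq_len(P)
  burst <- function(center, width, amp) amp * exp(-(phase - center)^2 /
                                                    (2 * width^2))

  # pass 1: true activations and noise-free envelopes
  C_true <- vector("list", cf$participants)
  env_true <- vector("list", cf$participants)
  for (p in seq_len(cf$participants)) {
    C_true[[p]] <- vector("list", cf$tasks)
    env_true[[p]] <- vector("list", cf$tasks)
    for (t in seq_len(cf$tasks)) {
      W_pt <- W_participant[[p]][, cf$shared_map[t, ], drop = FALSE]
      C_true[[p]][[t]] <- vector("list", cf$trials_per_task)
      env_true[[p]][[t]] <- vector("list", cf$trials_per_task)
      for (tr in seq_len(cf$trials_per_task)) {
        Ct <- matrix(0, k, P)
        for (j in seq_len(k)) {
          center <- centers_by_id[cf$shared_map[t, j]] +
            rnorm(1, 0, cf$jitter_sd)
          amp <- max(0.2, 1 + rnorm(1, 0, cf$amplitude_cv))
          Ct[j, ] <- burst(center, cf$burst_width, amp)
        }
        C_true[[p]][[t]][[tr]] <- Ct
        env_true[[p]][[t]][[tr]] <- W_pt %*% Ct
      }
    }
  }

  # per-participant, per-muscle peak over all tasks/trials (noise scale)
  peak <- matrix(0, cf$participants, m)
  for (p in seq_len(cf$participants)) {
    peak[p, ] <- apply(do.call(cbind, unlist(env_true[[p]], recursive = FALSE)),
                       1, max)
    peak[p, peak[p, ] <= 0] <- 1e-8
  }

  # pass 2: raw carrier-modulated signals
  nyq <- cf$sampling_rate / 2
  carrier_filter <- signal::butter(4, c(20, min(380, 0.95 * nyq)) / nyq,
                                   type = "pass")
  window <- cf$events[1]:cf$events[2]
  phase_at <- seq(cf$events[1], cf$events[2], length.out = P)

  trials <- list()
  idx <- 0L
  for (p in seq_len(cf$participants)) {
    for (t in seq_len(cf$tasks)) {
      for (tr in seq_len(cf$trials_per_task)) {
        env <- env_true[[p]][[t]][[tr]]
        if (cf$noise_sd > 0) {
          noise <- matrix(rnorm(m * P), m, P) * (cf$noise_sd * peak[p, ])
          env <- pmax(env + noise, 0)
        }
        signals <- matrix(0, m, cf$n_samples)
        for (mu in seq_len(m)) {
          carrier <- signal::filter(carrier_filter, rnorm(cf$n_samples))
          carrier <- as.numeric(carrier) / max(sd(carrier), 1e-12)
          amp <- rep(cf$baseline_sd * peak[p, mu], cf$n_samples)
          amp[window] <- amp[window] +
            approx(phase_at, env[mu, ], xout = window)$y
          signals[mu, ] <- carrier * amp
        }
        rownames(signals) <- muscle_names
        idx <- idx + 1L
        trials[[idx]] <- structure(list(
          participant_id = sprintf("P%d", p),
          task_id = sprintf("T%d", t),
          trial_id = tr,
          signals = signals,
          sampling_rate = cf$sampling_rate,
          events = cf$events,
          muscle_names = muscle_names
        ), class = "raw_trial")
      }
    }
  }

  ground_truth <- structure(list(
    config = cf, seed = as.integer(seed), shared_map = cf$shared_map,
    W_pool = W_pool, W_participant = W_participant,
    centers_by_id = centers_by_id, C_true = C_true, env_true = env_true,
    peak = peak, muscle_names = muscle_names
  ), class = "synergy_ground_truth")

  structure(list(trials = trials, ground_truth = ground_truth),
            class = "synergy_dataset")
}

#' Ground-truth synergy vectors for one participant and task
#'
#' With `normalized = TRUE` (default) the weights are expressed on the scale
#' the preprocessing pipeline produces: each muscle row is divided by that
#' muscle's peak noise-free envelope across all tasks (the cross-task
#' amplitude normalisation), and columns are rescaled to maximum 1.
#'
#' @param ground_truth a `"synergy_ground_truth"` object.
#' @param participant,task indices (1-based).
#' @param normalized express weights on the amplitude-normalised scale?
#' @return A muscles x k non-negative matrix with column maxima 1.
#' @export
true_synergies <- function(ground_truth, participant, task,
                           normalized = TRUE) {
  gt <- ground_truth
  W <- gt$W_participant[[participant]][, gt$shared_map[task, ], drop = FALSE]
  if (normalized) {
    W <- W / gt$peak[participant, ]
    W <- sweep(W, 2, apply(W, 2, max), "/")
  }
  W
}

#' Match estimated synergies to reference synergies
#'
#' Exhaustive search over all one-to-one assignments of estimated to
#' reference columns, maximising the mean cosine similarity. Intended for
#' recovery scoring against ground truth (k <= 8).
#'
#' @param W_est,W_ref non-negative matrices with the same number of rows and
#'   columns.
#' @return List with `permutation` (index into `W_est` columns for each
#'   `W_ref` column), `cossim` (per matched pair) and `mean_cossim`.
#' @export
match_synergies <- function(W_est, W_ref) {
  k <- ncol(W_ref)
  stopifnot(ncol(W_est) == k, nrow(W_est) == nrow(W_ref))
  if (k > 8L) stop("exhaustive matching supported for k <= 8", call. = FALSE)
  S <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) S[i, j] <- cos_sim(W_ref[, i], W_est[, j])
  }
  perms <- permutations_of(k)
  scores <- vapply(perms, function(p) mean(S[cbind(seq_len(k), p)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  list(permutation = best,
       cossim = S[cbind(seq_len(k), best)],
       mean_cossim = max(scores))
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
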
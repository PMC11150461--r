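#' Pipeline configuration
#'
#' Collects every tunable of the analysis pipeline with the study defaults:
#' 10-400 Hz band-pass and 6 Hz low-pass envelopes, 100-point phase,
#' 50-restart NMF over k = 1..(muscles - 1), NoS criteria (tVAF > 90%,
#' increment <= 1%), similarity thresholds (CosSim 0.8, r_max 0.9, Pearson
#' alpha 0.01), and a +/-10-sample cross-correlation lag window.
#'
#' @param manifest path to a dataset manifest (see [read_dataset()]); may be
#'   `NULL` when a dataset object is passed to [run_pipeline()] directly.
#' @param outdir output directory for result tables; `NULL` disables writing.
#' @param band,low_pass,filter_order,points preprocessing parameters.
#' @param restarts,max_iter,tol,method,k_range factorisation parameters
#'   (`k_range = NULL` means `1:(muscles - 1)`).
#' @param tvaf_threshold,increment_threshold NoS selection criteria.
#' @param cossim_threshold,rmax_threshold,alpha similarity thresholds.
#' @param max_lag_fraction cross-correlation lag window as a fraction of one
#'   trial block.
#' @param n_random random sources per target for the null (`NULL` = number
#'   of real sources).
#' @param seed master seed for factorisation restarts and random nulls.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(manifest = NULL, outdir = NULL,
                            band = c(10, 400), low_pass = 6,
                            filter_order = 4, points = 100L,
                            restarts = 50L, max_iter = 500L, tol = 1e-6,
                            method = "hals", k_range = NULL,
                            tvaf_threshold = 90, increment_threshold = 1,
                            cossim_threshold = 0.8, rmax_threshold = 0.9,
                            alpha = 0.01, max_lag_fraction = 0.1,
                            n_random = NULL, seed = 1L) {
  stop_if_not_number(tvaf_threshold, "tvaf_threshold", min = 0, max = 100)
  stop_if_not_number(increment_threshold, "increment_threshold", min = 0,
                     max = 100)
  stop_if_not_number(cossim_threshold, "cossim_threshold", min = 0, max = 1)
  stop_if_not_number(rmax_threshold, "rmax_threshold", min = 0, max = 1)
  stop_if_not_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  stop_if_not_number(max_lag_fraction, "max_lag_fraction", min = 0, max = 1)
  structure(list(
    manifest = manifest, outdir = outdir, band = band, low_pass = low_pass,
    filter_order = filter_order, points = as.integer(points),
    restarts = as.integer(restarts), max_iter = as.integer(max_iter),
    tol = tol, method = method, k_range = k_range,
    tvaf_threshold = tvaf_threshold,
    increment_threshold = increment_threshold,
    cossim_threshold = cossim_threshold, rmax_threshold = rmax_threshold,
    alpha = alpha, max_lag_fraction = max_lag_fraction,
    n_random = n_random, seed = as.integer(seed)
  ), class = "pipeline_config")
}

write_table <- function(df, outdir, name) {
  if (is.null(outdir)) return(invisible(NULL))
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  write.csv(df, file.path(outdir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run the full muscle-synergy pipeline
#'
#' Executes preprocess -> tVAF curves -> NoS/NoSoA selection -> reordering
#' -> pairwise inter-participant similarity -> cross-participant and
#' cross-task reconstruction with randomized nulls -> sharedOA/sharedIND
#' counting, and (optionally) writes every tidy result table plus a JSON
#' run report to `config$outdir`.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional `"synergy_dataset"`; if `NULL`, read from
#'   `config$manifest`.
#' @return (Invisibly) a list with `envelopes`, `curves`, `nos` (table +
#'   NoSoA), `cov`, `interparticipant`, `cross_participant`,
#'   `randomized_null`, `cross_task`, `shared`, and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  if (is.null(dataset)) {
    if (is.null(config$manifest)) {
      stop("either `dataset` or `config$manifest` must be given",
           call. = FALSE)
    }
    dataset <- read_dataset(config$manifest)
  }
  m <- length(dataset$trials[[1]]$muscle_names)
  if (!is.null(config$k_range) && max(config$k_range) > m - 1) {
    stop("k_range upper bound exceeds muscles - 1", call. = FALSE)
  }
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  }

  envelopes <- process_dataset(dataset, band = config$band,
                               low_pass = config$low_pass,
                               order = config$filter_order,
                               points = config$points)
  participants <- names(envelopes)
  tasks <- names(envelopes[[1]])
  n_pt <- length(participants) * length(tasks)
  seeds <- child_seeds(config$seed, 2L * n_pt)
  null_seeds <- matrix(seeds[(n_pt + 1L):(2L * n_pt)],
                       nrow = length(participants))

  # tVAF curves and model selection ------------------------------------------
  curves <- vector("list", length(participants))
  names(curves) <- participants
  si <- 0L
  curve_rows <- list()
  for (p in participants) {
    curves[[p]] <- vector("list", length(tasks))
    names(curves[[p]]) <- tasks
    for (t in tasks) {
      si <- si + 1L
      cv <- tvaf_curve(envelopes[[p]][[t]], restarts = config$restarts,
                       seed = seeds[si], k_range = config$k_range,
                       max_iter = config$max_iter, tol = config$tol,
                       method = config$method)
      curves[[p]][[t]] <- cv
      curve_rows[[si]] <- data.frame(participant = p, task = t,
                                     k = cv$k_range, tvaf = cv$tvaf_by_k,
                                     stringsAsFactors = FALSE)
    }
  }
  nos <- nos_table(curves, config$tvaf_threshold, config$increment_threshold)
  covs <- cov_summary(nos$table)
  k_all <- nos$nosoa

  decomp_at <- function(p, t, k) {
    cv <- curves[[p]][[t]]
    cv$decompositions[[match(k, cv$k_range)]]
  }

  # per-task inter-participant analyses --------------------------------------
  inter_rows <- list()
  recon_rows <- list()
  null_rows <- list()
  for (t in tasks) {
    ds <- setNames(lapply(participants, function(p) decomp_at(p, t, k_all)),
                   participants)
    reord <- reorder_to_reference(ds, reference = 1L)
    ds <- reord$decompositions
    pw <- pairwise_interparticipant(
      ds, cossim_threshold = config$cossim_threshold,
      rmax_threshold = config$rmax_threshold, alpha = config$alpha,
      max_lag_fraction = config$max_lag_fraction,
      block_length = config$points)
    pw$details$task <- t
    inter_rows[[t]] <- pw$details

    Es <- lapply(participants, function(p) envelopes[[p]][[t]])
    cps <- cross_participant_study(ds, Es,
                                   max_lag_fraction = config$max_lag_fraction,
                                   block_length = config$points)
    cps$task <- t
    recon_rows[[t]] <- cps

    for (pi in seq_along(participants)) {
      sources <- ds[-pi]
      if (!is.null(config$n_random)) {
        sources <- rep(sources, length.out = config$n_random)
      }
      nulls <- randomized_null(ds[[pi]], Es[[pi]], sources,
                               seed = null_seeds[pi, match(t, tasks)],
                               max_lag_fraction = config$max_lag_fraction,
                               block_length = config$points)
      nulls$task <- t
      nulls$target <- participants[pi]
      null_rows[[paste(t, pi)]] <- nulls
    }
  }

  # per-participant cross-task analyses ---------------------------------------
  shared_rows <- list()
  cross_task_rows <- list()
  for (p in participants) {
    if (length(tasks) >= 2) {
      ds_oa <- setNames(lapply(tasks, function(t) decomp_at(p, t, k_all)),
                        tasks)
      oa <- shared_oa(ds_oa)
      oa$pairs$participant <- p
      oa$pairs$n_all_task_shared <- length(oa$all_task_shared)

      nos_of <- function(t) {
        nos$table$nos[nos$table$participant == p & nos$table$task == t]
      }
      ds_ind <- setNames(lapply(tasks, function(t) decomp_at(p, t, nos_of(t))),
                         tasks)
      ind <- shared_ind(ds_ind)
      ind$pairs$participant <- p
      ind$pairs$n_all_task_shared <- length(ind$all_task_shared)
      shared_rows[[p]] <- rbind(oa$pairs, ind$pairs)

      Es <- setNames(lapply(tasks, function(t) envelopes[[p]][[t]]), tasks)
      ct <- cross_task_reconstruction(ds_oa, Es,
                                      max_lag_fraction = config$max_lag_fraction,
                                      block_length = config$points)
      ct$participant <- p
      cross_task_rows[[p]] <- ct
    }
  }

  results <- list(
    envelopes = envelopes, curves = curves, nos = nos, cov = covs,
    interparticipant = do.call(rbind, unname(inter_rows)),
    cross_participant = do.call(rbind, unname(recon_rows)),
    randomized_null = do.call(rbind, unname(null_rows)),
    cross_task = if (length(cross_task_rows) > 0) {
      do.call(rbind, unname(cross_task_rows))
    } else NULL,
    shared = if (length(shared_rows) > 0) {
      do.call(rbind, unname(shared_rows))
    } else NULL,
    config = config
  )

  if (!is.null(config$outdir)) {
    write_table(do.call(rbind, unname(curve_rows)), config$outdir,
                "tvaf_curves")
    write_table(nos$table, config$outdir, "nos_table")
    write_table(covs, config$outdir, "cov_summary")
    write_table(results$interparticipant, config$outdir,
                "interparticipant_similarity")
    write_table(results$cross_participant, config$outdir,
                "cross_participant_reconstruction")
    write_table(results$randomized_null, config$outdir, "randomized_null")
    if (!is.null(results$cross_task)) {
      write_table(results$cross_task, config$outdir,
                  "cross_task_reconstruction")
    }
    if (!is.null(results$shared)) {
      write_table(results$shared, config$outdir, "shared_synergies")
    }
    report <- list(
      package_version = as.character(utils::packageVersion("musyn")),
      r_version = R.version.string,
      nosoa = k_all,
      seed = config$seed,
      config = config[setdiff(names(config), c("manifest", "outdir"))]
    )
    jsonlite::write_json(report, file.path(config$outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(results)
}
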
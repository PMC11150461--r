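#' Reconstruct activation coefficients from fixed synergy vectors
#'
#' Solves, for every time point (column of `E`), the non-negative
#' least-squares problem `min ||E[, t] - W c||^2, c >= 0` with an exact
#' active-set solver, then scores the fit by [tvaf()]. Columns are
#' independent given the fixed design, so the per-column solve is exact for
#' the joint problem.
#'
#' @param E target envelope matrix (muscles x timepoints) or
#'   `"envelope_matrix"`.
#' @param W_fixed non-negative muscles x k matrix with no zero column.
#' @return List with `C_rec` (k x timepoints, non-negative) and `tvaf_rec`.
#' @export
reconstruct_C <- function(E, W_fixed) {
  E <- as_E(E)
  if (any(W_fixed < 0)) stop("W_fixed must be non-negative", call. = FALSE)
  zero <- which(apply(W_fixed, 2, max) <= 0)
  if (length(zero) > 0) {
    stop("zero column(s) in W_fixed at index: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  if (nrow(W_fixed) != nrow(E)) stop("muscle count mismatch", call. = FALSE)
  C_rec <- .nnls_cols_cpp(W_fixed, E)
  list(C_rec = C_rec, tvaf_rec = tvaf(E, W_fixed, C_rec))
}

#' Reconstruct synergy vectors from fixed activation coefficients
#'
#' The transposed problem of [reconstruct_C()]: rows of `W_rec` solve
#' `min ||E[i, ] - w C||^2, w >= 0`.
#'
#' @param E target envelope matrix (muscles x timepoints) or
#'   `"envelope_matrix"`.
#' @param C_fixed non-negative k x timepoints matrix with no zero row.
#' @return List with `W_rec` (muscles x k, non-negative) and `tvaf_rec`.
#' @export
reconstruct_W <- function(E, C_fixed) {
  E <- as_E(E)
  if (any(C_fixed < 0)) stop("C_fixed must be non-negative", call. = FALSE)
  zero <- which(apply(C_fixed, 1, max) <= 0)
  if (length(zero) > 0) {
    stop("zero row(s) in C_fixed at index: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  if (ncol(C_fixed) != ncol(E)) stop("timepoint count mismatch",
                                     call. = FALSE)
  W_rec <- t(.nnls_cols_cpp(t(C_fixed), t(E)))
  list(W_rec = W_rec, tvaf_rec = tvaf(E, W_rec, C_fixed))
}

reconstruction_similarity <- function(orig_W, rec_W, orig_C, rec_C, ...) {
  k <- if (!is.null(orig_W)) ncol(orig_W) else nrow(orig_C)
  rows <- vector("list", k)
  for (s in seq_len(k)) {
    if (!is.null(rec_W)) {
      rows[[s]] <- data.frame(
        synergy = s,
        cossim = cos_sim(orig_W[, s], rec_W[, s]),
        r = pearson_r(orig_W[, s], rec_W[, s]),
        rmax = NA_real_, stringsAsFactors = FALSE
      )
    } else {
      xc <- xcorr_rmax(orig_C[s, ], rec_C[s, ], ...)
      rows[[s]] <- data.frame(
        synergy = s,
        cossim = cos_sim(orig_C[s, ], rec_C[s, ]),
        r = pearson_r(orig_C[s, ], rec_C[s, ]),
        rmax = xc$r_max, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Cross-participant reconstruction study for one task
#'
#' For every ordered pair (target, source) of participants, reconstructs the
#' target's synergy vectors from the source's activation coefficients
#' (`W_rec`) and the target's activation coefficients from the source's
#' synergy vectors (`C_rec`), records the reconstruction tVAF, and scores
#' the per-synergy similarity between original and reconstructed factors
#' (W: CosSim, r; C: CosSim, r, r_max). Decompositions are assumed already
#' reordered to a common synergy ordering at a common k.
#'
#' @param decompositions named list of reordered `"synergy_decomposition"`.
#' @param envelopes named list of matching `"envelope_matrix"` objects (same
#'   names/order).
#' @param ... passed to [xcorr_rmax()].
#' @return Data frame: target, source, direction (`"W_rec"`/`"C_rec"`),
#'   tvaf_rec, synergy, cossim, r, rmax.
#' @export
cross_participant_study <- function(decompositions, envelopes, ...) {
  ids <- names(decompositions)
  if (is.null(ids)) ids <- sprintf("P%d", seq_along(decompositions))
  rows <- list()
  for (ti in seq_along(decompositions)) {
    E_t <- as_E(envelopes[[ti]])
    d_t <- decompositions[[ti]]
    for (si in seq_along(decompositions)) {
      if (si == ti) next
      d_s <- decompositions[[si]]
      rw <- reconstruct_W(E_t, d_s$C)
      sim_w <- reconstruction_similarity(d_t$W, rw$W_rec, NULL, NULL)
      sim_w$target <- ids[ti]; sim_w$source <- ids[si]
      sim_w$direction <- "W_rec"; sim_w$tvaf_rec <- rw$tvaf_rec

      rc <- reconstruct_C(E_t, d_s$W)
      sim_c <- reconstruction_similarity(NULL, NULL, d_t$C, rc$C_rec, ...)
      sim_c$target <- ids[ti]; sim_c$source <- ids[si]
      sim_c$direction <- "C_rec"; sim_c$tvaf_rec <- rc$tvaf_rec

      rows[[length(rows) + 1L]] <- rbind(sim_w, sim_c)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("target", "source", "direction", "tvaf_rec", "synergy",
          "cossim", "r", "rmax")]
}

# draw a random non-negative matrix standing in for W (columns max 1) or C
random_factor <- function(nrow, ncol, style = c("W", "C")) {
  style <- match.arg(style)
  M <- matrix(runif(nrow * ncol), nrow, ncol)
  if (style == "W") M <- sweep(M, 2, apply(M, 2, max), "/")
  M
}

#' Randomized-input reconstruction null
#'
#' Repeats the reconstruction of [cross_participant_study()] with seeded
#' random uniform matrices in place of each real source. Each random matrix
#' is preordered against the corresponding real source by greedy cosine
#' matching (random W columns to the source's W columns; random C rows to
#' the source's C rows) before being used as the fixed factor, mirroring
#' the preordering applied to real inputs. The resulting `tvaf_rand` values
#' quantify how much reconstruction quality arises by chance.
#'
#' @param target_decomposition the target's `"synergy_decomposition"`.
#' @param E_target the target's envelope matrix.
#' @param sources list of real source `"synergy_decomposition"` objects (one
#'   random matrix is drawn per source, so averages are comparable).
#' @param seed integer seed for the random sources.
#' @param ... passed to [xcorr_rmax()].
#' @return Data frame like [cross_participant_study()] with `source`
#'   `"rand1"`, `"rand2"`, ... and column `tvaf_rand` instead of `tvaf_rec`.
#' @export
randomized_null <- function(target_decomposition, E_target, sources,
                            seed = 1L, ...) {
  E_t <- as_E(E_target)
  d_t <- target_decomposition
  m <- nrow(d_t$W); k <- d_t$k; n <- ncol(d_t$C)
  seeds <- child_seeds(seed, length(sources))
  rows <- list()
  for (si in seq_along(sources)) {
    set.seed(seeds[si])
    src <- sources[[si]]

    W_rand <- random_factor(m, k, "W")
    S <- column_similarity_matrix(src$W, W_rand, cos_sim)
    gm <- greedy_match(S)
    perm <- integer(k); perm[gm$pairs[, 1]] <- gm$pairs[, 2]
    W_rand <- W_rand[, perm, drop = FALSE]
    rc <- reconstruct_C(E_t, W_rand)
    sim_c <- reconstruction_similarity(NULL, NULL, d_t$C, rc$C_rec, ...)
    sim_c$direction <- "C_rec"; sim_c$tvaf_rand <- rc$tvaf_rec

    C_rand <- random_factor(k, n, "C")
    S <- column_similarity_matrix(t(src$C), t(C_rand), cos_sim)
    gm <- greedy_match(S)
    perm <- integer(k); perm[gm$pairs[, 1]] <- gm$pairs[, 2]
    C_rand <- C_rand[perm, , drop = FALSE]
    rw <- reconstruct_W(E_t, C_rand)
    sim_w <- reconstruction_similarity(d_t$W, rw$W_rec, NULL, NULL)
    sim_w$direction <- "W_rec"; sim_w$tvaf_rand <- rw$tvaf_rec

    both <- rbind(sim_w, sim_c)
    both$source <- sprintf("rand%d", si)
    rows[[length(rows) + 1L]] <- both
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("source", "direction", "tvaf_rand", "synergy",
          "cossim", "r", "rmax")]
}
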
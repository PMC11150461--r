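#' Count shared synergies between two tasks
#'
#' Computes Pearson r for all column pairs of `W1` and `W2` and accepts
#' pairs greedily by descending r while r exceeds `r_threshold`, removing
#' both synergies after each acceptance (one-to-one matching: a synergy
#' cannot be shared twice).
#'
#' @param W1,W2 non-negative muscles x k matrices (same muscle count; k may
#'   differ).
#' @param r_threshold similarity threshold; defaults to
#'   [critical_r()]`(muscles, 0.01)`.
#' @return List with `n_shared` and `matched_pairs` (data frame: synergy1,
#'   synergy2, r).
#' @export
count_shared <- function(W1, W2, r_threshold = NULL) {
  if (nrow(W1) != nrow(W2)) stop("muscle count mismatch", call. = FALSE)
  if (is.null(r_threshold)) r_threshold <- critical_r(nrow(W1), 0.01)
  S <- column_similarity_matrix(W1, W2, pearson_r)
  gm <- greedy_match(S, threshold = r_threshold)
  matched <- if (nrow(gm$pairs) > 0) {
    data.frame(synergy1 = gm$pairs[, 1], synergy2 = gm$pairs[, 2],
               r = gm$values, stringsAsFactors = FALSE)
  } else {
    data.frame(synergy1 = integer(0), synergy2 = integer(0), r = numeric(0))
  }
  list(n_shared = nrow(matched), matched_pairs = matched)
}

#' Relative number of shared synergies
#'
#' `100 * n_shared / (k1 + k2 - n_shared)`: the shared count relative to the
#' union of the two tasks' synergy sets.
#'
#' @param n_shared shared-synergy count, `0 <= n_shared <= min(k1, k2)`.
#' @param k1,k2 synergy counts of the two tasks.
#' @return Percentage in \[0, 100\].
#' @export
pct_shared <- function(n_shared, k1, k2) {
  n_shared <- stop_if_not_count(n_shared, "n_shared", min = 0L)
  k1 <- stop_if_not_count(k1, "k1", min = 0L)
  k2 <- stop_if_not_count(k2, "k2", min = 0L)
  if (n_shared > min(k1, k2)) {
    stop("n_shared cannot exceed min(k1, k2)", call. = FALSE)
  }
  denom <- k1 + k2 - n_shared
  if (denom <= 0) stop("undefined: k1 + k2 - n_shared <= 0", call. = FALSE)
  100 * n_shared / denom
}

# shared-synergy analysis over all task pairs of one participant; the
# sharedOA and sharedIND variants differ only in the rank of the inputs
shared_analysis <- function(decompositions, r_threshold = NULL,
                            method = "sharedOA") {
  tasks <- names(decompositions)
  if (is.null(tasks)) tasks <- sprintf("T%d", seq_along(decompositions))
  n_tasks <- length(decompositions)
  if (n_tasks < 2) stop("at least two tasks required", call. = FALSE)

  prs <- combn(n_tasks, 2)
  pair_rows <- list()
  matchings <- vector("list", ncol(prs))
  for (pi in seq_len(ncol(prs))) {
    a <- prs[1, pi]; b <- prs[2, pi]
    cs <- count_shared(decompositions[[a]]$W, decompositions[[b]]$W,
                       r_threshold)
    matchings[[pi]] <- cs$matched_pairs
    k1 <- decompositions[[a]]$k; k2 <- decompositions[[b]]$k
    pair_rows[[pi]] <- data.frame(
      task1 = tasks[a], task2 = tasks[b], method = method,
      k1 = k1, k2 = k2, n_shared = cs$n_shared,
      pct_shared = pct_shared(cs$n_shared, k1, k2),
      stringsAsFactors = FALSE
    )
  }
  pairs_df <- do.call(rbind, pair_rows)

  # synergies of the first task shared consistently through ALL tasks:
  # the pairwise matchings must agree transitively
  all_shared <- integer(0)
  if (n_tasks >= 2) {
    pair_index <- function(a, b) which(prs[1, ] == a & prs[2, ] == b)
    lookup <- function(mp, from) {
      i <- match(from, mp$synergy1)
      if (is.na(i)) NA_integer_ else mp$synergy2[i]
    }
    for (j in seq_len(decompositions[[1]]$k)) {
      mapped <- integer(n_tasks)
      mapped[1] <- j
      ok <- TRUE
      for (t in 2:n_tasks) {
        mapped[t] <- lookup(matchings[[pair_index(1L, t)]], j)
        if (is.na(mapped[t])) { ok <- FALSE; break }
      }
      if (ok && n_tasks > 2) {
        for (a in 2:(n_tasks - 1)) {
          for (b in (a + 1):n_tasks) {
            mp <- matchings[[pair_index(a, b)]]
            if (is.na(lookup(mp, mapped[a])) ||
                lookup(mp, mapped[a]) != mapped[b]) {
              ok <- FALSE
              break
            }
          }
          if (!ok) break
        }
      }
      if (ok) all_shared <- c(all_shared, j)
    }
  }
  list(pairs = pairs_df, matchings = setNames(
    matchings, apply(prs, 2, function(ab) paste(tasks[ab], collapse = "-"))),
    all_task_shared = all_shared)
}

#' Shared synergies at the study-wide rank (sharedOA)
#'
#' All tasks are compared at the common rank NoSoA. For every task pair,
#' synergy vectors are matched one-to-one by Pearson r above the critical
#' threshold; the relative shared count follows
#' `100 * n / (k1 + k2 - n)`. Synergies of the first task whose pairwise
#' matches are transitively consistent across every task pair are flagged as
#' shared through all tasks.
#'
#' @param decompositions named list of `"synergy_decomposition"` objects,
#'   one per task, all at the same k (NoSoA).
#' @param r_threshold see [count_shared()].
#' @return List with `pairs` (data frame per task pair), `matchings` and
#'   `all_task_shared` (synergy indices of the first task).
#' @export
shared_oa <- function(decompositions, r_threshold = NULL) {
  ks <- vapply(decompositions, `[[`, 0L, "k")
  if (length(unique(ks)) != 1) {
    stop("sharedOA requires a common k (NoSoA) for all tasks", call. = FALSE)
  }
  shared_analysis(decompositions, r_threshold, method = "sharedOA")
}

#' Shared synergies at each task's own rank (sharedIND)
#'
#' Identical to [shared_oa()] except every task contributes its individually
#' selected NoS, so the compared ranks may differ between tasks.
#'
#' @param decompositions named list of `"synergy_decomposition"` objects,
#'   one per task, each at that task's NoS.
#' @param r_threshold see [count_shared()].
#' @return As [shared_oa()].
#' @export
shared_ind <- function(decompositions, r_threshold = NULL) {
  shared_analysis(decompositions, r_threshold, method = "sharedIND")
}

#' Cross-task reconstruction for one participant
#'
#' For every ordered task pair (target, source): the source's synergy
#' vectors are preordered by greedily matching the cosine similarity of the
#' source's activation coefficients to the target's, then used to
#' reconstruct the target's activation coefficients (`C_rec`); symmetrically
#' the source's coefficients are preordered by the cosine similarity of the
#' synergy vectors and used to reconstruct `W_rec`. Preordering is needed
#' because synergies are ordered within, not across, tasks. Original and
#' reconstructed factors are compared per synergy (CosSim, r, and r_max for
#' coefficients).
#'
#' @param decompositions named list of `"synergy_decomposition"` objects,
#'   one per task, at a common k.
#' @param envelopes named list of matching `"envelope_matrix"` objects.
#' @param ... passed to [xcorr_rmax()].
#' @return Data frame: target, source, direction, tvaf_rec, synergy,
#'   cossim, r, rmax.
#' @export
cross_task_reconstruction <- function(decompositions, envelopes, ...) {
  tasks <- names(decompositions)
  if (is.null(tasks)) tasks <- sprintf("T%d", seq_along(decompositions))
  rows <- list()
  for (ti in seq_along(decompositions)) {
    d_t <- decompositions[[ti]]
    E_t <- as_E(envelopes[[ti]])
    k <- d_t$k
    for (si in seq_along(decompositions)) {
      if (si == ti) next
      d_s <- decompositions[[si]]

      # C_rec: preorder source W by similarity of the C waveforms
      S <- column_similarity_matrix(t(d_t$C), t(d_s$C), cos_sim)
      gm <- greedy_match(S)
      perm <- integer(k); perm[gm$pairs[, 1]] <- gm$pairs[, 2]
      rc <- reconstruct_C(E_t, d_s$W[, perm, drop = FALSE])
      sim_c <- reconstruction_similarity(NULL, NULL, d_t$C, rc$C_rec, ...)
      sim_c$direction <- "C_rec"; sim_c$tvaf_rec <- rc$tvaf_rec

      # W_rec: preorder source C by similarity of the synergy vectors
      S <- column_similarity_matrix(d_t$W, d_s$W, cos_sim)
      gm <- greedy_match(S)
      perm <- integer(k); perm[gm$pairs[, 1]] <- gm$pairs[, 2]
      rw <- reconstruct_W(E_t, d_s$C[perm, , drop = FALSE])
      sim_w <- reconstruction_similarity(d_t$W, rw$W_rec, NULL, NULL)
      sim_w$direction <- "W_rec"; sim_w$tvaf_rec <- rw$tvaf_rec

      both <- rbind(sim_w, sim_c)
      both$target <- tasks[ti]
      both$source <- tasks[si]
      rows[[length(rows) + 1L]] <- both
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("target", "source", "direction", "tvaf_rec", "synergy",
          "cossim", "r", "rmax")]
}
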
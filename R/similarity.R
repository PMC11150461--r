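#' Cosine similarity
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return `sum(u * v) / (||u|| ||v||)`; lies in \[0, 1\] for non-negative
#'   inputs.
#' @export
cos_sim <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

#' Pearson correlation between two vectors
#'
#' Thin wrapper over [stats::cor()] that rejects zero-variance inputs.
#'
#' @param u,v numeric vectors of equal length with nonzero variance.
#' @return Product-moment correlation in \[-1, 1\].
#' @export
pearson_r <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  if (sd(u) == 0 || sd(v) == 0) {
    stop("Pearson r undefined for zero-variance input", call. = FALSE)
  }
  cor(u, v)
}

#' Critical value of Pearson's r
#'
#' Two-tailed critical correlation for `n` paired observations at
#' significance level `alpha`, from the inverse central t distribution with
#' `n - 2` degrees of freedom: `r = t / sqrt(t^2 + df)`. For synergy-vector
#' comparisons, `n` is the number of muscles; with 16 muscles and
#' `alpha = 0.01` this gives 0.623.
#'
#' @param n number of paired observations (>= 3).
#' @param alpha two-tailed significance level.
#' @return Critical r in (0, 1).
#' @export
critical_r <- function(n, alpha = 0.01) {
  n <- stop_if_not_count(n, "n", min = 3L)
  stop_if_not_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  df <- n - 2
  t <- qt(1 - alpha / 2, df)
  t / sqrt(t^2 + df)
}

#' Maximum cross-correlation between two activation waveforms
#'
#' Slides `c2` against `c1` over integer lags up to `max_lag` and returns
#' the maximal Pearson correlation of the overlapping segments together with
#' the maximising lag. Ties are resolved towards the smallest absolute lag,
#' negative lag first. Lags whose overlap has zero variance are skipped.
#'
#' By default the lag window is 10% of one trial block (`block_length`,
#' usually 100 points), so concatenated multi-trial waveforms are not
#' spuriously aligned across trial boundaries.
#'
#' @param c1,c2 numeric vectors of equal length (>= 3).
#' @param max_lag maximum absolute lag in samples; if `NULL`, computed as
#'   `floor(max_lag_fraction * min(block_length, length(c1)))`.
#' @param max_lag_fraction fraction used for the default `max_lag`.
#' @param block_length nominal length of one trial block.
#' @return List with `r_max` and `lag` (positive lag = `c2` delayed).
#' @export
xcorr_rmax <- function(c1, c2, max_lag = NULL, max_lag_fraction = 0.1,
                       block_length = 100L) {
  n <- length(c1)
  if (length(c2) != n) stop("length mismatch", call. = FALSE)
  if (n < 3) stop("waveforms must have length >= 3", call. = FALSE)
  if (is.null(max_lag)) {
    max_lag <- floor(max_lag_fraction * min(block_length, n))
  }
  max_lag <- min(max_lag, n - 3L)

  # lag order 0, -1, +1, -2, +2, ... implements the tie-break rule
  lags <- 0L
  for (l in seq_len(max_lag)) lags <- c(lags, -l, l)

  r_max <- -Inf
  best_lag <- NA_integer_
  any_valid <- FALSE
  for (lag in lags) {
    if (lag >= 0) {
      a <- c1[(1 + lag):n]; b <- c2[1:(n - lag)]
    } else {
      a <- c1[1:(n + lag)]; b <- c2[(1 - lag):n]
    }
    if (sd(a) == 0 || sd(b) == 0) next
    any_valid <- TRUE
    r <- cor(a, b)
    if (r > r_max) { r_max <- r; best_lag <- lag }
  }
  if (!any_valid) {
    stop("all lags skipped: zero variance in every overlap", call. = FALSE)
  }
  list(r_max = r_max, lag = best_lag)
}

# greedy one-to-one assignment maximising a score matrix: repeatedly take
# the globally largest remaining entry; ties by lowest row then column index
greedy_match <- function(S, threshold = -Inf) {
  nr <- nrow(S); nc <- ncol(S)
  S_work <- S
  pairs <- matrix(integer(0), ncol = 2)
  values <- numeric(0)
  for (step in seq_len(min(nr, nc))) {
    best <- max(S_work, na.rm = TRUE)
    if (!is.finite(best) || best <= threshold) break
    hits <- which(S_work == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    pairs <- rbind(pairs, c(i, j))
    values <- c(values, S[i, j])
    S_work[i, ] <- NA
    S_work[, j] <- NA
  }
  list(pairs = pairs, values = values)
}

column_similarity_matrix <- function(A, B, fun) {
  S <- matrix(0, ncol(A), ncol(B))
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) S[i, j] <- fun(A[, i], B[, j])
  }
  S
}

#' Reorder synergies to a reference participant's ordering
#'
#' Greedy matching on the cosine similarity of synergy vectors: the globally
#' most similar (reference, other) pair is fixed first, then removed, and so
#' on, so the most similar synergies occupy the same slot across
#' participants. `W` columns and `C` rows are permuted together.
#'
#' @param decompositions named list of `"synergy_decomposition"` objects
#'   (one per participant) with a common `k`.
#' @param reference name or index of the reference participant.
#' @return List with `decompositions` (reordered, reference untouched) and
#'   `permutations` (per participant, the source column placed at each slot).
#' @export
reorder_to_reference <- function(decompositions, reference = 1L) {
  ks <- vapply(decompositions, `[[`, 0L, "k")
  if (length(unique(ks)) != 1) {
    stop("all decompositions must share the same k", call. = FALSE)
  }
  k <- ks[1]
  if (is.character(reference)) reference <- match(reference,
                                                  names(decompositions))
  ref <- decompositions[[reference]]

  perms <- vector("list", length(decompositions))
  names(perms) <- names(decompositions)
  out <- decompositions
  for (i in seq_along(decompositions)) {
    if (i == reference) {
      perms[[i]] <- seq_len(k)
      next
    }
    d <- decompositions[[i]]
    S <- column_similarity_matrix(ref$W, d$W, cos_sim)
    gm <- greedy_match(S)
    perm <- integer(k)
    perm[gm$pairs[, 1]] <- gm$pairs[, 2]
    d$W <- d$W[, perm, drop = FALSE]
    d$C <- d$C[perm, , drop = FALSE]
    out[[i]] <- d
    perms[[i]] <- perm
  }
  list(decompositions = out, permutations = perms)
}

#' Pairwise inter-participant similarity of synergies
#'
#' For every unordered pair of participants and every synergy slot, computes
#' cosine similarity and Pearson r between synergy vectors (`W` columns) and
#' cosine similarity and maximum cross-correlation between activation
#' coefficients (`C` rows). Per-synergy averages across pairs are compared
#' against the similarity thresholds (W: CosSim > `cossim_threshold`,
#' r > `critical_r(muscles, alpha)`; C: CosSim > `cossim_threshold`,
#' r_max > `rmax_threshold`).
#'
#' @param decompositions named list of reordered `"synergy_decomposition"`
#'   objects with a common `k` (see [reorder_to_reference()]).
#' @param cossim_threshold,rmax_threshold,alpha similarity thresholds.
#' @param ... passed to [xcorr_rmax()] (lag window control).
#' @return List with `details` (one row per pair x synergy x metric) and
#'   `summary` (per synergy x metric: mean value, threshold, similar flag).
#' @export
pairwise_interparticipant <- function(decompositions, cossim_threshold = 0.8,
                                      rmax_threshold = 0.9, alpha = 0.01,
                                      ...) {
  ks <- vapply(decompositions, `[[`, 0L, "k")
  if (length(unique(ks)) != 1) {
    stop("all decompositions must share the same k", call. = FALSE)
  }
  k <- ks[1]
  ids <- names(decompositions)
  if (is.null(ids)) ids <- sprintf("P%d", seq_along(decompositions))
  m <- nrow(decompositions[[1]]$W)
  r_crit <- critical_r(m, alpha)

  prs <- combn(seq_along(decompositions), 2)
  rows <- vector("list", ncol(prs) * k * 4L)
  ri <- 0L
  for (pi in seq_len(ncol(prs))) {
    a <- decompositions[[prs[1, pi]]]
    b <- decompositions[[prs[2, pi]]]
    for (s in seq_len(k)) {
      xc <- xcorr_rmax(a$C[s, ], b$C[s, ], ...)
      vals <- list(
        list(metric = "W_cossim", value = cos_sim(a$W[, s], b$W[, s]),
             lag = NA_integer_, threshold = cossim_threshold),
        list(metric = "W_r", value = pearson_r(a$W[, s], b$W[, s]),
             lag = NA_integer_, threshold = r_crit),
        list(metric = "C_cossim", value = cos_sim(a$C[s, ], b$C[s, ]),
             lag = NA_integer_, threshold = cossim_threshold),
        list(metric = "C_rmax", value = xc$r_max, lag = xc$lag,
             threshold = rmax_threshold)
      )
      for (v in vals) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          participant1 = ids[prs[1, pi]], participant2 = ids[prs[2, pi]],
          synergy = s, metric = v$metric, value = v$value, lag = v$lag,
          threshold = v$threshold, stringsAsFactors = FALSE
        )
      }
    }
  }
  details <- do.call(rbind, rows[seq_len(ri)])

  summary <- do.call(rbind, lapply(split(
    details, list(details$synergy, details$metric)), function(g) {
      data.frame(synergy = g$synergy[1], metric = g$metric[1],
                 mean_value = mean(g$value), threshold = g$threshold[1],
                 similar = mean(g$value) > g$threshold[1],
                 stringsAsFactors = FALSE)
    }))
  summary <- summary[order(summary$synergy, summary$metric), ]
  rownames(summary) <- NULL
  list(details = details, summary = summary)
}
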
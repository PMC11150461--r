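#' Total variance accounted for (tVAF)
#'
#' `100 * (1 - ||E - W C||_F^2 / ||E||_F^2)` with the uncentred total sum of
#' squares, the standard definition in the synergy literature. May be
#' negative for pathological factors; not clamped.
#'
#' @param E data matrix (or `"envelope_matrix"`).
#' @param W,C factor matrices with conforming shapes.
#' @return tVAF in percent.
#' @export
tvaf <- function(E, W, C) {
  E <- as_E(E)
  if (nrow(W) != nrow(E) || ncol(C) != ncol(E) || ncol(W) != nrow(C)) {
    stop("non-conforming shapes for tVAF", call. = FALSE)
  }
  sst <- sum(E^2)
  if (sst == 0) stop("tVAF undefined: ||E||_F = 0", call. = FALSE)
  100 * (1 - sum((E - W %*% C)^2) / sst)
}

as_E <- function(E) {
  if (inherits(E, "envelope_matrix")) E$E else as.matrix(E)
}

#' Normalise a decomposition to unit-maximum synergy vectors
#'
#' Divides every column of `W` by its maximum and multiplies the matching
#' row of `C` by the same value, leaving the product `W %*% C` unchanged.
#'
#' @param W,C non-negative factor matrices.
#' @return List with `W` and `C`.
#' @export
normalize_decomposition <- function(W, C) {
  maxima <- apply(W, 2, max)
  zero <- which(maxima <= 0)
  if (length(zero) > 0) {
    stop("zero synergy vector(s) at index: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  list(W = sweep(W, 2, maxima, "/"), C = C * maxima)
}

#' Non-negative matrix factorisation with best-of-restarts selection
#'
#' Factorises a non-negative envelope matrix into synergy vectors `W`
#' (muscles x k, column maxima 1) and activation coefficients `C`
#' (k x timepoints), minimising the Frobenius reconstruction error. The
#' factorisation is repeated `restarts` times from random uniform
#' initialisations (each restart seeded deterministically from `seed`) and
#' the solution with the highest tVAF is returned.
#'
#' Solvers: `"hals"` (default) updates each synergy's weight column and
#' activation row by its exact non-negative least-squares minimiser given
#' the others; `"anls"` solves full columns/rows by an exact active-set NNLS
#' each sweep; `"mu"` uses multiplicative updates. All three decrease the
#' residual monotonically.
#'
#' @param E non-negative matrix or `"envelope_matrix"`.
#' @param k number of synergies, `1 <= k <= min(dim(E))`.
#' @param restarts number of random restarts.
#' @param seed integer seed controlling all restarts.
#' @param max_iter,tol iteration cap and relative residual-change tolerance.
#' @param method solver, one of `"hals"`, `"anls"`, `"mu"`.
#' @return A `"synergy_decomposition"`: `W`, `C`, `k`, `tvaf`, `restarts`,
#'   `best_restart_seed`, `converged`, `iterations`, `residual_trace`,
#'   `dead_components`.
#' @export
nmf <- function(E, k, restarts = 50L, seed = 1L, max_iter = 500L,
                tol = 1e-6, method = c("hals", "anls", "mu")) {
  method <- match.arg(method)
  E <- as_E(E)
  if (any(E < 0)) stop("E must be non-negative", call. = FALSE)
  k <- stop_if_not_count(k, "k")
  if (k > min(dim(E))) stop("k must not exceed min(dim(E))", call. = FALSE)
  restarts <- stop_if_not_count(restarts, "restarts")
  m <- nrow(E); n <- ncol(E)

  solver <- switch(method, hals = .nmf_hals_cpp, anls = .nmf_anls_cpp,
                   mu = .nmf_mu_cpp)
  seeds <- child_seeds(seed, restarts)
  best <- NULL
  best_tvaf <- -Inf
  for (r in seq_len(restarts)) {
    set.seed(seeds[r])
    W0 <- matrix(runif(m * k), m, k)
    C0 <- matrix(runif(k * n), k, n)
    fit <- solver(E, W0, C0, as.integer(max_iter), tol)
    fit_tvaf <- tvaf(E, fit$W, fit$C)
    if (fit_tvaf > best_tvaf) {
      best <- fit
      best_tvaf <- fit_tvaf
      best$seed <- seeds[r]
    }
  }

  W <- best$W; C <- best$C
  # degenerate components (can occur when k exceeds the effective rank):
  # replaced by a tiny fixed ramp so downstream normalisation is defined
  dead <- which(apply(W, 2, max) <= 0 | apply(C, 1, max) <= 0)
  if (length(dead) > 0) {
    for (j in dead) {
      W[, j] <- 1e-12 * seq_len(m) / m
      C[j, ] <- 0
    }
  }
  nd <- normalize_decomposition(W, C)

  structure(list(
    W = nd$W, C = nd$C, k = k, tvaf = best_tvaf, restarts = restarts,
    best_restart_seed = best$seed, converged = best$converged,
    iterations = best$iterations, residual_trace = best$residuals,
    dead_components = dead, method = method
  ), class = "synergy_decomposition")
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat(sprintf("synergy decomposition: %d muscles x %d timepoints, k = %d\n",
              nrow(x$W), ncol(x$C), x$k))
  cat(sprintf("tVAF = %.2f%% (best of %d restarts, %s, %s)\n", x$tvaf,
              x$restarts, x$method,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' tVAF curve over candidate synergy numbers
#'
#' Runs [nmf()] for every `k` in `k_range` (default `1:(muscles - 1)`).
#' Because each k is solved by randomly restarted local optimisation, a
#' higher k can occasionally score below a lower one; such local-minimum
#' artifacts are re-run once with fresh restarts and, if still lower,
#' clamped to the previous value and flagged, so the curve is
#' non-decreasing as the selection criteria assume.
#'
#' @param E non-negative matrix or `"envelope_matrix"`.
#' @param restarts,seed,max_iter,tol,method passed to [nmf()].
#' @param k_range candidate synergy numbers (increasing).
#' @return A `"tvaf_curve"`: `participant_id`, `task_id`, `k_range`,
#'   `tvaf_by_k`, `decompositions` (one per k), `clamped` (logical per k).
#' @export
tvaf_curve <- function(E, restarts = 50L, seed = 1L, k_range = NULL,
                       max_iter = 500L, tol = 1e-6, method = "hals") {
  participant_id <- if (inherits(E, "envelope_matrix")) E$participant_id else NA
  task_id <- if (inherits(E, "envelope_matrix")) E$task_id else NA
  E <- as_E(E)
  m <- nrow(E)
  if (is.null(k_range)) k_range <- seq_len(m - 1L)
  if (max(k_range) > min(dim(E))) {
    stop("k_range exceeds min(dim(E))", call. = FALSE)
  }
  seeds <- child_seeds(seed, 2L * length(k_range))

  decomps <- vector("list", length(k_range))
  tv <- numeric(length(k_range))
  clamped <- logical(length(k_range))
  for (i in seq_along(k_range)) {
    d <- nmf(E, k_range[i], restarts = restarts, seed = seeds[i],
             max_iter = max_iter, tol = tol, method = method)
    if (i > 1 && d$tvaf < tv[i - 1]) {
      d2 <- nmf(E, k_range[i], restarts = restarts,
                seed = seeds[length(k_range) + i],
                max_iter = max_iter, tol = tol, method = method)
      if (d2$tvaf > d$tvaf) d <- d2
    }
    decomps[[i]] <- d
    tv[i] <- d$tvaf
    if (i > 1 && tv[i] < tv[i - 1]) {
      tv[i] <- tv[i - 1]
      clamped[i] <- TRUE
    }
  }
  structure(list(
    participant_id = participant_id, task_id = task_id,
    k_range = as.integer(k_range), tvaf_by_k = tv,
    decompositions = decomps, clamped = clamped
  ), class = "tvaf_curve")
}
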
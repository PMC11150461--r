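# shared fixtures: tiny exact factorisations and small synthetic studies

# well-separated exact low-rank non-negative factorisation E = W %*% C
exact_factor_fixture <- function(m = 8, n = 40, k = 3, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(m * k, 0, 0.05), m, k)
  for (j in seq_len(k)) {
    idx <- ((j - 1) * floor(m / k) + 1):(j * floor(m / k))
    W[idx, j] <- runif(length(idx), 0.7, 1)
  }
  C <- matrix(0, k, n)
  centers <- seq(0.15, 0.85, length.out = k) * n
  for (j in seq_len(k)) {
    C[j, ] <- exp(-(seq_len(n) - centers[j])^2 / (2 * (n / 12)^2))
  }
  list(W = W, C = C, E = W %*% C)
}

# a synergy_decomposition built directly from known factors (no NMF)
fake_decomposition <- function(W, C) {
  nd <- musyn::normalize_decomposition(W, C)
  structure(list(W = nd$W, C = nd$C, k = ncol(W),
                 tvaf = musyn::tvaf(W %*% C, nd$W, nd$C),
                 restarts = 0L, best_restart_seed = NA_integer_,
                 converged = TRUE, iterations = 0L,
                 residual_trace = numeric(0), dead_components = integer(0),
                 method = "exact"),
            class = "synergy_decomposition")
}

# synergy-like weight matrix: a few dominant muscles over a small floor,
# the structure real synergy vectors exhibit
synergy_like_W <- function(m = 16, k = 4) {
  W <- matrix(runif(m * k, 0, 0.1), m, k)
  for (j in seq_len(k)) {
    dom <- sample.int(m, 4)
    W[dom, j] <- runif(4, 0.5, 1)
  }
  sweep(W, 2, apply(W, 2, max), "/")
}

# exhaustive one-to-one assignment maximising the total score (oracle)
exhaustive_assignment <- function(S) {
  k <- min(nrow(S), ncol(S))
  stopifnot(nrow(S) == ncol(S))
  best <- -Inf
  best_perm <- NULL
  for (p in musyn:::permutations_of(k)) {
    sc <- sum(S[cbind(seq_len(k), p)])
    if (sc > best) { best <- sc; best_perm <- p }
  }
  list(total = best, permutation = best_perm)
}

# exhaustive maximum-cardinality one-to-one matching above a threshold
exhaustive_threshold_matching <- function(S, threshold) {
  k1 <- nrow(S); k2 <- ncol(S)
  best <- 0L
  cols <- seq_len(k2)
  # enumerate injective partial maps row -> column via ordered subsets
  count_for <- function(rows_left, cols_free) {
    if (length(rows_left) == 0) return(0L)
    r <- rows_left[1]
    rest <- rows_left[-1]
    best_here <- count_for(rest, cols_free)   # skip row r
    for (cc in cols_free) {
      if (S[r, cc] > threshold) {
        best_here <- max(best_here,
                         1L + count_for(rest, setdiff(cols_free, cc)))
      }
    }
    best_here
  }
  count_for(seq_len(k1), cols)
}
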
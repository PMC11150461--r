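test_that("shared counting is exact on identical and unrelated synergy sets", {
  set.seed(60)
  W <- matrix(runif(16 * 4), 16, 4)
  cs <- count_shared(W, W)
  expect_equal(cs$n_shared, 4)
  expect_equal(cs$matched_pairs$synergy2[order(cs$matched_pairs$synergy1)],
               1:4)
  # orthogonal contrasts have pairwise correlation far below threshold
  W1 <- cbind(rep(c(1, 0), 8), rep(c(0, 1), 8))
  W2 <- cbind(rep(c(1, 0, 0, 0), 4), rep(c(0, 0, 1, 0), 4))
  expect_equal(count_shared(W1 + 0.01, W2 + 0.01)$n_shared, 0)
  expect_error(count_shared(W, W[1:8, ]), "mismatch")
})

test_that("count_shared is symmetric and obeys the one-to-one bound", {
  set.seed(61)
  for (rep in 1:20) {
    k1 <- sample(2:5, 1); k2 <- sample(2:5, 1)
    W1 <- matrix(runif(16 * k1), 16, k1)
    W2 <- matrix(runif(16 * k2), 16, k2)
    thr <- 0.3
    ab <- count_shared(W1, W2, thr)
    ba <- count_shared(W2, W1, thr)
    expect_equal(ab$n_shared, ba$n_shared)
    expect_lte(ab$n_shared, min(k1, k2))
    m1 <- ab$matched_pairs[order(ab$matched_pairs$synergy1), ]
    m2 <- ba$matched_pairs[order(ba$matched_pairs$synergy2), ]
    expect_equal(m1$synergy1, m2$synergy2)
    expect_equal(m1$synergy2, m2$synergy1)
  }
})

test_that("noisy copies are recognised as shared", {
  set.seed(62)
  hits <- 0
  for (s in 1:20) {
    W1 <- matrix(runif(16 * 4), 16, 4)
    W2 <- W1[, c(2, 3, 4, 1)] + matrix(rnorm(16 * 4, 0, 0.05), 16, 4)
    W2 <- pmax(W2, 0)
    W2[, 4] <- runif(16)                     # one unrelated synergy
    if (count_shared(W1, W2)$n_shared == 3) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("greedy threshold matching tracks the exhaustive optimum", {
  set.seed(63)
  agree <- 0
  n_inst <- 40
  thr <- critical_r(16, 0.01)
  for (rep in seq_len(n_inst)) {
    k <- sample(3:5, 1)
    # two tasks sharing k-1 perturbed synergies plus one unrelated each
    W1 <- synergy_like_W(16, k)
    W2 <- cbind(pmax(W1[, sample(k, k - 1)] +
                       matrix(rnorm(16 * (k - 1), 0, 0.1), 16, k - 1), 0),
                runif(16))[, sample(k)]
    S <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      S[i, j] <- pearson_r(W1[, i], W2[, j])
    }
    greedy_n <- nrow(musyn:::greedy_match(S, thr)$pairs)
    oracle_n <- exhaustive_threshold_matching(S, thr)
    expect_lte(greedy_n, oracle_n)
    if (greedy_n == oracle_n) agree <- agree + 1
  }
  expect_gte(agree / n_inst, 0.95)
})

test_that("relative shared counts follow the union formula", {
  expect_equal(pct_shared(4, 4, 4), 100)
  expect_equal(pct_shared(0, 3, 5), 0)
  expect_equal(pct_shared(2, 4, 4), 100 * 2 / 6)
  expect_equal(pct_shared(2, 3, 5), 100 * 2 / 6)
  # strictly increasing in the shared count
  vals <- vapply(0:4, pct_shared, 0, k1 = 4, k2 = 4)
  expect_true(all(diff(vals) > 0))
  expect_error(pct_shared(5, 4, 4), "min")
  expect_error(pct_shared(0, 0, 0), "undefined|k1")
})

test_that("sharedOA flags fully shared and fully disjoint designs", {
  set.seed(64)
  fx <- exact_factor_fixture(m = 16, n = 100, k = 4, seed = 64)
  same <- fake_decomposition(fx$W, fx$C)
  decs <- list(T1 = same, T2 = same, T3 = same)
  oa <- shared_oa(decs)
  expect_true(all(oa$pairs$n_shared == 4))
  expect_true(all(oa$pairs$pct_shared == 100))
  expect_equal(oa$all_task_shared, 1:4)

  # disjoint: different dominant muscles per task
  mk <- function(offset) {
    W <- matrix(0.01, 16, 2)
    W[offset + 1, 1] <- 1; W[offset + 2, 2] <- 1
    fake_decomposition(W, fx$C[1:2, ])
  }
  disj <- list(T1 = mk(0), T2 = mk(4), T3 = mk(8))
  oa2 <- shared_oa(disj)
  expect_true(all(oa2$pairs$n_shared == 0))
  expect_true(all(oa2$pairs$pct_shared == 0))
  expect_length(oa2$all_task_shared, 0)
})

test_that("sharedIND handles unequal synergy counts", {
  set.seed(65)
  W_common <- matrix(runif(16 * 2), 16, 2)
  W1 <- cbind(W_common, runif(16))                       # k1 = 3
  W2 <- cbind(W_common + rnorm(32, 0, 0.02), matrix(runif(16 * 3), 16, 3))
  W2 <- pmax(W2, 0)                                      # k2 = 5
  C1 <- matrix(runif(3 * 50), 3, 50)
  C2 <- matrix(runif(5 * 50), 5, 50)
  res <- shared_ind(list(A = fake_decomposition(W1, C1),
                         B = fake_decomposition(W2, C2)))
  row <- res$pairs[1, ]
  expect_equal(row$k1, 3)
  expect_equal(row$k2, 5)
  expect_gte(row$n_shared, 2)
  if (row$n_shared == 2) expect_equal(row$pct_shared, 100 * 2 / 6)
  expect_error(shared_oa(list(A = fake_decomposition(W1, C1),
                              B = fake_decomposition(W2, C2))),
               "common k")
})

test_that("cross-task reconstruction of identical decompositions is exact", {
  fx <- exact_factor_fixture(m = 16, n = 200, k = 4, seed = 66)
  same <- fake_decomposition(fx$W, fx$C)
  decs <- list(T1 = same, T2 = same, T3 = same)
  Es <- list(T1 = fx$E, T2 = fx$E, T3 = fx$E)
  out <- cross_task_reconstruction(decs, Es)
  # 3 tasks: every task reconstructed from the 2 other tasks, per direction
  counts <- table(out$target, out$direction) / 4   # 4 synergies per result
  expect_true(all(counts == 2))
  expect_true(all(abs(out$tvaf_rec - same$tvaf) < 1e-6))
  expect_true(all(out$cossim > 1 - 1e-9))
})
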
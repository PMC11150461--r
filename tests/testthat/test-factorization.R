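test_that("tVAF matches hand arithmetic and handles edge cases", {
  E <- matrix(c(1, 3, 2, 4), 2, 2)            # [[1,2],[3,4]] row-wise
  W <- diag(2)
  C <- matrix(c(1, 3, 2, 0), 2, 2)            # WC = [[1,2],[3,0]]
  expect_equal(tvaf(E, W, C), 100 * (1 - 16 / 30))
  expect_equal(tvaf(E, E, diag(2)), 100)
  expect_equal(tvaf(E, matrix(0, 2, 2), matrix(0, 2, 2)), 0)
  expect_error(tvaf(matrix(0, 2, 2), W, C), "undefined")
  expect_error(tvaf(E, diag(3), C), "shapes")
})

test_that("decomposition normalisation rescales without changing the product", {
  set.seed(2)
  W <- matrix(runif(16 * 4), 16, 4)
  C <- matrix(runif(4 * 600), 4, 600)
  W[, 2] <- W[, 2] / max(W[, 2]) * 4          # column max exactly 4
  nd <- normalize_decomposition(W, C)
  expect_equal(unname(apply(nd$W, 2, max)), rep(1, 4))
  expect_equal(nd$W[, 2], W[, 2] / 4)
  expect_equal(nd$C[2, ], C[2, ] * 4)
  expect_lt(max(abs(nd$W %*% nd$C - W %*% C)), 1e-12)
  # tVAF is invariant under the rescaling
  E <- W %*% C + 0.01
  expect_equal(tvaf(E, W, C), tvaf(E, nd$W, nd$C), tolerance = 1e-9)
  # already-normalised input is unchanged
  nd2 <- normalize_decomposition(nd$W, nd$C)
  expect_equal(nd2$W, nd$W)
  W[, 3] <- 0
  expect_error(normalize_decomposition(W, C), "3")
})

test_that("NMF recovers exact low-rank structure", {
  fx <- exact_factor_fixture(m = 9, n = 60, k = 3, seed = 8)
  for (method in c("hals", "anls", "mu")) {
    d <- nmf(fx$E, k = 3, restarts = 10, seed = 4, method = method)
    expect_gte(d$tvaf, 99.9)
  }
  # rank-1: W column proportional to the true left vector
  u <- runif(6, 0.1, 1); v <- runif(30, 0.1, 1)
  d1 <- nmf(outer(u, v), k = 1, restarts = 5, seed = 1)
  expect_gte(d1$tvaf, 99.99)
  expect_gt(cos_sim(d1$W[, 1], u), 0.999)
})

test_that("restarts are deterministic and the residual decreases monotonically", {
  set.seed(10)
  E <- matrix(runif(8 * 30), 8, 30)
  a <- nmf(E, k = 3, restarts = 8, seed = 99)
  b <- nmf(E, k = 3, restarts = 8, seed = 99)
  expect_identical(a$W, b$W)
  expect_identical(a$C, b$C)
  expect_identical(a$best_restart_seed, b$best_restart_seed)
  for (method in c("hals", "anls", "mu")) {
    d <- nmf(E, k = 3, restarts = 3, seed = 5, method = method)
    expect_true(all(diff(d$residual_trace) <= 1e-9))
  }
  # tVAF is recomputable from the stored factors
  expect_equal(a$tvaf, tvaf(E, a$W, a$C), tolerance = 1e-9)
})

test_that("tVAF is invariant to a global rescaling of the data", {
  set.seed(11)
  E <- matrix(runif(8 * 40), 8, 40)
  d1 <- nmf(E, k = 2, restarts = 6, seed = 42)
  d2 <- nmf(2 * E, k = 2, restarts = 6, seed = 42)
  expect_equal(d1$tvaf, d2$tvaf, tolerance = 1e-6)
})

test_that("best-of-restarts residual matches an independent NMF implementation", {
  set.seed(12)
  E <- matrix(runif(6 * 20), 6, 20)
  d <- nmf(E, k = 2, restarts = 50, seed = 3)
  ours <- sum((E - d$W %*% d$C)^2)

  csv <- tempfile(fileext = ".csv")
  write.table(E, csv, row.names = FALSE, col.names = FALSE, sep = ",")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.decomposition import NMF",
    "E = np.loadtxt(sys.argv[1], delimiter=',')",
    "best = np.inf",
    "for r in range(50):",
    "    m = NMF(n_components=2, init='random', random_state=r,",
    "            solver='cd', max_iter=5000, tol=1e-10)",
    "    W = m.fit_transform(E)",
    "    res = np.sum((E - W @ m.components_)**2)",
    "    best = min(best, res)",
    "print(float(best))"
  ), script)
  ref <- suppressWarnings(
    try(system2("python", c(script, csv), stdout = TRUE, stderr = FALSE),
        silent = TRUE))
  expect_false(inherits(ref, "try-error"))
  ref <- as.numeric(ref[length(ref)])
  expect_true(is.finite(ref))
  expect_lte(ours, ref * 1.01)
})

test_that("tVAF curves are monotone and saturate at the true rank", {
  fx <- exact_factor_fixture(m = 8, n = 60, k = 3, seed = 14)
  cv <- tvaf_curve(fx$E, restarts = 10, seed = 6, k_range = 1:6)
  expect_gte(cv$tvaf_by_k[3], 99.9)
  expect_true(all(cv$tvaf_by_k[4:6] >= cv$tvaf_by_k[3]))
  expect_true(all(diff(cv$tvaf_by_k) >= 0))
  expect_error(tvaf_curve(fx$E, k_range = 1:50), "k_range")
})

test_that("synthetic tVAF curves are concave near the origin", {
  hits <- 0
  n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    cf <- synthetic_config(participants = 1, tasks = 1, trials_per_task = 4,
                           noise_sd = 0.05)
    ds <- generate_dataset(cf, seed = 400 + s)
    env <- process_dataset(ds)
    cv <- tvaf_curve(env$P1$T1, restarts = 10, seed = s, k_range = 1:9)
    d2 <- cv$tvaf_by_k[2] - cv$tvaf_by_k[1]
    d8 <- cv$tvaf_by_k[9] - cv$tvaf_by_k[8]
    if (d2 > d8) hits <- hits + 1
  }
  expect_gt(hits, n_seeds / 2)
})

test_that("decompositions round-trip through JSON", {
  fx <- exact_factor_fixture(m = 6, n = 30, k = 2, seed = 15)
  d <- nmf(fx$E, k = 2, restarts = 4, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_decomposition(d, path)
  back <- read_decomposition(path)
  expect_equal(back$W, d$W, tolerance = 1e-12)
  expect_equal(back$C, d$C, tolerance = 1e-12)
  expect_equal(back$tvaf, d$tvaf)
  expect_equal(back$k, d$k)
  expect_equal(tvaf(fx$E, back$W, back$C), d$tvaf, tolerance = 1e-9)
})
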
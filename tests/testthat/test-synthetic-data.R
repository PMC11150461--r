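test_that("configuration validation rejects impossible designs", {
  expect_error(synthetic_config(participants = 0), "participants")
  expect_error(synthetic_config(trials_per_task = -1), "trials_per_task")
  expect_error(synthetic_config(noise_sd = -0.1), "noise_sd")
  expect_error(synthetic_config(k_per_task = 16, muscles = 16), "k_per_task")
  expect_error(synthetic_config(events = c(700, 200)), "events")
  # shared_map must reference ids 1..max without gaps, unique per task
  expect_error(synthetic_config(tasks = 2, k_per_task = 2,
                                shared_map = matrix(c(1, 3, 1, 3), 2, 2)),
               "shared_map")
  expect_error(synthetic_config(tasks = 2, k_per_task = 2,
                                shared_map = matrix(1L, 3, 2)),
               "shared_map")
})

test_that("generation is bitwise deterministic for a fixed seed", {
  cf <- synthetic_config(participants = 1, tasks = 2, trials_per_task = 2,
                         muscles = 6, k_per_task = 2, n_samples = 400,
                         events = c(80, 320))
  a <- generate_dataset(cf, seed = 7)
  b <- generate_dataset(cf, seed = 7)
  expect_identical(a$trials[[1]]$signals, b$trials[[1]]$signals)
  expect_identical(a$ground_truth$W_pool, b$ground_truth$W_pool)
  c <- generate_dataset(cf, seed = 8)
  expect_false(identical(a$trials[[1]]$signals, c$trials[[1]]$signals))
})

test_that("ground truth satisfies the declared invariants", {
  cf <- synthetic_config(participants = 2, tasks = 3, trials_per_task = 2)
  ds <- generate_dataset(cf, seed = 3)
  gt <- ds$ground_truth
  for (p in 1:2) {
    for (t in 1:3) {
      W <- true_synergies(gt, p, t, normalized = FALSE)
      expect_true(all(W >= 0))
      expect_equal(unname(apply(W, 2, max)), rep(1, ncol(W)))
      for (Ct in gt$C_true[[p]][[t]]) expect_true(all(Ct >= 0))
    }
  }
  expect_true(all(gt$shared_map >= 1) &&
                all(gt$shared_map <= max(gt$shared_map)))
  # events bracket the analysed phase inside every trial
  for (tr in ds$trials) {
    expect_true(tr$events[1] >= 1 && tr$events[2] <= ncol(tr$signals))
  }
})

test_that("noiseless data yields near-perfect synergy recovery", {
  cf <- synthetic_config(participants = 1, tasks = 1, trials_per_task = 6,
                         noise_sd = 0, jitter_sd = 0)
  ds <- generate_dataset(cf, seed = 21)
  env <- process_dataset(ds)
  d <- nmf(env$P1$T1, k = 4, restarts = 20, seed = 5)
  W_true <- true_synergies(ds$ground_truth, 1, 1)
  ms <- match_synergies(d$W, W_true)
  expect_true(all(ms$cossim > 0.95))
})

test_that("the intended envelope survives the preprocessing chain", {
  cf <- synthetic_config(participants = 1, tasks = 1, trials_per_task = 2,
                         noise_sd = 0, jitter_sd = 0)
  ds <- generate_dataset(cf, seed = 13)
  env <- process_dataset(ds)
  gt <- ds$ground_truth
  E <- env$P1$T1$E
  for (trial in 1:2) {
    intended <- gt$env_true[[1]][[1]][[trial]]
    block <- E[, (trial - 1) * 100 + 1:100]
    for (mu in seq_len(nrow(E))) {
      expect_gt(cor(intended[mu, ], block[mu, ]), 0.9)
    }
  }
})

test_that("recovery quality degrades monotonically with envelope noise", {
  noise_levels <- c(0, 0.15, 0.4)
  n_rep <- 10
  scores <- expand.grid(noise = noise_levels, rep = seq_len(n_rep))
  scores$cossim <- NA_real_
  for (i in seq_len(nrow(scores))) {
    cf <- synthetic_config(participants = 1, tasks = 1, trials_per_task = 3,
                           k_per_task = 3, noise_sd = scores$noise[i])
    ds <- generate_dataset(cf, seed = 100 + i)
    env <- process_dataset(ds)
    d <- nmf(env$P1$T1, k = 3, restarts = 10, seed = i)
    scores$cossim[i] <- match_synergies(
      d$W, true_synergies(ds$ground_truth, 1, 1))$mean_cossim
  }
  means <- tapply(scores$cossim, scores$noise, mean)
  # one-sided trend test: recovery decreases with noise
  fit <- summary(lm(cossim ~ noise, data = scores))
  slope_t <- fit$coefficients["noise", "t value"]
  p_one_sided <- pt(slope_t, df = fit$df[2])
  expect_lt(p_one_sided, 0.05)
  expect_true(means[1] >= means[length(means)])
})

test_that("a synergy declared shared across all tasks is detected on noiseless data", {
  cf <- synthetic_config(participants = 1, tasks = 3, trials_per_task = 4,
                         noise_sd = 0, jitter_sd = 0, n_shared_all = 1)
  ds <- generate_dataset(cf, seed = 31)
  env <- process_dataset(ds)
  dec <- lapply(names(env$P1), function(t) {
    nmf(env$P1[[t]], k = 4, restarts = 20, seed = match(t, names(env$P1)))
  })
  names(dec) <- names(env$P1)
  oa <- shared_oa(dec)
  expect_true(all(oa$pairs$n_shared >= 1))
  expect_true(all(vapply(oa$matchings, function(mp) all(mp$r > 0.623), TRUE)))
  expect_length(oa$all_task_shared, 1)
})

test_that("datasets round-trip through the delimited-text layout", {
  cf <- synthetic_config(participants = 1, tasks = 2, trials_per_task = 2,
                         muscles = 6, k_per_task = 2, n_samples = 300,
                         events = c(60, 240))
  ds <- generate_dataset(cf, seed = 2)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_dataset(manifest)
  expect_equal(length(back$trials), length(ds$trials))
  expect_equal(back$trials[[3]]$signals, ds$trials[[3]]$signals,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$trials[[3]]$events, ds$trials[[3]]$events)
  expect_identical(back$trials[[3]]$muscle_names, ds$trials[[3]]$muscle_names)
})
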
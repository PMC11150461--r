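test_that("envelope of an all-zero signal is zero and errors are explicit", {
  expect_equal(emg_envelope(rep(0, 1000), 1000), rep(0, 1000))
  expect_error(emg_envelope(c(rep(0, 500), NA, rep(0, 499)), 1000),
               "non-finite")
  expect_error(emg_envelope(rep(0, 20), 1000), "too short")
  expect_error(emg_envelope(rep(0, 1000), 790), "sampling_rate")
})

test_that("band-pass rejects sub-band content and passes in-band content", {
  fs <- 1000
  t <- seq_len(2000) / fs
  slow <- sin(2 * pi * 2 * t)            # 2 Hz: below the 10 Hz edge
  env_slow <- emg_envelope(slow, fs)
  interior <- 500:1500
  expect_lt(max(env_slow[interior]), 0.05)

  A <- 1.7                               # 50 Hz: well inside the band
  fast <- A * sin(2 * pi * 50 * t)
  env_fast <- emg_envelope(fast, fs)
  plateau <- 2 * A / pi                  # mean of the rectified sine
  expect_true(all(abs(env_fast[interior] - plateau) < 0.05 * plateau))
})

test_that("envelope is invariant to a constant offset (demeaning)", {
  set.seed(4)
  fs <- 1000
  x <- rnorm(1500)
  e1 <- emg_envelope(x, fs)
  e2 <- emg_envelope(x + 3.7, fs)
  # away from the filter warm-up edges the offset is fully removed
  interior <- 400:1100
  expect_lt(max(abs(e1 - e2)[interior]), 0.05 * max(e1))
})

test_that("time normalisation preserves identity, linearity and endpoints", {
  x <- rnorm(300)
  # a segment of exactly 100 samples maps to itself
  expect_equal(time_normalize(x, c(51, 150)), x[51:150])
  # linear ramp stays linear
  ramp <- seq(0, 1, length.out = 200)
  out <- time_normalize(c(rep(0, 10), ramp, rep(0, 10)), c(11, 210))
  expect_equal(out, seq(0, 1, length.out = 100), tolerance = 1e-9)
  expect_error(time_normalize(x, c(0, 100)), "bounds")
  expect_error(time_normalize(x, c(200, 400)), "bounds")
  expect_error(time_normalize(x, c(10, 11)), "at least 3")
})

test_that("time normalisation error matches the interpolation bound", {
  # t^2 on 500 samples: linear interpolation error <= h^2/8 * max|f''|
  n <- 500
  tt <- seq(0, 1, length.out = n)
  y <- tt^2
  out <- time_normalize(y, c(1, n))
  grid <- seq(0, 1, length.out = 100)
  h <- 1 / (n - 1)
  expect_true(all(abs(out - grid^2) <= h^2 / 8 * 2 + 1e-12))
})

test_that("assembly concatenates trials and normalises across tasks", {
  m_names <- c("m1", "m2")
  # muscle 1 peaks at 10 in task B and 5 in task A; muscle 2 constant 5
  trialA <- rbind(seq(0, 5, length.out = 10), rep(5, 10))
  trialB <- rbind(seq(0, 10, length.out = 10), rep(2, 10))
  out <- assemble_envelopes(list(list(trialA, trialA), list(trialB)),
                            m_names, task_ids = c("A", "B"))
  expect_equal(dim(out$A$E), c(2, 20))
  expect_equal(out$A$trial_boundaries, c(1, 11))
  expect_equal(max(out$A$E[1, ]), 0.5)
  expect_equal(max(out$B$E[1, ]), 1.0)
  expect_equal(out$A$normalization_factors, c(10, 5))
  # one task, one trial, constant envelope -> row of ones
  single <- assemble_envelopes(list(list(rbind(rep(5, 8)))), "m1")
  expect_equal(single$T1$E[1, ], rep(1, 8))
  # block slicing reproduces the normalised trial
  expect_equal(out$A$E[, 11:20], trialA / c(10, 5), ignore_attr = TRUE)
})

test_that("assembly reports degenerate muscles and shape mismatches by name", {
  ok <- rbind(rep(1, 5), rep(0, 5))
  expect_error(assemble_envelopes(list(list(ok)), c("good", "flat_muscle")),
               "flat_muscle")
  expect_error(
    assemble_envelopes(list(list(ok, ok[1, , drop = FALSE])), c("a", "b")),
    "muscle count mismatch")
})

test_that("permuting muscle order permutes envelope rows identically", {
  cf <- synthetic_config(participants = 1, tasks = 1, trials_per_task = 2,
                         muscles = 6, k_per_task = 2, n_samples = 400,
                         events = c(80, 320))
  ds <- generate_dataset(cf, seed = 5)
  env1 <- process_dataset(ds)$P1$T1
  perm <- c(3, 1, 6, 2, 5, 4)
  ds2 <- ds
  for (i in seq_along(ds2$trials)) {
    ds2$trials[[i]]$signals <- ds2$trials[[i]]$signals[perm, ]
    ds2$trials[[i]]$muscle_names <- ds2$trials[[i]]$muscle_names[perm]
  }
  env2 <- process_dataset(ds2)$P1$T1
  expect_equal(env2$E, env1$E[perm, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("generated studies produce 16 x (trials * 100) matrices with unit cross-task maxima", {
  cf <- synthetic_config(participants = 1, tasks = 3, trials_per_task = 6)
  ds <- generate_dataset(cf, seed = 17)
  env <- process_dataset(ds)$P1
  expect_length(env, 3)
  for (t in names(env)) expect_equal(dim(env[[t]]$E), c(16, 600))
  global_max <- apply(do.call(cbind, lapply(env, `[[`, "E")), 1, max)
  expect_equal(global_max, rep(1, 16), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(vapply(env, function(e) all(e$E >= 0 & e$E <= 1), TRUE)))
})
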
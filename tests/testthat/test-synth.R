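test_that("activation curves follow the ramp-and-hold trapezoid", {
  p <- protocol_spec(sampling_rate = 1000, trial_duration = 6,
                     ramp_duration = 3, target_level = 0.4)
  curves <- make_activation_curves(p, 2, shape_jitter = 0, seed = 1)
  expect_equal(dim(curves), c(2, 6000))
  # linear ramp midpoint: half the target
  mid <- round(1.5 * p$sampling_rate) + 1
  expect_equal(curves[1, mid], 0.2, tolerance = 1e-3)
  # plateau is constant at the target
  plateau <- curves[1, 3002:6000]
  expect_true(all(abs(plateau - 0.4) < 1e-12))
  # curves identical across components when jitter is off
  expect_equal(curves[1, ], curves[2, ])
})

test_that("curve jitter is bounded by shape_jitter relative to the target", {
  p <- protocol_spec(target_level = 0.4)
  trap <- make_activation_curves(p, 1, shape_jitter = 0, seed = 1)
  for (seed in 1:5) {
    jittered <- make_activation_curves(p, 1, shape_jitter = 0.1, seed = seed)
    expect_lte(max(abs(jittered - trap)) / p$target_level, 0.1 + 1e-12)
    expect_true(all(jittered >= 0))
  }
  # deterministic given seed
  expect_identical(make_activation_curves(p, 2, 0.1, seed = 7),
                   make_activation_curves(p, 2, 0.1, seed = 7))
})

test_that("invalid curve arguments are rejected", {
  p <- protocol_spec()
  expect_error(make_activation_curves(p, 0), class = "fosemg_invalid_argument")
  expect_error(make_activation_curves(p, 2, shape_jitter = 1),
               class = "fosemg_invalid_argument")
  expect_error(protocol_spec(trial_duration = -1),
               class = "fosemg_invalid_argument")
  expect_error(protocol_spec(ramp_duration = 10),
               class = "fosemg_invalid_argument")
})

test_that("activation patterns peak at their centers with a positive floor", {
  g <- grid_spec()
  W <- make_activation_patterns(g, 2, list(c(2, 3), c(4, 8)), width = 1)
  expect_equal(dim(W), c(32, 2))
  # peak location after reshaping to the grid (row-major flattening)
  img1 <- matrix(W[, 1], g$n_rows, g$n_cols, byrow = TRUE)
  expect_equal(as.integer(which(img1 == max(img1), arr.ind = TRUE)), c(2L, 3L))
  img2 <- matrix(W[, 2], g$n_rows, g$n_cols, byrow = TRUE)
  expect_equal(as.integer(which(img2 == max(img2), arr.ind = TRUE)), c(4L, 8L))
  expect_true(all(W > 0))
})

test_that("degenerate and corner patterns behave as constructed", {
  g <- grid_spec()
  # width -> 0 limit: indicator of the center electrode plus floor
  W0 <- make_activation_patterns(g, 1, list(c(3, 5)), width = 0, floor = 0.02)
  ch <- (3 - 1) * 8 + 5
  expect_equal(W0[ch, 1], 1.02)
  expect_true(all(abs(W0[-ch, 1] - 0.02) < 1e-15))
  # opposite corners at width 1: nearly uncorrelated columns
  Wc <- make_activation_patterns(g, 2, list(c(1, 1), c(4, 8)), width = 1)
  expect_lt(cor(Wc[, 1], Wc[, 2]), 0.2)
  expect_error(make_activation_patterns(g, 1, list(c(5, 1))),
               class = "fosemg_invalid_argument")
})

test_that("synthesized HD-SEMG is an amplitude-modulated mixture", {
  p <- short_protocol()
  nt <- n_samples(p)
  curves <- make_activation_curves(p, 1, 0, seed = 1)
  g <- grid_spec(2, 2)
  ones <- matrix(1, 4, 1)
  s <- synthesize_hdsemg(ones, curves, p$sampling_rate,
                         carrier_band = c(20, 200), noise_sd = 0, seed = 3)
  expect_equal(dim(s), c(4, nt))
  # all channels carry the same carrier realization
  expect_equal(s[1, ], s[4, ])
  # near-zero channel means
  expect_lt(abs(mean(s[1, ])), 3 * sd(s[1, ]) / sqrt(nt))
  # linearity: doubling a pattern column doubles the contribution
  s2 <- synthesize_hdsemg(2 * ones, curves, p$sampling_rate,
                          carrier_band = c(20, 200), noise_sd = 0, seed = 3)
  expect_equal(s2, 2 * s, tolerance = 1e-12, ignore_attr = TRUE)
  # all-zero curves give pure noise
  s0 <- synthesize_hdsemg(ones, 0 * curves, p$sampling_rate, noise_sd = 0.1,
                          seed = 3)
  expect_lt(max(abs(rowMeans(s0))), 0.05)
  expect_error(synthesize_hdsemg(ones, rbind(curves, curves)),
               class = "fosemg_invalid_argument")
})

test_that("rectified and filtered channels recover the modulating curve", {
  p <- protocol_spec(trial_duration = 4, ramp_duration = 2)
  curves <- make_activation_curves(p, 1, 0.1, seed = 2)
  W <- matrix(c(1, 0.5), 2, 1)
  s <- synthesize_hdsemg(W, curves, p$sampling_rate, noise_sd = 0, seed = 5)
  env <- lowpass_envelope(rectify(s[1, ]), p$sampling_rate)
  expect_gt(cor(env, curves[1, ]), 0.95)
})

test_that("synthetic force traces evaluate the named pool functions", {
  h_bi <- random_activation(200, 1)
  h_tr <- random_activation(200, 2)
  expect_equal(synthesize_force(h_bi, h_tr, c(bias = 0.5), noise_sd = 0),
               rep(0.5, 200))
  expect_equal(synthesize_force(h_bi, h_tr, c(H_BI = 1), noise_sd = 0), h_bi)
  y <- synthesize_force(h_bi, h_tr, c(H_BI = 0.5, "H_TR^2" = 0.3), noise_sd = 0)
  expect_equal(y, 0.5 * h_bi + 0.3 * h_tr^2)
  expect_error(synthesize_force(h_bi, h_tr, c(nonsense = 1)),
               class = "fosemg_invalid_argument")
})

test_that("lever relation returns the balancing wrist force", {
  expect_equal(lever_force(10, 2, 2), -10)
  expect_equal(lever_force(0, 1, 3), 0)
  expect_equal(lever_force(6, 2, 3), -4)
  expect_error(lever_force(1, 1, 0), class = "fosemg_invalid_argument")
})

test_that("trial-set simulation is reproducible and structurally sound", {
  p <- short_protocol(reps = 2)
  a <- simulate_trial_set(protocol = p, seed = 11)
  b <- simulate_trial_set(protocol = p, seed = 11)
  expect_identical(a, b)
  expect_length(a$repetitions, 2)
  expect_equal(dim(a$repetitions[[1]]$agonist), c(32, n_samples(p)))
  expect_length(a$repetitions[[1]]$force, n_samples(p))
  # different repetitions use fresh carriers
  expect_false(identical(a$repetitions[[1]]$agonist, a$repetitions[[2]]$agonist))
})
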
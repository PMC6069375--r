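test_that("PCA recovers a rank-1 spatial structure", {
  set.seed(2)
  w <- c(3, 1, 0.5, 2, 0.1, 1.5, 0.7, 0.2)
  src <- rnorm(2000)
  s <- outer(w, src) + matrix(rnorm(8 * 2000, sd = 0.01), 8)
  d <- decompose_pca(s, 2, sampling_rate = 1000)
  cosine <- abs(sum(d$patterns[, 1] * w)) / sqrt(sum(w^2))
  expect_gt(cosine, 0.99)
  expect_true(all(d$curves >= 0))
  # eigenvalue ordering is non-increasing
  expect_true(all(diff(d$eigenvalues) <= 1e-9))
  expect_error(decompose_pca(s, 9), class = "fosemg_invalid_argument")
})

test_that("PCA curves are invariant to a global sign flip of the data", {
  set.seed(3)
  s <- matrix(rnorm(6 * 800), 6) * c(3, 1, 2, 0.5, 1, 1)
  d1 <- decompose_pca(s, 2, 1000)
  d2 <- decompose_pca(-s, 2, 1000)
  expect_equal(d1$curves, d2$curves, tolerance = 1e-8)
})

test_that("FastICA recovers a known mixing up to permutation and scale", {
  set.seed(5)
  nt <- 4000
  sources <- rbind(rnorm(nt) * exp(rnorm(nt)), runif(nt, -1, 1)^3)
  A <- matrix(c(1, 0.4, 0.3, 1), 2)
  X <- A %*% sources
  d <- decompose_ica(X, 2, seed = 1, sampling_rate = 1000)
  for (k in 1:2) {
    cosines <- abs(apply(A, 2, function(a)
      sum(a * d$patterns[, k]) / sqrt(sum(a^2) * sum(d$patterns[, k]^2))))
    expect_gt(max(cosines), 0.95)
  }
  # determinism given seed
  d2 <- decompose_ica(X, 2, seed = 1, sampling_rate = 1000)
  expect_identical(d$patterns, d2$patterns)
  expect_true(all(d$curves >= 0))
})

test_that("one-component ICA reduces to the dominant whitened direction", {
  set.seed(6)
  s <- rbind(3 * rnorm(1500)^3, 0.05 * rnorm(1500))
  d <- decompose_ica(s, 1, seed = 2, sampling_rate = 1000)
  expect_equal(d$n_components, 1)
  expect_length(d$curves[1, ], 1500)
})

test_that("NMF objective is monotone and exact factorizations are recovered", {
  set.seed(7)
  # exact rank-1 nonnegative input
  e1 <- outer(runif(10, 0.2, 1), runif(300, 0, 2))
  d1 <- decompose_nmf(e1, 1, seed = 1, max_iter = 5000, tol = 1e-12)
  rel <- utils::tail(d1$objective_path, 1) / sum(e1^2)
  expect_lte(rel, 1e-6)
  # monotone non-increasing objective on every tested input
  for (seed in 1:5) {
    set.seed(seed)
    e <- matrix(runif(12 * 60), 12)
    d <- decompose_nmf(e, 3, seed = seed)
    expect_true(all(diff(d$objective_path) <= 1e-8 * d$objective_path[1]))
    expect_true(all(d$patterns >= 0))
    expect_true(all(d$curves >= 0))
  }
  expect_error(decompose_nmf(matrix(c(-1, 1, 2, 3), 2), 1),
               class = "fosemg_invalid_argument")
})

test_that("NMF separates two spatially distinct generator components", {
  p <- short_protocol()
  g <- grid_spec()
  W <- make_activation_patterns(g, 2, list(c(1, 2), c(4, 7)), width = 0.8)
  # temporally distinct drives: ramp-up versus ramp-down
  nt <- n_samples(p)
  up <- 0.4 * pmin((seq_len(nt) - 1) / (nt / 2), 1)
  curves <- rbind(up, rev(up))
  s <- synthesize_hdsemg(W, curves, p$sampling_rate, noise_sd = 0.01, seed = 9)
  E <- pmax(lowpass_envelope(rectify(s), p$sampling_rate), 0)
  d <- decompose_nmf(E, 2, seed = 4)
  # best-permutation match between recovered and true curves
  cors <- abs(cor(t(d$curves), t(curves)))
  best <- max(min(cors[1, 1], cors[2, 2]), min(cors[1, 2], cors[2, 1]))
  expect_gt(best, 0.9)
})

test_that("activation signals are normalized sums of curves", {
  curves <- rbind(c(1, 0), c(0, 1))
  expect_equal(activation_signal(curves), c(1, 1))
  one <- matrix(random_activation(50, 11), 1)
  expect_equal(activation_signal(one), normalize_to_max(one[1, ]))
  # scale invariance: duplicating a curve leaves the shape unchanged
  expect_equal(activation_signal(rbind(one, one)), activation_signal(one))
  expect_error(activation_signal(matrix(0, 2, 5)),
               class = "fosemg_invalid_argument")
})

test_that("factorized activation tracks the true drive better than a random control", {
  p <- short_protocol()
  g <- grid_spec()
  wins <- c(pca = 0, ica = 0, nmf = 0)
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    W <- make_activation_patterns(g, 2, list(c(2, 2), c(3, 7)),
                                  width = c(2, 0.8), gains = c(1, 0.8))
    curves <- make_activation_curves(p, 2, shape_jitter = 0.3, seed = 100 + r)
    s <- synthesize_hdsemg(W, curves, p$sampling_rate, noise_sd = 0.03,
                           seed = 100 + r)
    truth <- colSums(curves)
    # control: activation from a random (signed) pattern projection
    set.seed(200 + r)
    ctrl <- pmax(lowpass_envelope(rectify(drop(rnorm(32) %*% s)),
                                  p$sampling_rate), 0)
    c_ctrl <- cor(ctrl, truth)
    for (m in names(wins)) {
      h <- switch(m,
        pca = activation_signal(decompose_pca(s, 2, p$sampling_rate)),
        ica = activation_signal(decompose_ica(s, 2, seed = r,
                                              sampling_rate = p$sampling_rate)),
        nmf = activation_signal(decompose_nmf(
          pmax(lowpass_envelope(rectify(s), p$sampling_rate), 0), 2, seed = r)))
      if (cor(h, truth) > c_ctrl) wins[m] <- wins[m] + 1
    }
  }
  expect_true(all(wins >= 0.9 * n_rep))
})
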
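test_that("candidate pools have the documented size and order", {
  h_bi <- random_activation(100, 1)
  h_tr <- random_activation(100, 2)
  pool <- candidate_pool(h_bi, h_tr)
  expect_length(pool$names, 14)
  expect_equal(pool$names[1], "bias")
  expect_equal(pool$columns[, "bias"], rep(1, 100))
  # algebraic identities between columns
  pool_same <- candidate_pool(h_bi, h_bi)
  expect_equal(pool_same$columns[, "H_BI*H_TR"], pool_same$columns[, "H_BI^2"])
  pool_zero <- candidate_pool(h_bi, rep(0, 100))
  expect_equal(pool_zero$columns[, "sqrt(H_BI*H_TR)"], rep(0, 100))
  single <- candidate_pool_single(h_bi)
  expect_length(single$names, 6)
  # powers are ordered on the unit interval
  expect_true(all(single$columns[, "H^3"] <= single$columns[, "H^2"] + 1e-15))
  expect_true(all(single$columns[, "H^2"] <= single$columns[, "H"] + 1e-15))
  expect_error(candidate_pool(h_bi, h_tr[-1]), class = "fosemg_invalid_argument")
  expect_error(candidate_pool(-h_bi, h_tr), class = "fosemg_invalid_argument")
})

test_that("sigmoid basis is monotone and bounded", {
  x <- seq(-10, 10, length.out = 200)
  s <- sigm(x)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
})

test_that("a constant target is represented exactly by the bias", {
  h <- random_activation(150, 3)
  pool <- candidate_pool(h, h^1.5)
  m <- fos_fit(rep(3, 150), pool)
  expect_equal(m$selected[1], "bias")
  expect_equal(m$a, 3, tolerance = 1e-12)
  expect_equal(utils::tail(m$training_rmsd_path, 1), 0, tolerance = 1e-10)
})

test_that("FOS coefficients equal OLS on the selected columns", {
  for (seed in 1:10) {
    h_bi <- random_activation(300, seed)
    h_tr <- random_activation(300, seed + 50)
    pool <- candidate_pool(h_bi, h_tr)
    set.seed(seed)
    y <- drop(pool$columns %*% rnorm(14, sd = 0.3)) + rnorm(300, sd = 0.05)
    m <- fos_fit(y, pool, max_functions = 7, rmsd_reduction_threshold = 0)
    X <- pool$columns[, match(m$selected, pool$names), drop = FALSE]
    expect_equal(m$fitted, ols_fit(y, X), tolerance = 1e-8)
  }
})

test_that("training RMSD path is non-increasing with above-threshold steps", {
  h_bi <- random_activation(400, 21)
  h_tr <- random_activation(400, 22)
  pool <- candidate_pool(h_bi, h_tr)
  set.seed(23)
  y <- 0.3 + 0.6 * h_bi + 0.2 * sqrt(h_tr) + rnorm(400, sd = 0.03)
  m <- fos_fit(y, pool, max_functions = 7, rmsd_reduction_threshold = 0.2)
  path <- c(sqrt(mean(y^2)) * 100, m$training_rmsd_path)
  decrements <- -diff(path)
  expect_true(all(decrements >= 0.2 - 1e-9))
})

test_that("mse_reduction matches the OLS refit oracle", {
  set.seed(31)
  n <- 200
  X <- cbind(1, matrix(rnorm(n * 3), n))
  y <- rnorm(n)
  # orthogonalize selected columns by Gram-Schmidt for the call
  q1 <- X[, 1]
  q2 <- X[, 2] - mean(X[, 2] * q1) / mean(q1^2) * q1
  Q <- cbind(q1, q2)
  resid <- y - Q %*% (colMeans(Q * y) / colMeans(Q^2))
  cand <- X[, 3]
  red <- mse_reduction(cand, Q, drop(resid))
  mse_before <- mean((y - ols_fit(y, X[, 1:2]))^2)
  mse_after <- mean((y - ols_fit(y, X[, 1:3]))^2)
  expect_equal(red, mse_before - mse_after, tolerance = 1e-10)
  # candidate in the span of the selections reduces nothing
  expect_equal(mse_reduction(2 * q1 + q2, Q, drop(resid)), 0)
  # empty selected set, candidate = y: full explanation
  expect_equal(mse_reduction(y, NULL, y), mean(y^2), tolerance = 1e-12)
})

test_that("collinear candidates are skipped, not fatal", {
  h <- rep(0.5, 120)  # constant activation: all non-bias columns constant
  pool <- candidate_pool_single(h)
  set.seed(41)
  y <- rnorm(120)
  m <- fos_fit(y, pool, max_functions = 6, rmsd_reduction_threshold = 0)
  expect_equal(m$diagnostics$termination, "all_candidates_collinear")
  expect_equal(length(m$selected), 1)  # only one constant direction fits
})

test_that("prediction reproduces fitted values and hand-built models", {
  h_bi <- random_activation(250, 51)
  h_tr <- random_activation(250, 52)
  pool <- candidate_pool(h_bi, h_tr)
  set.seed(53)
  y <- 0.2 + 0.7 * h_bi + rnorm(250, sd = 0.02)
  m <- fos_fit(y, pool)
  expect_equal(fos_predict(m, h_bi, h_tr), m$fitted, tolerance = 1e-12)
  expect_equal(predict(m, h_bi, h_tr), m$fitted, tolerance = 1e-12)
  # exact affine target bias 1 + 2 * H evaluates to (1, 2, 3) on (0, 0.5, 1)
  hgrid <- seq(0, 1, length.out = 50)
  hm <- fos_fit(1 + 2 * hgrid, candidate_pool_single(hgrid),
                max_functions = 6, rmsd_reduction_threshold = 1e-10)
  expect_equal(fos_predict(hm, c(0, 0.5, 1)), c(1, 2, 3), tolerance = 1e-7)
  expect_error(fos_predict(structure(list(), class = "fos_model"), h_bi, h_tr),
               class = "fosemg_state_error")
})

test_that("tidy and glance expose the model in tabular form", {
  h <- random_activation(200, 61)
  m <- fos_fit(0.1 + 0.5 * h, candidate_pool_single(h),
               rmsd_reduction_threshold = 1e-10)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("step", "term", "estimate", "g", "rmsd_after"))
  expect_equal(nrow(td), length(m$selected))
  gl <- glance(m)
  expect_equal(gl$n_terms, length(m$selected))
  expect_lt(gl$training_rmsd, 1e-6)
})
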
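# Small, fast fixtures used across the suite. Everything is generated in
# code; the short protocol keeps per-test simulation cheap while retaining
# the ramp-and-hold structure.

short_protocol <- function(level = 0.4, reps = 3) {
  protocol_spec(sampling_rate = 500, trial_duration = 2, ramp_duration = 1,
                target_level = level, n_repetitions = reps)
}

# smooth nonnegative activation-like series on [0, 1]
random_activation <- function(n, seed) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n)
  x <- abs(colSums(runif(3, 0.5, 1) *
                     sin(outer(2 * pi * runif(3, 0.5, 2), t) + runif(3, 0, 2 * pi))))
  x / max(x)
}

# ordinary least-squares projection of y on columns X (the independent
# oracle for FOS algebra)
ols_fit <- function(y, X) {
  qr.fitted(qr(X), y)
}

ols_coef_se <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  res <- y - X %*% fit$coefficients
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  xtx_inv <- chol2inv(chol(crossprod(X)))
  list(coef = fit$coefficients, se = sqrt(diag(xtx_inv) * sigma2))
}
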
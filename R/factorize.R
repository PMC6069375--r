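new_decomposition <- function(patterns, curves, method, extra = list()) {
  stopifnot(ncol(patterns) == nrow(curves))
  structure(
    c(list(patterns = patterns, curves = curves, method = method,
           n_components = ncol(patterns)), extra),
    class = "semg_decomposition"
  )
}

#' @export
print.semg_decomposition <- function(x, ...) {
  cat(sprintf("<semg_decomposition> method = %s, %d components, %d channels x %d samples\n",
              x$method, x$n_components, nrow(x$patterns), ncol(x$curves)))
  invisible(x)
}

#' Decompose HD-SEMG by principal component analysis
#'
#' Raw signals go straight into PCA: channels are mean-centered, the
#' channel covariance is diagonalized, and the leading eigenvectors (unit
#' norm, ordered by decreasing eigenvalue, each oriented so its
#' largest-magnitude weight is positive) become the activation patterns.
#' The principal-component score series are full-wave rectified and
#' low-pass filtered into nonnegative activation curves.
#'
#' @param s Channels x samples signal matrix.
#' @param n_components Number of components to keep (`<=` channels).
#' @param sampling_rate,cutoff,order Envelope filter settings, see
#'   [lowpass_envelope()].
#' @return A `semg_decomposition` with fields `patterns` (channels x n),
#'   `curves` (n x samples, nonnegative), `eigenvalues`.
#' @export
decompose_pca <- function(s, n_components, sampling_rate = 1000,
                          cutoff = 5, order = 50) {
  m <- nrow(s)
  if (n_components < 1 || n_components > m) {
    stop_invalid("n_components must lie in [1, channels].")
  }
  sc <- s - rowMeans(s)
  cv <- tcrossprod(sc) / (ncol(s) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  W <- eig$vectors[, seq_len(n_components), drop = FALSE]
  # orient each eigenvector so its largest-magnitude weight is positive
  for (k in seq_len(n_components)) {
    if (W[which.max(abs(W[, k])), k] < 0) W[, k] <- -W[, k]
  }
  scores <- crossprod(W, sc)  # n x samples
  curves <- pmax(lowpass_envelope(rectify(scores), sampling_rate, cutoff, order), 0)
  new_decomposition(W, curves, "pca",
                    list(eigenvalues = eig$values[seq_len(n_components)]))
}

#' Decompose HD-SEMG by FastICA
#'
#' Fixed-point FastICA with the log-cosh negentropy contrast and symmetric
#' decorrelation, run on data whitened to `n_components` principal
#' dimensions. The estimated mixing-matrix columns (back-projected into
#' channel space) are the activation patterns; source envelopes
#' (rectified + low-pass filtered) are the activation curves. Deterministic
#' given `seed` (seeded random orthonormal start).
#'
#' Convergence is declared when the symmetric-decorrelated fixed-point
#' update of `W` coincides with `W` up to row permutation and sign. The
#' first attempt runs the plain fixed-point iteration; on non-convergence
#' (weak, nearly Gaussian sources can drive the undamped iteration into
#' limit cycles) deterministically re-seeded restarts use a damped
#' (stabilized) update before the fit is declared non-convergent.
#'
#' @inheritParams decompose_pca
#' @param seed Integer seed for the unmixing initialization.
#' @param max_iter Maximum fixed-point iterations per restart.
#' @param tol Convergence tolerance on the fixed-point residual (1 minus
#'   the worst row cosine between `W` and its updated image).
#' @param n_restarts Number of initializations tried (first undamped, the
#'   rest damped) before erroring.
#' @return A `semg_decomposition`; `sources` holds the raw source series.
#' @export
decompose_ica <- function(s, n_components, seed = 1, sampling_rate = 1000,
                          cutoff = 5, order = 50, max_iter = 3000, tol = 1e-6,
                          n_restarts = 4) {
  m <- nrow(s); nt <- ncol(s)
  if (n_components < 1 || n_components > m) {
    stop_invalid("n_components must lie in [1, channels].")
  }
  sc <- s - rowMeans(s)
  cv <- tcrossprod(sc) / (nt - 1)
  eig <- eigen(cv, symmetric = TRUE)
  E <- eig$vectors[, seq_len(n_components), drop = FALSE]
  d <- eig$values[seq_len(n_components)]
  K <- diag(1 / sqrt(d), n_components) %*% t(E)        # whitening, n x m
  Z <- K %*% sc                                        # n x samples, unit cov
  W <- NULL
  it_total <- 0L
  last_delta <- Inf
  mus <- c(1, 0.5, 0.25, 0.1)
  for (attempt in seq_len(max(n_restarts, 1))) {
    mu <- mus[min(attempt, length(mus))]
    W_try <- local_seed(derive_seed(seed, 503L, attempt), {
      sym_decorrelate(matrix(rnorm(n_components^2), n_components))
    })
    converged <- FALSE
    n_still <- 0L
    for (it in seq_len(max_iter)) {
      U <- W_try %*% Z
      G <- tanh(U)
      W_fp <- (G %*% t(Z)) / nt - diag(rowMeans(1 - G^2), n_components) %*% W_try
      W_new <- if (mu == 1) sym_decorrelate(W_fp) else
        sym_decorrelate(W_try + mu * (W_fp - W_try))
      # permutation/sign-invariant movement of the iterate; require it to
      # stall for a few consecutive iterations under damping
      cmat <- abs(W_new %*% t(W_try))
      last_delta <- max(1 - pmin(apply(cmat, 1, max), 1))
      W_try <- W_new
      n_still <- if (last_delta < tol) n_still + 1L else 0L
      if (n_still >= 3L) { converged <- TRUE; break }
    }
    it_total <- it_total + it
    if (converged) { W <- W_try; break }
  }
  if (is.null(W)) {
    rlang::abort(
      sprintf("FastICA did not converge within %d iterations over %d restarts (delta = %.3g).",
              it_total, n_restarts, last_delta),
      class = "fosemg_convergence_error", iterations = it_total)
  }
  it <- it_total
  sources <- W %*% Z                                   # n x samples
  mixing <- E %*% diag(sqrt(d), n_components) %*% t(W) # channels x n
  curves <- pmax(lowpass_envelope(rectify(sources), sampling_rate, cutoff, order), 0)
  new_decomposition(mixing, curves, "ica",
                    list(sources = sources, iterations = it))
}

# Symmetric decorrelation: W <- (W W^T)^(-1/2) W.
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors) %*% W
}

#' Decompose envelope matrices by nonnegative matrix factorization
#'
#' Lee-Seung multiplicative updates minimizing the squared Frobenius
#' distance `||E - WH||_F^2`, from seeded uniform-random initialization.
#' The objective is non-increasing at every update; iteration stops at a
#' relative-improvement tolerance or `max_iter`. Because of the
#' nonnegativity constraint, NMF operates on envelopes (rectified and
#' low-pass filtered *before* factorization), unlike PCA/ICA which
#' factorize the raw signals.
#'
#' @param e Nonnegative channels x samples envelope matrix (see
#'   [avg_envelope()] for envelope extraction).
#' @param n_components Factorization rank.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum number of multiplicative updates.
#' @param tol Relative improvement of the objective below which iteration
#'   stops.
#' @return A `semg_decomposition` with nonnegative `patterns` and `curves`,
#'   plus `objective_path` (squared Frobenius error after every iteration)
#'   and `iterations`.
#' @export
decompose_nmf <- function(e, n_components, seed = 1, max_iter = 2000,
                          tol = 1e-5) {
  if (any(e < 0)) stop_invalid("NMF input must be nonnegative.")
  m <- nrow(e); nt <- ncol(e)
  if (n_components < 1 || n_components > min(m, nt)) {
    stop_invalid("n_components must lie in [1, min(channels, samples)].")
  }
  init <- local_seed(derive_seed(seed, 601L), {
    sc <- sqrt(mean(e) / n_components)
    list(W = matrix(runif(m * n_components), m) * sc,
         H = matrix(runif(n_components * nt), n_components) * sc)
  })
  W <- init$W; H <- init$H
  eps <- .Machine$double.eps
  obj <- numeric(max_iter)
  prev <- sum((e - W %*% H)^2)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    H <- H * (crossprod(W, e)) / (crossprod(W) %*% H + eps)
    W <- W * (e %*% t(H)) / (W %*% tcrossprod(H) + eps)
    obj[it] <- sum((e - W %*% H)^2)
    if (prev > 0 && (prev - obj[it]) / prev < tol) break
    prev <- obj[it]
  }
  # canonicalize the W/H scale indeterminacy: pattern columns to unit peak,
  # curves carry the amplitude (otherwise the curve sum depends on the
  # arbitrary scale split left by the random initialization)
  peaks <- apply(W, 2, max)
  peaks[peaks == 0] <- 1
  W <- sweep(W, 2, peaks, "/")
  H <- H * peaks
  new_decomposition(W, H, "nmf",
                    list(objective_path = obj[seq_len(it)], iterations = it))
}

#' Per-muscle activation signal from a decomposition
#'
#' Sums all activation curves of the muscle and normalizes the sum to unit
#' maximum; this single nonnegative time series per muscle (H_BI for the
#' biceps grid, H_TR for the triceps grid) is the input the FOS force model
#' consumes.
#'
#' @param d A `semg_decomposition`, or a components x samples curve matrix.
#' @return Nonnegative numeric vector with maximum exactly 1.
#' @export
activation_signal <- function(d) {
  curves <- if (inherits(d, "semg_decomposition")) d$curves else d
  if (!is.matrix(curves)) curves <- matrix(curves, nrow = 1)
  if (nrow(curves) < 1) stop_invalid("decomposition has no curves.")
  total <- colSums(curves)
  if (max(total) <= 0) {
    stop_invalid("all activation curves are zero; normalization is undefined.")
  }
  normalize_to_max(total)
}

#' Extract per-repetition activation signals from a trial set
#'
#' Runs the chosen processing method on every repetition of a simulated or
#' loaded [simulate_trial_set()] object and returns FOS-ready inputs: the
#' per-muscle activation signals and the max-normalized force.
#'
#' @param trials A `trial_set`.
#' @param method One of `"avg"` (average envelope baseline), `"pca"`,
#'   `"ica"`, `"nmf"`.
#' @param n_agonist,n_antagonist Component counts per muscle; the defaults
#'   (2 and 3) follow the anatomical head counts of biceps and triceps.
#' @param seed Integer seed forwarded to stochastic decompositions. One
#'   seed serves every repetition: the initialization is an analysis-level
#'   constant, so that differences between repetitions reflect the data,
#'   not the initialization draw.
#' @return A list of repetitions, each `list(h_bi, h_tr, force)` with all
#'   three series normalized to unit maximum.
#' @export
extract_activation_trials <- function(trials, method = c("avg", "pca", "ica", "nmf"),
                                      n_agonist = 2, n_antagonist = 3, seed = 1) {
  method <- match.arg(method)
  fs <- trials$protocol$sampling_rate
  grid_activation <- function(s, n_comp, sub) {
    switch(method,
      avg = normalize_to_max(avg_envelope(s, fs)),
      pca = activation_signal(decompose_pca(s, n_comp, fs)),
      ica = activation_signal(decompose_ica(s, n_comp, seed = sub,
                                            sampling_rate = fs)),
      nmf = activation_signal(decompose_nmf(envelope_matrix(s, fs), n_comp,
                                            seed = sub))
    )
  }
  purrr::map(trials$repetitions, function(rep) {
    list(
      h_bi = grid_activation(rep$agonist, n_agonist, derive_seed(seed, 71L)),
      h_tr = grid_activation(rep$antagonist, n_antagonist, derive_seed(seed, 73L)),
      force = normalize_to_max(rep$force)
    )
  })
}
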
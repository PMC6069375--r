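#' Ground-truth activation curves
#'
#' Builds the nonnegative time-varying amplitude of each activation pattern:
#' a trapezoid that ramps linearly from zero to `protocol$target_level` over
#' the ramp phase and then holds the target, perturbed multiplicatively by a
#' smooth low-frequency jitter `1 + shape_jitter * s(t)` with `s` clipped to
#' `[-1, 1]`, so curves stay nonnegative and deviate from the ideal
#' trapezoid by at most `shape_jitter * target_level` at any sample.
#' Each component receives an independent jitter realization, which is what
#' makes the components temporally distinguishable to a factorization.
#'
#' @param protocol A [protocol_spec()].
#' @param n_components Number of activation curves to generate.
#' @param shape_jitter Relative jitter amplitude in `[0, 1)`; 0 gives the
#'   exact trapezoid.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `n_components` x `n_samples(protocol)` matrix, rows = curves.
#' @examples
#' curves <- make_activation_curves(protocol_spec(), 2, shape_jitter = 0.1, seed = 1)
#' @export
make_activation_curves <- function(protocol, n_components, shape_jitter = 0.1,
                                   seed = 1) {
  if (n_components < 1) stop_invalid("n_components must be at least 1.")
  if (shape_jitter < 0 || shape_jitter >= 1) {
    stop_invalid("shape_jitter must lie in [0, 1).")
  }
  nt <- n_samples(protocol)
  t <- (seq_len(nt) - 1) / protocol$sampling_rate
  trap <- protocol$target_level * pmin(t / protocol$ramp_duration, 1)
  curves <- matrix(0, n_components, nt)
  for (k in seq_len(n_components)) {
    if (shape_jitter > 0) {
      s <- local_seed(derive_seed(seed, 101L, k), smooth_jitter(t))
      curves[k, ] <- trap * (1 + shape_jitter * s)
    } else {
      curves[k, ] <- trap
    }
  }
  curves
}

# Smooth zero-mean jitter: a short random Fourier series in 0.2-1 Hz,
# rescaled to peak magnitude <= 1 (then clipped for safety).
smooth_jitter <- function(t) {
  freqs <- runif(3, 0.2, 1)
  amps <- runif(3, 0.5, 1)
  phases <- runif(3, 0, 2 * pi)
  s <- colSums(amps * sin(outer(2 * pi * freqs, t) + phases))
  s <- s / max(abs(s))
  pmin(pmax(s, -1), 1)
}

#' Ground-truth spatial activation patterns
#'
#' Each pattern is a 2-D Gaussian bump over the electrode grid, peak value 1
#' at its center electrode plus a small positive floor everywhere, flattened
#' row-major to channel order (channel = (row-1) * n_cols + col). Distinct
#' centers give spatially distinct ("highlighted area") patterns. An
#' optional per-component `gains` vector scales whole columns, emulating
#' components of unequal strength.
#'
#' @param grid A [grid_spec()].
#' @param n_components Number of patterns; must equal `length(centers)`.
#' @param centers List of `c(row, col)` electrode coordinates inside the grid.
#' @param width Gaussian standard deviation in electrode pitches, scalar or
#'   one value per component (regions of unequal spatial extent);
#'   `width = 0` degenerates to an indicator of the center electrode (plus
#'   floor).
#' @param floor Small positive baseline weight added to every channel.
#' @param gains Optional per-component multiplicative gain (recycled).
#' @return A `n_channels(grid)` x `n_components` matrix of nonnegative weights.
#' @examples
#' W <- make_activation_patterns(grid_spec(), 2, list(c(1, 1), c(4, 8)), width = 1)
#' @export
make_activation_patterns <- function(grid, n_components, centers, width = 1.5,
                                     floor = 0.02, gains = 1) {
  if (length(centers) != n_components) {
    stop_invalid("length(centers) must equal n_components.")
  }
  gains <- rep_len(gains, n_components)
  width <- rep_len(width, n_components)
  m <- n_channels(grid)
  W <- matrix(0, m, n_components)
  rows <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  for (k in seq_len(n_components)) {
    ctr <- centers[[k]]
    if (length(ctr) != 2 || ctr[1] < 1 || ctr[1] > grid$n_rows ||
        ctr[2] < 1 || ctr[2] > grid$n_cols) {
      stop_invalid(sprintf("center %d lies outside the %dx%d grid.",
                           k, grid$n_rows, grid$n_cols))
    }
    d2 <- (rows - ctr[1])^2 + (cols - ctr[2])^2
    bump <- if (width[k] > 0) exp(-d2 / (2 * width[k]^2)) else as.numeric(d2 == 0)
    W[, k] <- gains[k] * (bump + floor)
  }
  W
}

#' Synthesize a multichannel HD-SEMG trial
#'
#' Amplitude-modulation model of surface EMG: each component k carries an
#' independent zero-mean, unit-variance, band-limited Gaussian carrier
#' `n_k(t)` (white noise band-passed with a zero-phase FIR), modulated by
#' its activation curve and mixed through the spatial pattern. Channel `c`
#' is `sum_k W[c, k] * H[k, t] * n_k(t) + eps_c(t)` with white measurement
#' noise of standard deviation `noise_sd`. Independent carriers per
#' component make the components statistically independent by construction.
#'
#' @param patterns Channels x components pattern matrix (`W`).
#' @param curves Components x samples curve matrix (`H`).
#' @param sampling_rate Sampling rate in Hz.
#' @param carrier_band Passband in Hz; an upper edge at or above Nyquist
#'   degenerates to a high-pass at the lower edge.
#' @param noise_sd Standard deviation of additive white channel noise.
#' @param seed Integer seed.
#' @param channel_gains Optional per-channel multiplicative gain vector
#'   (electrode/contact heterogeneity); default 1 for all channels.
#' @return A channels x samples signal matrix with attribute `sampling_rate`.
#' @export
synthesize_hdsemg <- function(patterns, curves, sampling_rate = 1000,
                              carrier_band = c(20, 500), noise_sd = 0.05,
                              seed = 1, channel_gains = NULL) {
  if (ncol(patterns) != nrow(curves)) {
    stop_invalid("ncol(patterns) must equal nrow(curves).")
  }
  if (carrier_band[1] <= 0 || carrier_band[1] >= carrier_band[2]) {
    stop_invalid("carrier_band must satisfy 0 < low < high.")
  }
  m <- nrow(patterns); n <- ncol(patterns); nt <- ncol(curves)
  carriers <- local_seed(derive_seed(seed, 211L), {
    vapply(seq_len(n), function(k) {
      band_limited_carrier(nt, sampling_rate, carrier_band)
    }, numeric(nt))
  })  # nt x n
  modulated <- t(carriers) * curves          # n x nt
  S <- patterns %*% modulated
  if (noise_sd > 0) {
    S <- S + local_seed(derive_seed(seed, 223L),
                        matrix(rnorm(m * nt, sd = noise_sd), m, nt))
  }
  if (!is.null(channel_gains)) S <- S * rep_len(channel_gains, m)
  attr(S, "sampling_rate") <- sampling_rate
  S
}

# White Gaussian noise band-passed with a zero-phase 201-tap FIR, then
# restandardized to mean 0, variance 1. Consumes the current RNG stream.
band_limited_carrier <- function(nt, sampling_rate, band) {
  x <- rnorm(nt)
  nyq <- sampling_rate / 2
  if (band[2] >= 0.999 * nyq) {
    b <- signal::fir1(200, band[1] / nyq, type = "high")
  } else {
    b <- signal::fir1(200, band / nyq, type = "pass")
  }
  y <- zero_phase_fir(x, b)
  (y - mean(y)) / sd(y)
}

#' Synthesize a force trace from activation signals
#'
#' Evaluates a linear combination of candidate-pool basis functions of the
#' two activation signals and adds white measurement noise. Used to build
#' ground-truth forces that the FOS model can represent exactly, so that
#' coefficient recovery and noiseless realizability can be tested.
#'
#' @param h_bi,h_tr Nonnegative activation signals (equal length).
#' @param coeffs Named numeric vector; names must be candidate-pool basis
#'   names (see [basis_names()]), e.g. `c(bias = 0.1, "H_BI" = 0.5, "H_TR^2" = 0.3)`.
#' @param noise_sd Standard deviation of additive white noise (0 for none).
#' @param seed Integer seed for the noise.
#' @return Numeric force trace of the same length as the inputs.
#' @examples
#' h <- seq(0, 1, length.out = 5)
#' synthesize_force(h, h, c("H_BI" = 1), noise_sd = 0)
#' @export
synthesize_force <- function(h_bi, h_tr, coeffs, noise_sd = 0, seed = 1) {
  check_same_length(h_bi, h_tr, "h_bi", "h_tr")
  if (is.null(names(coeffs)) || any(names(coeffs) == "")) {
    stop_invalid("coeffs must be a fully named numeric vector.")
  }
  unknown <- setdiff(names(coeffs), basis_names("dual"))
  if (length(unknown) > 0) {
    stop_invalid(paste0("unknown basis function name(s): ",
                        paste(unknown, collapse = ", ")))
  }
  y <- rep(0, length(h_bi))
  for (nm in names(coeffs)) {
    y <- y + coeffs[[nm]] * eval_basis(nm, h_bi, h_tr)
  }
  if (noise_sd > 0) {
    y <- y + local_seed(derive_seed(seed, 307L), rnorm(length(y), sd = noise_sd))
  }
  y
}

#' Static lever relation between elbow and wrist force
#'
#' In a static isometric task the moments about the elbow joint balance:
#' `F_wrist * L_wrist + F_elbow * L_elbow = 0`, so the force measured at the
#' wrist is proportional to (and opposes) the force generated at the elbow.
#'
#' @param f_elbow Force at the elbow.
#' @param l_elbow,l_wrist Moment arms of the elbow and wrist forces about
#'   the elbow joint (same length units); `l_wrist` must be nonzero.
#' @return `F_wrist = -f_elbow * l_elbow / l_wrist`.
#' @examples
#' lever_force(6, 2, 3)  # -4
#' @export
lever_force <- function(f_elbow, l_elbow, l_wrist) {
  if (any(l_wrist == 0)) stop_invalid("l_wrist must be nonzero.")
  -f_elbow * l_elbow / l_wrist
}

#' Simulate a full set of repeated HD-SEMG + force trials
#'
#' Generates the study conditions the pipeline assumes: an agonist grid
#' (biceps, 2 spatially distinct components) and an antagonist grid
#' (triceps, 3 components at a co-contraction fraction of the agonist
#' drive), each repetition with fresh carriers, fresh curve jitter, and a
#' force trace produced by the agonist minus a fraction of the antagonist
#' drive plus sensor noise. Patterns are fixed across repetitions (they are
#' time-invariant properties of the muscle); per-channel electrode gains
#' are drawn once per set. The defaults realize the heterogeneity
#' conditions used by the packaged benchmark: disjoint activation regions
#' of unequal spatial extent and gain, temporally distinct component curves
#' (independent within-trapezoid jitter), and heterogeneous electrode
#' gains. Under these conditions the uniform channel average weights the
#' regions by their surface footprint rather than by their contribution to
#' the force-generating drive, which is what gives factorization methods
#' their advantage.
#'
#' @param protocol A [protocol_spec()].
#' @param grid A [grid_spec()] shared by both electrode grids.
#' @param seed Integer seed; the whole set is deterministic given it.
#' @param agonist_centers,antagonist_centers Lists of `c(row, col)` pattern
#'   centers; defaults give disjoint active regions.
#' @param agonist_widths,antagonist_widths Gaussian pattern widths in
#'   electrode pitches, one per component; defaults mix broad and compact
#'   regions (unequal surface footprints).
#' @param agonist_gains,antagonist_gains Per-component gains (unequal by
#'   default).
#' @param channel_gain_range Range of per-channel electrode gains drawn
#'   uniformly once per grid.
#' @param shape_jitter Relative curve jitter per repetition; large enough
#'   (default 0.3) to make the component curves temporally distinguishable
#'   within the common ramp-and-hold profile.
#' @param noise_sd Channel noise standard deviation; the default 0.03
#'   corresponds to a baseline noise floor of a few percent of the
#'   peak-channel EMG amplitude (roughly 20 dB), typical of surface EMG
#'   hardware.
#' @param cocontraction Antagonist drive as a fraction of the agonist drive.
#' @param antagonist_force_weight Weight of the antagonist drive subtracted
#'   from the agonist drive in the generated force.
#' @param force_noise_sd Sensor noise on the force trace.
#' @return A `trial_set`: list with `repetitions` (each holding `agonist`
#'   and `antagonist` signal matrices, `force`, and the true curves),
#'   `protocol`, `grid` and `truth` (patterns, gains).
#' @export
simulate_trial_set <- function(protocol = protocol_spec(),
                               grid = grid_spec(),
                               seed = 1,
                               agonist_centers = list(c(2, 2), c(3, 7)),
                               antagonist_centers = list(c(2, 2), c(2, 5), c(3, 7)),
                               agonist_widths = c(2.0, 0.8),
                               antagonist_widths = c(1.6, 1.0, 0.7),
                               agonist_gains = c(1, 0.8),
                               antagonist_gains = c(0.5, 0.4, 0.3),
                               channel_gain_range = c(0.6, 1.4),
                               shape_jitter = 0.3,
                               noise_sd = 0.03,
                               cocontraction = 0.25,
                               antagonist_force_weight = 0.3,
                               force_noise_sd = 0.005) {
  W_ag <- make_activation_patterns(grid, length(agonist_centers),
                                   agonist_centers, agonist_widths,
                                   gains = agonist_gains)
  W_ant <- make_activation_patterns(grid, length(antagonist_centers),
                                    antagonist_centers, antagonist_widths,
                                    gains = antagonist_gains)
  m <- n_channels(grid)
  gains <- local_seed(derive_seed(seed, 401L), list(
    agonist = runif(m, channel_gain_range[1], channel_gain_range[2]),
    antagonist = runif(m, channel_gain_range[1], channel_gain_range[2])
  ))
  reps <- vector("list", protocol$n_repetitions)
  for (r in seq_len(protocol$n_repetitions)) {
    H_ag <- make_activation_curves(protocol, ncol(W_ag), shape_jitter,
                                   seed = derive_seed(seed, 11L, r))
    H_ant <- cocontraction *
      make_activation_curves(protocol, ncol(W_ant), shape_jitter,
                             seed = derive_seed(seed, 13L, r))
    S_ag <- synthesize_hdsemg(W_ag, H_ag, protocol$sampling_rate,
                              noise_sd = noise_sd,
                              seed = derive_seed(seed, 17L, r),
                              channel_gains = gains$agonist)
    S_ant <- synthesize_hdsemg(W_ant, H_ant, protocol$sampling_rate,
                               noise_sd = noise_sd,
                               seed = derive_seed(seed, 19L, r),
                               channel_gains = gains$antagonist)
    force <- colMeans(H_ag) - antagonist_force_weight * colMeans(H_ant)
    if (force_noise_sd > 0) {
      force <- force + local_seed(derive_seed(seed, 23L, r),
                                  rnorm(length(force), sd = force_noise_sd))
    }
    reps[[r]] <- list(agonist = S_ag, antagonist = S_ant, force = force,
                      curves_agonist = H_ag, curves_antagonist = H_ant)
  }
  structure(
    list(repetitions = reps, protocol = protocol, grid = grid,
         truth = list(patterns_agonist = W_ag, patterns_antagonist = W_ant,
                      channel_gains = gains)),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "<trial_set> %d repetitions, %d+%d channels, %d samples @ %g Hz, target %g MVC\n",
    length(x$repetitions), n_channels(x$grid), n_channels(x$grid),
    n_samples(x$protocol), x$protocol$sampling_rate, x$protocol$target_level))
  invisible(x)
}
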
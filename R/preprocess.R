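#' Replace bad channels by their nearest good grid neighbor
#'
#' Mirrors the usual handling of broken or poorly contacting electrodes in
#' HD-SEMG grids: each bad channel's row is overwritten with a copy of an
#' adjacent good electrode in the 4-neighborhood (up/down/left/right), ties
#' broken by the smallest channel index. Channel indices are row-major over
#' the grid.
#'
#' @param s Channels x samples signal matrix.
#' @param bad Integer vector of bad channel indices (possibly empty).
#' @param grid A [grid_spec()] describing the electrode layout.
#' @return The repaired signal matrix.
#' @export
replace_bad_channels <- function(s, bad, grid = grid_spec()) {
  m <- nrow(s)
  if (m != n_channels(grid)) {
    stop_invalid("nrow(s) must equal the grid channel count.")
  }
  bad <- unique(as.integer(bad))
  if (length(bad) == 0) return(s)
  if (any(bad < 1 | bad > m)) stop_invalid("bad channel index out of range.")
  if (length(bad) == m) {
    rlang::abort("all channels are bad; input is unrecoverable.",
                 class = "fosemg_unrecoverable_input")
  }
  good <- setdiff(seq_len(m), bad)
  out <- s
  for (ch in bad) {
    row <- (ch - 1L) %/% grid$n_cols + 1L
    col <- (ch - 1L) %% grid$n_cols + 1L
    nb <- list(c(row - 1L, col), c(row + 1L, col), c(row, col - 1L), c(row, col + 1L))
    nb <- Filter(function(p) p[1] >= 1 && p[1] <= grid$n_rows &&
                   p[2] >= 1 && p[2] <= grid$n_cols, nb)
    cand <- sort(intersect(vapply(nb, function(p) channel_index(grid, p[1], p[2]),
                                  integer(1)), good))
    if (length(cand) == 0) {
      stop_invalid(sprintf("bad channel %d has no good 4-neighbor.", ch))
    }
    out[ch, ] <- s[cand[1], ]
  }
  out
}

#' Full-wave rectification
#'
#' @param x Numeric vector or matrix.
#' @return Elementwise absolute value.
#' @export
rectify <- function(x) abs(x)

# Windowed FIR low-pass used for envelope extraction: `order + 1` taps,
# Hanning (raised cosine, endpoints included) window, renormalized so the
# DC gain is exactly 1.
design_envelope_fir <- function(sampling_rate, cutoff = 5, order = 50) {
  if (cutoff <= 0 || cutoff >= sampling_rate / 2) {
    stop_invalid("cutoff must lie in (0, sampling_rate / 2).")
  }
  b <- signal::fir1(order, cutoff / (sampling_rate / 2), type = "low",
                    window = signal::hanning(order + 1))
  as.numeric(b) / sum(b)
}

# Zero-phase (forward-backward) FIR application. For a FIR filter the
# forward-backward cascade is exactly a centered convolution with the
# symmetric kernel conv(b, rev(b)); odd reflection padding gives the edges
# locally extended data instead of implicit zeros.
zero_phase_fir <- function(x, b) {
  np <- length(b)
  n <- length(x)
  if (n <= np) stop_invalid("signal must be longer than the filter.")
  kernel <- stats::convolve(b, b, type = "open")  # conv(b, rev(b)), length 2*np-1
  pre <- 2 * x[1] - x[seq(np + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - np)]
  xp <- c(pre, x, post)
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  as.numeric(y[seq(np + 1, np + n)])
}

#' Low-pass envelope filter
#'
#' Applies the envelope low-pass: a 51-tap (by default) Hanning-window FIR
#' at 5 Hz, run forward and backward (zero-phase) over each channel, so the
#' envelope stays aligned with the simultaneously sampled force trace. The
#' designed filter has DC gain exactly 1; filtering is linear (no clamping),
#' so small negative excursions of a rectified input are possible near sharp
#' transients.
#'
#' @param x Numeric vector, or channels x samples matrix (filtered per row).
#' @param sampling_rate Sampling rate in Hz.
#' @param cutoff Low-pass cutoff in Hz.
#' @param order FIR order (taps - 1).
#' @return Filtered signal, same shape as `x`.
#' @examples
#' env <- lowpass_envelope(abs(rnorm(2000)), sampling_rate = 1000)
#' @export
lowpass_envelope <- function(x, sampling_rate = 1000, cutoff = 5, order = 50) {
  b <- design_envelope_fir(sampling_rate, cutoff, order)
  if (is.matrix(x)) {
    t(apply(x, 1, zero_phase_fir, b = b))
  } else {
    zero_phase_fir(as.numeric(x), b)
  }
}

#' Frequency response of the envelope filter
#'
#' Magnitude response of the envelope low-pass at the requested frequencies.
#' With `zero_phase = TRUE` (the default, matching how the filter is
#' applied) the forward-backward magnitude `|H(f)|^2` is returned.
#'
#' @param freq Frequencies in Hz.
#' @inheritParams lowpass_envelope
#' @param zero_phase Return the effective forward-backward response?
#' @return Magnitude gain at each frequency (linear scale).
#' @examples
#' # attenuation at 50 Hz in dB:
#' -20 * log10(envelope_filter_response(50, 1000))
#' @export
envelope_filter_response <- function(freq, sampling_rate = 1000, cutoff = 5,
                                     order = 50, zero_phase = TRUE) {
  b <- design_envelope_fir(sampling_rate, cutoff, order)
  h <- vapply(freq, function(f) {
    Mod(sum(b * exp(-2i * pi * f * (seq_along(b) - 1) / sampling_rate)))
  }, numeric(1))
  if (zero_phase) h^2 else h
}

#' Normalize a time series to unit maximum
#'
#' Scales a signal so its maximum over the movement cycle is exactly 1; both
#' the FOS input signals and the measured force are normalized this way
#' before modeling, so RMSD is expressed in percent of peak force.
#'
#' @param x Numeric vector with `max(x) > 0`.
#' @return `x / max(x)`.
#' @export
normalize_to_max <- function(x) {
  m <- max(x)
  if (!is.finite(m) || m <= 0) {
    stop_invalid("normalize_to_max requires a positive maximum.")
  }
  x / m
}

#' Average-envelope activation signal (AVG-ENVLP baseline)
#'
#' The conventional baseline: rectify every channel, low-pass to the
#' envelope, and average across all channels of the grid. The result is
#' clamped at zero (envelopes are nonnegative by convention).
#'
#' @param s Channels x samples signal matrix.
#' @inheritParams lowpass_envelope
#' @return Nonnegative activation time series (length = samples).
#' @export
avg_envelope <- function(s, sampling_rate = 1000, cutoff = 5, order = 50) {
  env <- lowpass_envelope(rectify(s), sampling_rate, cutoff, order)
  pmax(colMeans(env), 0)
}

# Envelope matrix for NMF: rectified, low-pass filtered, clamped >= 0.
envelope_matrix <- function(s, sampling_rate = 1000, cutoff = 5, order = 50) {
  pmax(lowpass_envelope(rectify(s), sampling_rate, cutoff, order), 0)
}
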
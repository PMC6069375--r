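#' Contraction protocol specification
#'
#' Describes one isometric elbow-flexion trial: force ramps linearly from
#' zero to `target_level` (a fraction of maximum voluntary contraction, MVC)
#' over `ramp_duration` seconds, then holds at the target for the remainder
#' of the trial. The default is the 6-s trial (3-s ramp + 3-s hold) sampled
#' at 1000 Hz used throughout the package, giving 6000 samples per trial.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_duration Total trial duration in seconds.
#' @param ramp_duration Duration of the linear ramp in seconds; must not
#'   exceed `trial_duration`.
#' @param target_level Contraction target as a fraction of MVC in (0, 1].
#'   The experimental levels are 0.2, 0.4 and 0.6.
#' @param n_repetitions Number of repetitions of the trial at this level.
#' @return An object of class `protocol_spec`.
#' @examples
#' p <- protocol_spec(target_level = 0.4)
#' n_samples(p)
#' @export
protocol_spec <- function(sampling_rate = 1000, trial_duration = 6,
                          ramp_duration = 3, target_level = 0.4,
                          n_repetitions = 7) {
  if (sampling_rate <= 0 || trial_duration <= 0 || ramp_duration <= 0) {
    stop_invalid("sampling_rate, trial_duration and ramp_duration must be positive.")
  }
  if (ramp_duration > trial_duration) {
    stop_invalid("ramp_duration must not exceed trial_duration.")
  }
  if (target_level <= 0 || target_level > 1) {
    stop_invalid("target_level must lie in (0, 1].")
  }
  if (n_repetitions < 1) stop_invalid("n_repetitions must be at least 1.")
  n <- sampling_rate * trial_duration
  if (abs(n - round(n)) > 1e-9) {
    stop_invalid("sampling_rate * trial_duration must be an integer sample count.")
  }
  structure(
    list(sampling_rate = sampling_rate, trial_duration = trial_duration,
         ramp_duration = ramp_duration, target_level = target_level,
         n_repetitions = as.integer(n_repetitions)),
    class = "protocol_spec"
  )
}

#' @rdname protocol_spec
#' @param protocol A `protocol_spec`.
#' @export
n_samples <- function(protocol) {
  as.integer(round(protocol$sampling_rate * protocol$trial_duration))
}

#' Electrode grid specification
#'
#' Geometry of one high-density surface-EMG electrode grid. Channels are
#' numbered row-major: channel index = (row - 1) * n_cols + col, so a
#' pattern column reshapes back to the physical grid with
#' `matrix(w, n_rows, n_cols, byrow = TRUE)`.
#'
#' @param n_rows,n_cols Grid dimensions; the default 4 x 8 grid has 32
#'   channels.
#' @param inter_electrode_distance Center-to-center electrode spacing in mm
#'   (metadata only; no computation depends on it).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec()
#' n_channels(g)
#' @export
grid_spec <- function(n_rows = 4, n_cols = 8, inter_electrode_distance = 10) {
  if (n_rows < 1 || n_cols < 1) stop_invalid("grid dimensions must be positive.")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         inter_electrode_distance = inter_electrode_distance),
    class = "grid_spec"
  )
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
n_channels <- function(grid) grid$n_rows * grid$n_cols

# row-major channel index of a (row, col) electrode
channel_index <- function(grid, row, col) (row - 1L) * grid$n_cols + col

#' Enumerate the full factorial training design
#'
#' One row per FOS training run in the full experimental design:
#' subjects x force levels x processing methods x repetitions. With the
#' default arguments (7 subjects, 3 levels, 4 methods, 7 repetitions) the
#' design enumerates to 588 training runs.
#'
#' @param n_subjects Number of subjects.
#' @param levels Force levels as fractions of MVC.
#' @param methods Processing methods compared.
#' @param n_repetitions Repetitions per level.
#' @return A tibble with columns `subject`, `level`, `method`, `repetition`.
#' @examples
#' nrow(experiment_grid())  # 588
#' @export
experiment_grid <- function(n_subjects = 7,
                            levels = c(0.2, 0.4, 0.6),
                            methods = c("avg", "pca", "ica", "nmf"),
                            n_repetitions = 7) {
  tidyr::expand_grid(
    subject = seq_len(n_subjects),
    level = levels,
    method = methods,
    repetition = seq_len(n_repetitions)
  )
}
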
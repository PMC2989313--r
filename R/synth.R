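#' Synthetic-EMG generator parameters
#'
#' Parameters of the surface-EMG emulator. The generated signal is
#' band-limited zero-mean Gaussian noise whose amplitude (RMS) envelope is a
#' function of arm angle: at angle `a` on the abduction branch the target RMS
#' is `envelope_fn(a) * channel_gain + noise_floor`; on the adduction branch
#' the envelope term is additionally multiplied by `hysteresis_gain`
#' (values below 1 reproduce the higher-in-abduction-than-adduction
#' amplitude asymmetry of the middle deltoid).
#'
#' @param sample_rate Sampling rate in Hz. Default 2000 (a typical surface
#'   EMG acquisition rate).
#' @param band Length-2 numeric, pass band in Hz. Default `c(10, 500)`,
#'   matching common hardware analog filtering. The upper edge is clipped
#'   just below Nyquist if necessary.
#' @param envelope_fn Vectorized function mapping angle in degrees to RMS
#'   amplitude (arbitrary units, must be `>= 0` on `[0, 90]`). Default is
#'   linear in angle, 0.2 at 0 degrees rising to 2.0 at 90 degrees, the
#'   roughly tenfold linear amplitude growth seen for the middle deltoid.
#' @param hysteresis_gain Positive multiplier applied to the envelope on the
#'   adduction branch. Default 1 (no hysteresis).
#' @param noise_floor Additive baseline RMS (same units as the envelope),
#'   emulating quiescent-muscle and instrumentation noise. Default 0.05.
#' @param channel_gains Numeric vector of per-channel envelope multipliers;
#'   length gives the channel count. Used to emulate inter-electrode-distance
#'   (pickup gain) differences. Default `1` (single channel).
#' @param seed Integer RNG seed, or `NULL` to draw from the current RNG
#'   state.
#'
#' @return An object of class `synth_params`.
#' @seealso [generate_static_session()], [generate_dynamic_session()]
#' @export
synth_params <- function(sample_rate = 2000,
                         band = c(10, 500),
                         envelope_fn = function(angle) 0.2 + 1.8 * angle / 90,
                         hysteresis_gain = 1,
                         noise_floor = 0.05,
                         channel_gains = 1,
                         seed = NULL) {
  stopifnot(is.numeric(sample_rate), length(sample_rate) == 1L, sample_rate > 0)
  stopifnot(is.numeric(band), length(band) == 2L)
  if (band[1] < 0 || band[1] >= band[2])
    stop("`band` must satisfy 0 <= low < high")
  stopifnot(is.function(envelope_fn))
  stopifnot(is.numeric(hysteresis_gain), length(hysteresis_gain) == 1L,
            hysteresis_gain > 0)
  stopifnot(is.numeric(noise_floor), length(noise_floor) == 1L, noise_floor >= 0)
  stopifnot(is.numeric(channel_gains), length(channel_gains) >= 1L,
            all(channel_gains >= 0))
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(sample_rate = sample_rate, band = band, envelope_fn = envelope_fn,
         hysteresis_gain = hysteresis_gain, noise_floor = noise_floor,
         channel_gains = channel_gains, seed = seed),
    class = "synth_params"
  )
}

#' Static-contraction protocol
#'
#' A sequence of held arm positions. The reference protocol holds each of
#' ten positions (0 to 90 degrees in 10-degree steps) for 3 seconds;
#' positions reached while raising the arm are tagged `abduction`, while
#' lowering `adduction`. `direction = "both"` runs the abduction sequence and
#' then the same positions in reverse order on the adduction branch.
#'
#' @param positions Numeric vector of angles in degrees. Default
#'   `seq(0, 90, by = 10)`.
#' @param hold_duration Seconds the arm is held at each position. Default 3.
#' @param direction One of `"abduction"`, `"adduction"`, `"both"`.
#' @param gap_duration Seconds of repositioning "gap" signal inserted between
#'   holds (baseline noise, excluded from analysis). Default 0.
#'
#' @return An object of class `static_protocol`.
#' @export
static_protocol <- function(positions = seq(0, 90, by = 10),
                            hold_duration = 3,
                            direction = c("abduction", "adduction", "both"),
                            gap_duration = 0) {
  direction <- match.arg(direction)
  if (length(positions) < 1L) stop("`positions` must be non-empty")
  stopifnot(is.numeric(positions))
  if (!is.numeric(hold_duration) || hold_duration <= 0)
    stop("`hold_duration` must be > 0")
  stopifnot(is.numeric(gap_duration), gap_duration >= 0)
  structure(
    list(positions = positions, hold_duration = hold_duration,
         direction = direction, gap_duration = gap_duration),
    class = "static_protocol"
  )
}

#' Dynamic-contraction protocol
#'
#' A constant-speed abduction ramp from the bottom to the top of
#' `angle_range`, a hold at the top, and (optionally) an adduction ramp
#' back, repeated `n_cycles` times. The reference trial ramps 0 to 90
#' degrees at about 4.5 degrees/s with a 4 s hold at 90 degrees.
#'
#' @param speed Ramp speed in degrees per second. Default 4.5.
#' @param hold_at_top Seconds held at the top angle. Default 4.
#' @param angle_range Length-2 ascending numeric, degrees. Default `c(0, 90)`.
#' @param include_adduction Include the return (adduction) ramp. Default TRUE.
#' @param n_cycles Number of movement cycles in one session. Default 1; a
#'   study session pooling repeated trials uses e.g. 5.
#'
#' @return An object of class `dynamic_protocol`.
#' @export
dynamic_protocol <- function(speed = 4.5,
                             hold_at_top = 4,
                             angle_range = c(0, 90),
                             include_adduction = TRUE,
                             n_cycles = 1) {
  if (!is.numeric(speed) || speed <= 0) stop("`speed` must be > 0")
  stopifnot(is.numeric(hold_at_top), hold_at_top >= 0)
  stopifnot(is.numeric(angle_range), length(angle_range) == 2L)
  if (angle_range[1] >= angle_range[2])
    stop("`angle_range` must be ascending")
  stopifnot(is.logical(include_adduction), length(include_adduction) == 1L)
  stopifnot(is.numeric(n_cycles), n_cycles >= 1)
  structure(
    list(speed = speed, hold_at_top = hold_at_top, angle_range = angle_range,
         include_adduction = include_adduction, n_cycles = as.integer(n_cycles)),
    class = "dynamic_protocol"
  )
}

#' EMG session container
#'
#' Holds one recording (or simulation) session: the sampled EMG channels,
#' the stimulus aligned sample-by-sample (a factor of position labels for a
#' static protocol, or a numeric angle trace in degrees for a dynamic one),
#' and per-sample direction tags (`abduction`, `adduction`, `hold`, `gap`).
#'
#' @param emg Numeric vector (one channel) or `n x K` matrix of sampled EMG,
#'   arbitrary amplitude units.
#' @param sample_rate Sampling rate, Hz.
#' @param stimulus Per-sample stimulus: factor of position labels (static)
#'   or numeric angle in degrees (dynamic). Same length as the signal.
#' @param direction Character vector of per-sample movement tags, same
#'   length; defaults to `"abduction"` everywhere.
#' @param metadata Named list of session metadata (protocol kind, seed,
#'   subject id, generator settings, ...).
#'
#' @return An object of class `emg_session`.
#' @export
emg_session <- function(emg, sample_rate, stimulus, direction = NULL,
                        metadata = list()) {
  if (is.vector(emg)) emg <- matrix(emg, ncol = 1L)
  stopifnot(is.matrix(emg), is.numeric(emg))
  n <- nrow(emg)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a positive number")
  if (length(stimulus) != n)
    stop("stimulus length (", length(stimulus),
         ") does not match signal length (", n, ")")
  if (is.null(direction)) direction <- rep("abduction", n)
  if (length(direction) != n)
    stop("direction length does not match signal length")
  structure(
    list(emg = emg, sample_rate = sample_rate, stimulus = stimulus,
         direction = as.character(direction), metadata = metadata),
    class = "emg_session"
  )
}

#' @export
print.emg_session <- function(x, ...) {
  n <- nrow(x$emg)
  kind <- x$metadata$kind %||% if (is.factor(x$stimulus)) "static" else "dynamic"
  cat(sprintf("<emg_session> %s, %d channel(s), %.2f s at %g Hz\n",
              kind, ncol(x$emg), n / x$sample_rate, x$sample_rate))
  if (is.factor(x$stimulus)) {
    cat("  positions:", paste(levels(x$stimulus), collapse = ", "), "deg\n")
  } else {
    cat(sprintf("  angle trace: %.1f .. %.1f deg\n",
                min(x$stimulus), max(x$stimulus)))
  }
  cat("  directions:", paste(unique(x$direction), collapse = ", "), "\n")
  invisible(x)
}

#' Session kind ("static" or "dynamic")
#' @param session An [emg_session()].
#' @return `"static"` if the stimulus is a label factor, else `"dynamic"`.
#' @export
session_kind <- function(session) {
  if (is.factor(session$stimulus)) "static" else "dynamic"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Band-limited unit-RMS Gaussian noise
#'
#' White Gaussian noise passed through a 4th-order Butterworth band-pass
#' filter (applied forward and backward with [signal::filtfilt()] for zero
#' phase), then rescaled so its sample RMS is exactly 1. The exact
#' normalization conditions the draw on its empirical power, which makes
#' downstream amplitude targets exact at the whole-segment scale while
#' leaving within-segment windowed fluctuations intact.
#'
#' @param n Number of samples (at least 24, to accommodate the filter's
#'   start-up transient).
#' @param band Length-2 pass band in Hz; the upper edge is clipped just
#'   below Nyquist.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (and advanced).
#'
#' @return Numeric vector of length `n`, zero-mean, unit sample RMS.
#' @export
bandlimited_noise <- function(n, band = c(10, 500), sample_rate = 2000,
                              seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 24)
  if (band[1] >= band[2]) stop("`band` must satisfy low < high")
  draw <- function() .filter_band(rnorm(n), band, sample_rate)
  x <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}

# Butterworth band-pass (or low-pass when the low edge is 0); upper edge
# clipped below Nyquist.
.filter_band <- function(x, band, sample_rate) {
  nyq <- sample_rate / 2
  hi <- min(band[2], 0.99 * nyq)
  lo <- max(band[1], 0)
  if (lo <= 0) {
    bf <- signal::butter(4, hi / nyq, type = "low")
  } else {
    bf <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
  }
  signal::filtfilt(bf, x)
}

# Unit-RMS band noise from the *current* RNG state (internal to generators).
.unit_noise <- function(n, params) {
  x <- .filter_band(rnorm(n), params$band, params$sample_rate)
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}

#' Generate a synthetic static-contraction session
#'
#' Simulates the held-position protocol: at each position the channel is
#' band-limited Gaussian noise scaled so the hold's sample RMS equals
#' `envelope_fn(angle) * direction_gain * channel_gain + noise_floor`, where
#' the direction gain is `hysteresis_gain` on the adduction branch and 1
#' otherwise. Per-sample labels identify the position; optional
#' repositioning gaps are tagged `"gap"` with an `NA` label and carry only
#' baseline noise.
#'
#' @param params A [synth_params()].
#' @param protocol A [static_protocol()].
#' @param subject Optional subject identifier stored in metadata.
#'
#' @return An [emg_session()] with a factor stimulus.
#' @export
generate_static_session <- function(params = synth_params(),
                                    protocol = static_protocol(),
                                    subject = NULL) {
  stopifnot(inherits(params, "synth_params"),
            inherits(protocol, "static_protocol"))
  fs <- params$sample_rate
  hold_n <- round(protocol$hold_duration * fs)
  gap_n <- round(protocol$gap_duration * fs)
  if (hold_n < 24) stop("hold_duration too short for the band filter")

  segs <- switch(protocol$direction,
    abduction = data.frame(angle = protocol$positions, dir = "abduction"),
    adduction = data.frame(angle = protocol$positions, dir = "adduction"),
    both = rbind(
      data.frame(angle = protocol$positions, dir = "abduction"),
      data.frame(angle = rev(protocol$positions), dir = "adduction"))
  )
  lvls <- as.character(sort(unique(protocol$positions)))
  n_seg <- nrow(segs)
  n_total <- n_seg * hold_n + (n_seg - 1L) * gap_n
  K <- length(params$channel_gains)

  gen <- function() {
    emg <- matrix(0, n_total, K)
    label <- rep(NA_character_, n_total)
    dir <- rep("gap", n_total)
    for (ch in seq_len(K)) {
      pos <- 1L
      for (i in seq_len(n_seg)) {
        a <- segs$angle[i]
        dgain <- if (segs$dir[i] == "adduction") params$hysteresis_gain else 1
        amp <- params$envelope_fn(a) * dgain * params$channel_gains[ch] +
          params$noise_floor
        if (amp < 0) stop("negative target amplitude at angle ", a)
        idx <- pos:(pos + hold_n - 1L)
        emg[idx, ch] <- if (amp > 0) amp * .unit_noise(hold_n, params) else 0
        if (ch == 1L) {
          label[idx] <- as.character(a)
          dir[idx] <- segs$dir[i]
        }
        pos <- pos + hold_n
        if (gap_n > 0L && i < n_seg) {
          gidx <- pos:(pos + gap_n - 1L)
          if (params$noise_floor > 0)
            emg[gidx, ch] <- params$noise_floor * .unit_noise(gap_n, params)
          pos <- pos + gap_n
        }
      }
    }
    list(emg = emg, label = label, dir = dir)
  }
  out <- if (is.null(params$seed)) gen() else
    withr::with_seed(params$seed, gen())

  emg_session(
    out$emg, fs,
    stimulus = factor(out$label, levels = lvls),
    direction = out$dir,
    metadata = list(kind = "static", seed = params$seed, subject = subject,
                    protocol = unclass(protocol),
                    hysteresis_gain = params$hysteresis_gain,
                    noise_floor = params$noise_floor,
                    channel_gains = params$channel_gains,
                    band = params$band)
  )
}

#' Generate a synthetic dynamic-contraction session
#'
#' Simulates the continuous movement protocol: the angle trace ramps from
#' the bottom to the top of the range at constant `speed` (abduction), holds
#' at the top, and optionally ramps back (adduction), for `n_cycles` cycles.
#' Each channel is a single stream of unit-RMS band-limited noise modulated
#' sample-by-sample by the target amplitude
#' `envelope_fn(angle) * direction_gain * channel_gain + noise_floor`
#' (direction gain = `hysteresis_gain` during adduction, 1 during abduction
#' and the top hold).
#'
#' @inheritParams generate_static_session
#' @param protocol A [dynamic_protocol()].
#'
#' @return An [emg_session()] with a numeric angle-trace stimulus.
#' @export
generate_dynamic_session <- function(params = synth_params(),
                                     protocol = dynamic_protocol(),
                                     subject = NULL) {
  stopifnot(inherits(params, "synth_params"),
            inherits(protocol, "dynamic_protocol"))
  fs <- params$sample_rate
  a0 <- protocol$angle_range[1]; a1 <- protocol$angle_range[2]
  n_up <- round((a1 - a0) / protocol$speed * fs)
  n_hold <- round(protocol$hold_at_top * fs)
  up <- a0 + (seq_len(n_up) - 1L) * protocol$speed / fs
  angle_cycle <- c(up, rep(a1, n_hold))
  dir_cycle <- c(rep("abduction", n_up), rep("hold", n_hold))
  if (protocol$include_adduction) {
    down <- a1 - (seq_len(n_up) - 1L) * protocol$speed / fs
    angle_cycle <- c(angle_cycle, down)
    dir_cycle <- c(dir_cycle, rep("adduction", n_up))
  }
  angle <- rep(angle_cycle, protocol$n_cycles)
  dir <- rep(dir_cycle, protocol$n_cycles)
  n <- length(angle)
  if (n < 24) stop("protocol too short for the band filter")
  K <- length(params$channel_gains)

  env <- params$envelope_fn(angle)
  if (length(env) == 1L) env <- rep(env, n)
  if (length(env) != n)
    stop("`envelope_fn` must be vectorized over angle")
  if (any(env < 0)) stop("`envelope_fn` must be >= 0 on the angle range")
  dgain <- ifelse(dir == "adduction", params$hysteresis_gain, 1)

  gen <- function() {
    emg <- matrix(0, n, K)
    for (ch in seq_len(K)) {
      amp <- env * dgain * params$channel_gains[ch] + params$noise_floor
      emg[, ch] <- amp * .unit_noise(n, params)
    }
    emg
  }
  emg <- if (is.null(params$seed)) gen() else withr::with_seed(params$seed, gen())

  emg_session(
    emg, fs, stimulus = angle, direction = dir,
    metadata = list(kind = "dynamic", seed = params$seed, subject = subject,
                    protocol = unclass(protocol),
                    hysteresis_gain = params$hysteresis_gain,
                    noise_floor = params$noise_floor,
                    channel_gains = params$channel_gains,
                    band = params$band)
  )
}
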
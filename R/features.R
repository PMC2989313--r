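#' Window specification for segmentation
#'
#' @param length_ms Window length in milliseconds.
#' @param overlap_ms Overlap between consecutive windows in milliseconds
#'   (default 0; the reference pipeline is non-overlapping).
#'
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_ms, overlap_ms = 0) {
  stopifnot(is.numeric(length_ms), length(length_ms) == 1L, length_ms > 0)
  stopifnot(is.numeric(overlap_ms), length(overlap_ms) == 1L)
  if (overlap_ms < 0 || overlap_ms >= length_ms)
    stop("`overlap_ms` must satisfy 0 <= overlap < length")
  structure(list(length_ms = length_ms, overlap_ms = overlap_ms),
            class = "window_spec")
}

#' Segment a session into windows
#'
#' Splits one channel into fixed-length windows (length `round(length_ms *
#' fs / 1000)` samples) stepping by length minus overlap; a trailing partial
#' window is dropped. Each window carries a stimulus attribute: for a static
#' session, the position label, with windows that straddle two labels or
#' contain gap samples discarded; for a dynamic session, the mean of the
#' angle trace over the window. The direction tag is taken at the window's
#' center sample.
#'
#' @param session An [emg_session()].
#' @param spec A [window_spec()], or a window length in ms.
#' @param channel Channel index (default 1).
#'
#' @return A list of class `segmented_windows` with elements `windows`
#'   (a `N x m` matrix, one kept window per column), `stimulus`, `direction`,
#'   `time_s` (window center times), `window_samples`, and `n_dropped`
#'   (windows discarded for mixed labels / gaps).
#' @export
segment_windows <- function(session, spec, channel = 1) {
  if (is.numeric(spec)) spec <- window_spec(spec)
  stopifnot(inherits(session, "emg_session"), inherits(spec, "window_spec"))
  if (channel < 1 || channel > ncol(session$emg))
    stop("channel out of range")
  fs <- session$sample_rate
  N <- round(spec$length_ms * fs / 1000)
  if (N < 2) stop("window must contain at least 2 samples")
  n <- nrow(session$emg)
  if (N > n) stop("window longer than session")
  step <- N - round(spec$overlap_ms * fs / 1000)
  starts <- seq.int(1L, n - N + 1L, by = step)
  m <- length(starts)
  idx <- outer(seq_len(N) - 1L, starts, `+`)

  x <- session$emg[, channel]
  W <- matrix(x[idx], nrow = N)
  time_s <- (starts - 1 + (N - 1) / 2) / fs
  dir <- session$direction[starts + N %/% 2L]

  if (is.factor(session$stimulus)) {
    code <- as.integer(session$stimulus)
    C <- matrix(code[idx], nrow = N)
    C[is.na(C)] <- 0L
    first <- C[1L, ]
    keep <- first > 0L &
      colSums(C == matrix(first, N, m, byrow = TRUE)) == N
    stim <- factor(levels(session$stimulus)[ifelse(keep, first, NA)],
                   levels = levels(session$stimulus))
    out <- list(windows = W[, keep, drop = FALSE],
                stimulus = stim[keep],
                direction = dir[keep],
                time_s = time_s[keep],
                window_samples = N,
                n_dropped = sum(!keep))
  } else {
    A <- matrix(session$stimulus[idx], nrow = N)
    out <- list(windows = W, stimulus = colMeans(A), direction = dir,
                time_s = time_s, window_samples = N, n_dropped = 0L)
  }
  class(out) <- "segmented_windows"
  out
}

#' Root mean square of a window
#'
#' `sqrt(mean(x^2))`: the RMS amplitude estimator.
#'
#' @param window Numeric vector, at least one sample.
#' @return Non-negative scalar, signal units.
#' @export
rms <- function(window) {
  if (length(window) < 1L) stop("empty window")
  sqrt(mean(window^2))
}

#' Absolute mean value of a window
#'
#' `mean(abs(x))`: the AMV (average rectified value) estimator.
#'
#' @inheritParams rms
#' @return Non-negative scalar, signal units.
#' @export
amv <- function(window) {
  if (length(window) < 1L) stop("empty window")
  mean(abs(window))
}

#' Difference absolute mean value of a window
#'
#' Mean absolute first difference, `sum(abs(diff(x))) / (N - 1)`: the DAMV
#' estimator. Invariant under additive offsets.
#'
#' @inheritParams rms
#' @return Non-negative scalar, signal units.
#' @export
damv <- function(window) {
  n <- length(window)
  if (n < 2L) stop("DAMV needs at least 2 samples")
  sum(abs(diff(window))) / (n - 1)
}

#' Variance of a window (population form)
#'
#' `mean(x^2) - mean(x)^2`: the VAR amplitude estimator, using the
#' divisor-`N` (population) form implied by its expectation definition.
#' Invariant under additive offsets; equals `rms(x)^2` for zero-mean
#' windows.
#'
#' @inheritParams rms
#' @return Non-negative scalar, squared signal units.
#' @export
var_feature <- function(window) {
  if (length(window) < 1L) stop("empty window")
  max(0, mean(window^2) - mean(window)^2)
}

#' Supported amplitude-estimation techniques
#' @return Character vector `c("RMS", "AMV", "DAMV", "VAR")`.
#' @export
techniques <- function() c("RMS", "AMV", "DAMV", "VAR")

# Column-wise estimator evaluation on a window matrix.
.feature_values <- function(W, technique) {
  switch(technique,
    RMS  = sqrt(colMeans(W^2)),
    AMV  = colMeans(abs(W)),
    DAMV = colSums(abs(diff(W))) / (nrow(W) - 1),
    VAR  = pmax(0, colMeans(W^2) - colMeans(W)^2),
    stop("unknown technique: ", technique)
  )
}

#' Extract a windowed feature series from a session
#'
#' Segments the chosen channel ([segment_windows()]) and evaluates one
#' amplitude estimator per window, carrying the per-window stimulus
#' attribute and direction tag through.
#'
#' @inheritParams segment_windows
#' @param technique One of `"RMS"`, `"AMV"`, `"DAMV"`, `"VAR"`.
#'
#' @return A data frame of class `feature_series` with columns `time_s`,
#'   `stimulus`, `direction`, `value`, and attributes `technique`,
#'   `window_ms`, `sample_rate`, `mode` (`"static"`/`"dynamic"`), and
#'   `n_dropped`.
#' @export
extract_features <- function(session, spec, technique = "RMS", channel = 1) {
  technique <- match.arg(toupper(technique), techniques())
  seg <- segment_windows(session, spec, channel)
  if (is.numeric(spec)) spec <- window_spec(spec)
  out <- data.frame(time_s = seg$time_s,
                    stimulus = seg$stimulus,
                    direction = seg$direction,
                    value = .feature_values(seg$windows, technique),
                    stringsAsFactors = FALSE)
  structure(out,
            technique = technique,
            window_ms = spec$length_ms,
            sample_rate = session$sample_rate,
            mode = session_kind(session),
            n_dropped = seg$n_dropped,
            class = c("feature_series", "data.frame"))
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s, %d windows of %g ms (%s mode)\n",
              attr(x, "technique"), nrow(x), attr(x, "window_ms"),
              attr(x, "mode")))
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more windows\n")
  invisible(x)
}
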
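#' Information versus window length for one session
#'
#' Computes one information value per window length: segment, evaluate the
#' estimator per window, discretize, and take the plug-in mutual
#' information. Lengths that yield fewer than `min_windows` windows or fewer
#' than two occupied stimulus bins are reported as `NA` (missing), never
#' silently dropped. Reference grids are 20-1000 ms step 10 for static
#' sessions and 20-2000 ms step 10 for dynamic ones.
#'
#' @param session An [emg_session()].
#' @param technique Amplitude estimator, see [techniques()].
#' @param lengths_ms Numeric grid of window lengths in milliseconds.
#' @param stim_bin_deg Angle bin width in degrees (dynamic sessions).
#' @param response_rule,response_bins Response discretization, see
#'   [response_bin_count()].
#' @param channel Channel index.
#' @param min_windows Minimum stimulus-response pairs per length (default 4,
#'   the floor of the square-root binning rule).
#'
#' @return Data frame with columns `window_ms`, `information_bits`,
#'   `n_windows`.
#' @export
window_sweep <- function(session, technique = "RMS", lengths_ms,
                         stim_bin_deg = 5, response_rule = "sqrt",
                         response_bins = NULL, channel = 1,
                         min_windows = 4) {
  if (length(lengths_ms) < 1L) stop("empty window-length grid")
  info <- rep(NA_real_, length(lengths_ms))
  nw <- rep(NA_integer_, length(lengths_ms))
  for (i in seq_along(lengths_ms)) {
    res <- tryCatch({
      fs <- extract_features(session, lengths_ms[i], technique, channel)
      if (nrow(fs) < min_windows) stop("too few windows")
      mi <- suppressWarnings(
        series_information(fs, stim_bin_deg, response_rule, response_bins))
      list(mi$information, nrow(fs))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      info[i] <- res[[1]]
      nw[i] <- res[[2]]
    }
  }
  data.frame(window_ms = lengths_ms, information_bits = info, n_windows = nw)
}

#' Normalize per-subject information curves and aggregate
#'
#' Each subject's information-versus-window-length curve is divided by its
#' own maximum (so every curve peaks at exactly 1), then the mean and
#' standard deviation across subjects are taken per window length.
#'
#' @param curves A list of [window_sweep()] data frames sharing the same
#'   `window_ms` grid (one per subject/session), or a single such data
#'   frame.
#'
#' @return An object of class `sweep_result`: list with `window_ms`,
#'   `information` (subjects-by-lengths matrix, raw bits), `normalized`
#'   (same shape), and `summary` (data frame: `window_ms`, `mean_norm`,
#'   `sd_norm`, `mean_bits`, `sd_bits`).
#' @export
normalize_and_aggregate <- function(curves) {
  if (is.data.frame(curves)) curves <- list(curves)
  if (length(curves) < 1L) stop("no curves supplied")
  grid <- curves[[1]]$window_ms
  for (cv in curves) {
    if (!identical(cv$window_ms, grid))
      stop("curves must share the same window-length grid")
  }
  raw <- do.call(rbind, lapply(curves, function(cv) cv$information_bits))
  norm <- t(apply(raw, 1L, function(v) {
    if (all(is.na(v))) stop("a curve has no finite information values")
    v / max(v, na.rm = TRUE)
  }))
  summ <- data.frame(
    window_ms = grid,
    mean_norm = apply(norm, 2L, mean, na.rm = TRUE),
    sd_norm = apply(norm, 2L, function(v)
      if (sum(!is.na(v)) > 1L) sd(v, na.rm = TRUE) else 0),
    mean_bits = apply(raw, 2L, mean, na.rm = TRUE),
    sd_bits = apply(raw, 2L, function(v)
      if (sum(!is.na(v)) > 1L) sd(v, na.rm = TRUE) else 0)
  )
  structure(list(window_ms = grid, information = raw, normalized = norm,
                 summary = summ),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d subject(s), %d window lengths (%g..%g ms)\n",
              nrow(x$information), length(x$window_ms),
              min(x$window_ms), max(x$window_ms)))
  opt <- optimal_window(x)
  cat(sprintf("  optimal window %g ms; plateau %g..%g ms\n",
              opt$optimum_ms, opt$plateau_ms[1], opt$plateau_ms[2]))
  invisible(x)
}

#' Plot an aggregated information-vs-window-length curve
#'
#' Mean normalized information with a +/- SD band, the usual display of a
#' segmentation sweep.
#'
#' @param x A `sweep_result`.
#' @param ... Passed to [graphics::plot()].
#' @importFrom graphics plot polygon lines
#' @importFrom grDevices adjustcolor
#' @export
plot.sweep_result <- function(x, ...) {
  s <- x$summary
  ok <- !is.na(s$mean_norm)
  plot(s$window_ms[ok], s$mean_norm[ok], type = "n",
       xlab = "window length (ms)", ylab = "normalized information", ...)
  polygon(c(s$window_ms[ok], rev(s$window_ms[ok])),
          c(pmin(1, s$mean_norm[ok] + s$sd_norm[ok]),
            rev(pmax(0, s$mean_norm[ok] - s$sd_norm[ok]))),
          border = NA, col = adjustcolor("grey40", 0.3))
  lines(s$window_ms[ok], s$mean_norm[ok], lwd = 2)
  invisible(x)
}

#' Optimal window length and information plateau
#'
#' The optimal segmentation is read off the aggregated curve with a plateau
#' criterion: the smallest window length whose mean normalized information
#' reaches `(1 - tolerance)` of the curve's global maximum, together with
#' the contiguous run of qualifying lengths containing it. With
#' `tolerance = 0` this reduces to the peak location.
#'
#' @param sweep A `sweep_result` (or a single [window_sweep()] data frame).
#' @param tolerance Fraction of the maximum regarded as "at the plateau"
#'   (default 0.05).
#'
#' @return List with `optimum_ms`, `plateau_ms` (length-2 range), and
#'   `threshold` (bits or normalized units, as aggregated).
#' @export
optimal_window <- function(sweep, tolerance = 0.05) {
  if (is.data.frame(sweep)) sweep <- normalize_and_aggregate(sweep)
  stopifnot(inherits(sweep, "sweep_result"))
  stopifnot(tolerance >= 0, tolerance < 1)
  mu <- sweep$summary$mean_norm
  grid <- sweep$summary$window_ms
  ok <- !is.na(mu)
  if (!any(ok)) stop("no finite values in the aggregated curve")
  thr <- (1 - tolerance) * max(mu[ok])
  qual <- ok & mu >= thr - 1e-12
  first <- which(qual)[1]
  run_end <- first
  while (run_end < length(qual) && qual[run_end + 1L]) run_end <- run_end + 1L
  list(optimum_ms = grid[first],
       plateau_ms = c(grid[first], grid[run_end]),
       threshold = thr)
}

#' Compare amplitude-estimation techniques at a fixed window length
#'
#' Computes the information each technique extracts from each session at
#' one segmentation, and summarizes as mean and standard deviation across
#' sessions, the study-level technique comparison.
#'
#' @param sessions A list of [emg_session()] objects (or a single session).
#' @param window_ms Window length in milliseconds.
#' @param techniques Character vector of estimators (default all four).
#' @inheritParams window_sweep
#'
#' @return List of class `emg_comparison`: `results` (tidy data frame:
#'   `session`, `technique`, `information_bits`, `n_windows`) and `summary`
#'   (`technique`, `mean_bits`, `sd_bits`, `n_sessions`).
#' @export
compare_techniques <- function(sessions, window_ms,
                               techniques = c("RMS", "AMV", "DAMV", "VAR"),
                               stim_bin_deg = 5, response_rule = "sqrt",
                               response_bins = NULL, channel = 1) {
  if (inherits(sessions, "emg_session")) sessions <- list(sessions)
  if (length(sessions) < 1L) stop("no sessions supplied")
  rows <- list()
  for (i in seq_along(sessions)) {
    for (tech in techniques) {
      fs <- extract_features(sessions[[i]], window_ms, tech, channel)
      mi <- suppressWarnings(
        series_information(fs, stim_bin_deg, response_rule, response_bins))
      rows[[length(rows) + 1L]] <- data.frame(
        session = i, technique = tech,
        information_bits = mi$information, n_windows = nrow(fs))
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results$technique),
    function(d) data.frame(technique = d$technique[1],
                           mean_bits = mean(d$information_bits),
                           sd_bits = if (nrow(d) > 1L) sd(d$information_bits)
                                     else 0,
                           n_sessions = nrow(d))))
  summ <- summ[match(techniques, summ$technique), ]
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ),
            class = "emg_comparison")
}

#' @export
print.emg_comparison <- function(x, ...) {
  cat("<emg_comparison> information (bits), mean +/- SD across sessions:\n")
  with(x$summary, for (i in seq_along(technique))
    cat(sprintf("  %-5s %.3f +/- %.3f  (n = %d)\n", technique[i],
                mean_bits[i], sd_bits[i], n_sessions[i])))
  invisible(x)
}

# Information on a subset of windows of a feature series (the joint
# builders only consume the stimulus and value columns).
.subset_information <- function(fs, keep, stim_bin_deg, response_rule,
                                response_bins) {
  sub <- as.data.frame(fs)[keep, , drop = FALSE]
  mi <- suppressWarnings(
    series_information(sub, stim_bin_deg, response_rule, response_bins))
  c(mi$information, nrow(sub))
}

#' Abduction / adduction information analysis
#'
#' Quantifies the movement-direction (hysteresis) effect: the information
#' computed from abduction-branch windows only, adduction-branch windows
#' only, and the pooled set. Windows tagged `"hold"` (top-of-range dwell in
#' dynamic sessions) contribute the top angle bin to both single-direction
#' subsets as well as to the pooled set; this inclusion is recorded in the
#' returned metadata.
#'
#' @inheritParams compare_techniques
#' @param session An [emg_session()] whose direction tags include both
#'   `abduction` and `adduction`.
#' @param technique One amplitude estimator.
#'
#' @return Data frame with columns `direction`
#'   (`abduction`/`adduction`/`pooled`), `information_bits`, `n_windows`;
#'   attribute `hold_windows` notes the hold-window policy.
#' @export
direction_analysis <- function(session, window_ms, technique = "RMS",
                               stim_bin_deg = 5, response_rule = "sqrt",
                               response_bins = NULL, channel = 1) {
  fs <- extract_features(session, window_ms, technique, channel)
  dirs <- unique(fs$direction)
  if (!all(c("abduction", "adduction") %in% dirs))
    stop("session must contain both abduction and adduction windows")
  sel <- list(abduction = fs$direction %in% c("abduction", "hold"),
              adduction = fs$direction %in% c("adduction", "hold"),
              pooled = fs$direction %in% c("abduction", "adduction", "hold"))
  out <- do.call(rbind, lapply(names(sel), function(nm) {
    v <- .subset_information(fs, sel[[nm]], stim_bin_deg, response_rule,
                             response_bins)
    data.frame(direction = nm, information_bits = v[1], n_windows = v[2])
  }))
  attr(out, "hold_windows") <-
    "hold-tagged windows included in both single-direction subsets (top angle bin)"
  out
}

#' Inter-electrode-distance (multi-channel) information analysis
#'
#' Applies the direction analysis to every channel of a multi-channel
#' session using the same windows, emulating the comparison of
#' simultaneously recorded inter-electrode distances (channels differ by
#' envelope gain / SNR in the generator).
#'
#' @inheritParams direction_analysis
#' @param session A multi-channel [emg_session()] (>= 2 channels).
#'
#' @return Data frame with columns `channel`, `direction`,
#'   `information_bits`, `n_windows`.
#' @export
ied_analysis <- function(session, window_ms, technique = "RMS",
                         stim_bin_deg = 5, response_rule = "sqrt",
                         response_bins = NULL) {
  K <- ncol(session$emg)
  if (K < 2L) stop("IED analysis needs at least 2 channels")
  out <- do.call(rbind, lapply(seq_len(K), function(ch) {
    d <- direction_analysis(session, window_ms, technique, stim_bin_deg,
                            response_rule, response_bins, channel = ch)
    cbind(channel = ch, d)
  }))
  rownames(out) <- NULL
  out
}
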
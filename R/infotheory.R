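#' Number of response bins from the histogram square-root rule
#'
#' The response (feature) axis is discretized with the common histogram
#' rule: the class count is approximately the square root of the number of
#' data points. Rounding is half-away-from-zero with a floor of 2 bins; a
#' fixed count can be forced instead.
#'
#' @param n_pairs Number of stimulus-response pairs (windows).
#' @param rule `"sqrt"` (default) or `"fixed"`.
#' @param m Bin count when `rule = "fixed"` (>= 2).
#'
#' @return Integer bin count.
#' @export
response_bin_count <- function(n_pairs, rule = c("sqrt", "fixed"), m = NULL) {
  rule <- match.arg(rule)
  if (rule == "fixed") {
    if (is.null(m) || m < 2) stop("fixed rule needs `m` >= 2")
    return(as.integer(m))
  }
  if (n_pairs < 4) stop("square-root rule needs at least 4 pairs")
  max(2L, as.integer(floor(sqrt(n_pairs) + 0.5)))
}

# Equal-width binning over [lo, hi], left-closed bins with the maximum
# clamped into the top bin (so the last bin is right-closed).
.equal_width_bin <- function(x, lo, hi, nbins) {
  if (hi <= lo) return(rep(1L, length(x)))
  b <- floor((x - lo) / (hi - lo) * nbins) + 1L
  pmin.int(pmax.int(b, 1L), nbins)
}

#' Construct a joint stimulus-response distribution
#'
#' Low-level constructor from a co-occurrence count matrix (rows = stimulus
#' bins, columns = response bins) or directly from a probability matrix.
#'
#' @param counts Non-negative count matrix, or `NULL` if `probs` is given.
#' @param probs Probability matrix (entries >= 0 summing to 1), or `NULL`.
#' @param stimulus_bins Row labels: class labels, or numeric bin edges of
#'   length `nrow + 1` (degrees).
#' @param response_edges Numeric response bin edges of length `ncol + 1`, or
#'   `NULL`.
#'
#' @return An object of class `joint_distribution` with elements `probs`,
#'   `counts`, `stimulus_bins`, `response_edges`, `n` (total count, `NA`
#'   when built from probabilities).
#' @export
joint_distribution <- function(counts = NULL, probs = NULL,
                               stimulus_bins = NULL, response_edges = NULL) {
  if (is.null(counts) && is.null(probs))
    stop("provide `counts` or `probs`")
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("negative counts")
    total <- sum(counts)
    if (total <= 0) stop("empty co-occurrence matrix")
    probs <- counts / total
    n <- total
  } else {
    probs <- as.matrix(probs)
    if (any(probs < 0)) stop("negative probabilities")
    s <- sum(probs)
    if (abs(s - 1) > 1e-8) stop("probabilities must sum to 1")
    probs <- probs / s
    counts <- NULL
    n <- NA_real_
  }
  if (!is.null(response_edges) && any(diff(response_edges) <= 0) &&
      length(response_edges) > 2)
    stop("response bin edges must be strictly increasing")
  structure(list(probs = probs, counts = counts,
                 stimulus_bins = stimulus_bins,
                 response_edges = response_edges, n = n),
            class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat(sprintf("<joint_distribution> %d stimulus x %d response bins (n = %s)\n",
              nrow(x$probs), ncol(x$probs),
              if (is.na(x$n)) "?" else format(x$n)))
  invisible(x)
}

#' Joint distribution for a static (labelled-position) session
#'
#' Builds the stimulus-by-response probability matrix from a class-labelled
#' feature series: response bins are equal-width over the global observed
#' min-max (count from [response_bin_count()] over all pairs), each
#' (class, response-bin) pair increments one cell, and the matrix is
#' normalized by the total window count, so the stimulus marginal reflects
#' the empirical per-class window counts.
#'
#' If every response is identical the response axis degenerates to a single
#' bin (information 0 downstream) with a warning.
#'
#' @param series A [extract_features()] series with factor (label) stimuli.
#' @param response_rule `"sqrt"` (default) or `"fixed"`.
#' @param response_bins Bin count when `response_rule = "fixed"`.
#'
#' @return A [joint_distribution()].
#' @export
build_joint_static <- function(series, response_rule = "sqrt",
                               response_bins = NULL) {
  stim <- series$stimulus
  if (!is.factor(stim)) stop("static joint needs class-label stimuli")
  keep <- !is.na(stim)
  stim <- droplevels(stim[keep])
  r <- series$value[keep]
  n <- length(r)
  if (n < 1L) stop("no usable windows")
  lo <- min(r); hi <- max(r)
  if (hi <= lo) {
    warning("all responses identical; using a single degenerate response bin")
    nb <- 1L
    edges <- c(lo, lo)
    rbin <- rep(1L, n)
  } else {
    nb <- response_bin_count(n, response_rule, response_bins)
    edges <- seq(lo, hi, length.out = nb + 1L)
    rbin <- .equal_width_bin(r, lo, hi, nb)
  }
  counts <- table(stimulus = stim,
                  response = factor(rbin, levels = seq_len(nb)))
  joint_distribution(counts = unclass(counts),
                     stimulus_bins = levels(stim),
                     response_edges = edges)
}

#' Joint distribution for a dynamic (angle-trace) session
#'
#' Builds the co-occurrence matrix of the sliding-window design: stimulus
#' rows are equal-width angle bins of `stim_bin_deg` degrees spanning the
#' observed min-max of the per-window mean angle; response columns are as in
#' the static design. Each window increments one cell; normalization by the
#' window count gives the joint distribution, whose row and column sums are
#' the stimulus and response marginals.
#'
#' @param series A [extract_features()] series with numeric (degrees)
#'   window stimuli.
#' @param stim_bin_deg Stimulus bin width in degrees (default 5, the
#'   reference discretization; 3, 8 and 10 are also studied).
#' @inheritParams build_joint_static
#'
#' @return A [joint_distribution()] whose `stimulus_bins` are the angle bin
#'   edges.
#' @export
build_joint_dynamic <- function(series, stim_bin_deg = 5,
                                response_rule = "sqrt",
                                response_bins = NULL) {
  s <- series$stimulus
  if (is.factor(s)) stop("dynamic joint needs a continuous angle stimulus")
  stopifnot(is.numeric(stim_bin_deg), stim_bin_deg > 0)
  r <- series$value
  n <- length(r)
  if (n < 1L) stop("no usable windows")
  smin <- min(s); smax <- max(s)
  ns <- max(2L, as.integer(ceiling((smax - smin) / stim_bin_deg - 1e-9)))
  sedges <- smin + stim_bin_deg * (0:ns)
  sbin <- pmin.int(floor((s - smin) / stim_bin_deg) + 1L, ns)
  if (length(unique(sbin)) < 2L)
    stop("fewer than 2 occupied stimulus bins")
  lo <- min(r); hi <- max(r)
  if (hi <= lo) {
    warning("all responses identical; using a single degenerate response bin")
    nb <- 1L
    redges <- c(lo, lo)
    rbin <- rep(1L, n)
  } else {
    nb <- response_bin_count(n, response_rule, response_bins)
    redges <- seq(lo, hi, length.out = nb + 1L)
    rbin <- .equal_width_bin(r, lo, hi, nb)
  }
  counts <- table(stimulus = factor(sbin, levels = seq_len(ns)),
                  response = factor(rbin, levels = seq_len(nb)))
  joint_distribution(counts = unclass(counts),
                     stimulus_bins = sedges,
                     response_edges = redges)
}

#' Marginal distributions of a joint
#'
#' Row sums give the stimulus marginal `P(s)`; column sums give the response
#' marginal `P(r)` (the sum of joint probabilities over stimuli for each
#' response).
#'
#' @param joint A [joint_distribution()].
#' @return List with numeric vectors `p_s` and `p_r`.
#' @export
marginals <- function(joint) {
  stopifnot(inherits(joint, "joint_distribution"))
  list(p_s = rowSums(joint$probs), p_r = colSums(joint$probs))
}

#' Conditional stimulus distribution given the response
#'
#' `P(s | r) = P(s, r) / P(r)` column by column. Columns with `P(r) = 0`
#' are undefined (`NA`); they carry no probability and are excluded from
#' the information sum.
#'
#' @param joint A [joint_distribution()].
#' @return Matrix of the same shape as `joint$probs`.
#' @export
conditional_stimulus <- function(joint) {
  stopifnot(inherits(joint, "joint_distribution"))
  p_r <- colSums(joint$probs)
  out <- sweep(joint$probs, 2L, p_r, `/`)
  out[, p_r == 0] <- NA_real_
  out
}

#' Mutual information of a joint stimulus-response distribution
#'
#' The plug-in Shannon information, in bits, computed in the
#' response-decomposed form
#' `I = sum_r P(r) * sum_s P(s|r) * log2( P(s|r) / P(s) )`,
#' with `0 * log 0 = 0` and zero-probability responses skipped. No
#' smoothing is applied; an optional Miller-Madow first-order bias
#' correction (based on occupied-cell counts) is available but off by
#' default, matching the raw plug-in estimate.
#'
#' @param joint A [joint_distribution()].
#' @param bias_correction `"none"` (default) or `"miller_madow"`.
#'
#' @return An object of class `mi_result`: list with `information` (bits),
#'   `joint`, `p_s`, `p_r`, `n_windows`.
#' @export
mutual_information <- function(joint, bias_correction = c("none",
                                                          "miller_madow")) {
  stopifnot(inherits(joint, "joint_distribution"))
  bias_correction <- match.arg(bias_correction)
  P <- joint$probs
  p_s <- unname(rowSums(P))
  p_r <- unname(colSums(P))
  info <- 0
  for (j in which(p_r > 0)) {
    cond <- P[, j] / p_r[j]
    nz <- cond > 0
    info <- info + p_r[j] * sum(cond[nz] * log2(cond[nz] / p_s[nz]))
  }
  if (bias_correction == "miller_madow" && !is.na(joint$n)) {
    k_sr <- sum(P > 0); k_s <- sum(p_s > 0); k_r <- sum(p_r > 0)
    info <- info + (k_s + k_r - k_sr - 1) / (2 * joint$n * log(2))
  }
  structure(list(information = info, joint = joint, p_s = p_s, p_r = p_r,
                 n_windows = joint$n),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result> I = %.4f bits (%d x %d bins, n = %s)\n",
              x$information, nrow(x$joint$probs), ncol(x$joint$probs),
              if (is.na(x$n_windows)) "?" else format(x$n_windows)))
  invisible(x)
}

#' Shannon entropy of a discrete distribution, in bits
#'
#' @param p Numeric vector of probabilities (zeros allowed).
#' @return Entropy in bits.
#' @export
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information of a feature series (one call from windows to bits)
#'
#' Convenience wrapper: builds the static or dynamic joint (according to
#' the series' stimulus kind) and returns [mutual_information()].
#'
#' @param series A [extract_features()] series.
#' @param stim_bin_deg Angle bin width in degrees (dynamic only).
#' @inheritParams build_joint_static
#' @inheritParams mutual_information
#' @return An `mi_result`.
#' @export
series_information <- function(series, stim_bin_deg = 5,
                               response_rule = "sqrt", response_bins = NULL,
                               bias_correction = "none") {
  joint <- if (is.factor(series$stimulus)) {
    build_joint_static(series, response_rule, response_bins)
  } else {
    build_joint_dynamic(series, stim_bin_deg, response_rule, response_bins)
  }
  mutual_information(joint, bias_correction)
}
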
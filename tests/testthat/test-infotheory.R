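test_that("response bin count follows the square-root rule", {
  expect_equal(response_bin_count(100, "sqrt"), 10L)
  expect_equal(response_bin_count(150, "sqrt"), 12L)  # round(12.247)
  expect_equal(response_bin_count(4, "sqrt"), 2L)
  expect_equal(response_bin_count(999, "fixed", m = 8), 8L)
  expect_error(response_bin_count(3, "sqrt"), "at least 4")
  expect_error(response_bin_count(100, "fixed"), "m")
})

test_that("marginals and conditionals follow their definitions", {
  j <- joint_distribution(probs = matrix(c(0.5, 0, 0, 0.5), 2, 2))
  m <- marginals(j)
  expect_equal(m$p_s, c(0.5, 0.5))
  expect_equal(m$p_r, c(0.5, 0.5))
  cond <- conditional_stimulus(j)
  expect_equal(cond, diag(2))

  j2 <- joint_distribution(probs = matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2))
  m2 <- marginals(j2)
  expect_equal(m2$p_s, c(0.5, 0.5))
  expect_equal(m2$p_r, c(0.5, 0.5))
  cond2 <- conditional_stimulus(j2)
  expect_equal(cond2[, 1], c(0.8, 0.2))
  expect_equal(cond2[, 2], c(0.2, 0.8))

  # independent joint: every occupied column equals P(s)
  ji <- joint_distribution(probs = outer(c(0.3, 0.7), c(0.6, 0.4)))
  ci <- conditional_stimulus(ji)
  expect_equal(ci[, 1], c(0.3, 0.7))
  expect_equal(ci[, 2], c(0.3, 0.7))

  # zero-probability columns are undefined
  jz <- joint_distribution(probs = matrix(c(0.5, 0.5, 0, 0), 2, 2))
  expect_true(all(is.na(conditional_stimulus(jz)[, 2])))
})

test_that("mutual information matches hand-computed joints", {
  expect_equal(
    mutual_information(
      joint_distribution(probs = matrix(c(0.5, 0, 0, 0.5), 2, 2)))$information,
    1)
  expect_equal(
    mutual_information(
      joint_distribution(probs = matrix(0.25, 2, 2)))$information,
    0)
  # frozen value computed with the independent symmetric-form oracle
  j <- joint_distribution(probs = matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2))
  expect_equal(mi_oracle(j$probs), 0.2780719051126378, tolerance = 1e-14)
  expect_equal(mutual_information(j)$information, 0.2780719051126378,
               tolerance = 1e-12)
})

test_that("static joint reflects class structure and window counts", {
  # separable classes, equal counts -> diagonal 0.5 / 0.5
  fs <- fake_series(factor(rep(c("A", "B"), each = 10)),
                    c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1)))
  j <- build_joint_static(fs, response_rule = "fixed", response_bins = 2)
  expect_equal(unname(rowSums(j$probs)), c(0.5, 0.5))
  expect_equal(sum(j$probs %in% c(0.5)), 2)
  expect_equal(mutual_information(j)$information, 1)

  # paper-geometry pair count: 10 classes x 15 windows -> 12 response bins
  set.seed(7)
  fs2 <- fake_series(factor(rep(as.character(seq(0, 90, 10)), each = 15)),
                     rnorm(150, rep(1:10, each = 15), 0.2))
  j2 <- build_joint_static(fs2)
  expect_equal(ncol(j2$probs), 12L)
  expect_equal(nrow(j2$probs), 10L)
  expect_equal(sum(j2$probs), 1, tolerance = 1e-12)

  # all-identical responses degenerate to one bin with information zero
  fs3 <- fake_series(factor(rep(c("A", "B"), 10)), rep(2.5, 20))
  expect_warning(j3 <- build_joint_static(fs3), "degenerate")
  expect_equal(ncol(j3$probs), 1L)
  expect_equal(mutual_information(j3)$information, 0)
})

test_that("dynamic co-occurrence matrix uses equal-width degree bins", {
  set.seed(8)
  ang <- runif(2000, 0, 90 - 1e-9)
  fs <- fake_series(ang, ang + rnorm(2000, 0, 1))
  j <- build_joint_dynamic(fs, stim_bin_deg = 5)
  expect_equal(nrow(j$probs), 18L)  # 90 / 5
  expect_equal(ncol(j$probs), response_bin_count(2000))
  expect_equal(sum(j$probs), 1, tolerance = 1e-12)
  expect_length(j$stimulus_bins, 19L)
  expect_equal(diff(j$stimulus_bins), rep(5, 18))

  # deterministic strictly-increasing response, bins fine enough -> I = H(S)
  ang2 <- rep(seq(2.5, 87.5, by = 5), each = 50)
  fs2 <- fake_series(ang2, ang2 * 2)
  j2 <- build_joint_dynamic(fs2, stim_bin_deg = 5,
                            response_rule = "fixed", response_bins = 500)
  mi2 <- mutual_information(j2)
  expect_equal(mi2$information, entropy_bits(rowSums(j2$probs)),
               tolerance = 1e-12)

  expect_error(build_joint_dynamic(fake_series(rep(1, 10), rnorm(10))),
               "stimulus bins")
})

test_that("information is invariant to transposition and relabeling", {
  set.seed(99)
  for (i in 1:25) {
    P <- random_joint(sample(2:6, 1), sample(2:6, 1))
    I <- mutual_information(joint_distribution(probs = P))$information
    It <- mutual_information(joint_distribution(probs = t(P)))$information
    expect_equal(I, It, tolerance = 1e-12)
    Pp <- P[sample(nrow(P)), sample(ncol(P)), drop = FALSE]
    Ip <- mutual_information(joint_distribution(probs = Pp))$information
    expect_equal(I, Ip, tolerance = 1e-12)
    # bounded by the marginal entropies
    expect_gte(I, -1e-12)
    expect_lte(I, entropy_bits(rowSums(P)) + 1e-9)
    expect_lte(I, entropy_bits(colSums(P)) + 1e-9)
  }
})

test_that("shuffled stimulus-response pairs carry little information", {
  set.seed(21)
  n <- 5000
  stim <- factor(rep(as.character(seq(0, 90, 10)), length.out = n))
  resp <- rnorm(n, as.integer(stim), 0.3)
  resp_shuffled <- resp[sample(n)]
  mi <- series_information(fake_series(stim, resp_shuffled),
                           response_rule = "fixed", response_bins = 10)
  expect_lt(mi$information, 0.05)
})

test_that("the Miller-Madow hook adjusts by the occupied-cell count", {
  counts <- matrix(c(30, 5, 5, 30), 2, 2)
  j <- joint_distribution(counts = counts)
  plain <- mutual_information(j)$information
  mm <- mutual_information(j, bias_correction = "miller_madow")$information
  # (k_s + k_r - k_sr - 1) / (2 n ln 2) with all cells occupied: 2+2-4-1 < 0
  expect_lt(mm, plain)
  expect_equal(mm - plain, (2 + 2 - 4 - 1) / (2 * 70 * log(2)),
               tolerance = 1e-12)
})

test_that("joint_distribution validates its inputs", {
  expect_error(joint_distribution(), "provide")
  expect_error(joint_distribution(counts = matrix(-1, 2, 2)), "negative")
  expect_error(joint_distribution(probs = matrix(0.3, 2, 2)), "sum to 1")
  expect_error(joint_distribution(counts = matrix(0, 2, 2)), "empty")
})
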
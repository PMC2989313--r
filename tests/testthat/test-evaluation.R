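test_that("a one-point sweep equals the direct information computation", {
  s <- quick_static(seed = 31)
  sw <- window_sweep(s, "RMS", 200)
  fs <- extract_features(s, 200, "RMS")
  mi <- series_information(fs)
  expect_equal(sw$information_bits, mi$information)
  expect_equal(sw$n_windows, nrow(fs))
})

test_that("lengths that cannot be evaluated are reported as missing", {
  s <- quick_static(seed = 31)  # 30 s session
  sw <- window_sweep(s, "RMS", c(200, 40000))
  expect_false(is.na(sw$information_bits[1]))
  expect_true(is.na(sw$information_bits[2]))
  expect_equal(sw$window_ms, c(200, 40000))
  expect_error(window_sweep(s, "RMS", numeric(0)), "empty")
})

test_that("normalization divides each curve by its own maximum", {
  grid <- c(100, 200)
  c1 <- data.frame(window_ms = grid, information_bits = c(1, 2),
                   n_windows = c(10L, 5L))
  c2 <- data.frame(window_ms = grid, information_bits = c(2, 4),
                   n_windows = c(10L, 5L))
  agg <- normalize_and_aggregate(list(c1, c2))
  expect_equal(agg$normalized, matrix(c(0.5, 0.5, 1, 1), 2, 2))
  expect_equal(agg$summary$mean_norm, c(0.5, 1))
  expect_equal(agg$summary$sd_norm, c(0, 0))
  expect_equal(agg$summary$mean_bits, c(1.5, 3))

  # single curve: max exactly 1, SD zero everywhere
  one <- normalize_and_aggregate(c1)
  expect_equal(max(one$normalized), 1)
  expect_true(all(one$summary$sd_norm == 0))

  # idempotence: normalizing an already-normalized curve changes nothing
  cn <- data.frame(window_ms = grid,
                   information_bits = one$normalized[1, ],
                   n_windows = c(10L, 5L))
  again <- normalize_and_aggregate(cn)
  expect_equal(again$normalized[1, ], one$normalized[1, ])

  expect_error(normalize_and_aggregate(list(c1, transform(c2, window_ms = c(100, 300)))),
               "same window-length grid")
})

test_that("optimal window is the first length entering the plateau", {
  grid <- seq(20, 200, by = 20)
  rising_flat <- data.frame(
    window_ms = grid,
    information_bits = c(0.2, 0.5, 0.8, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0),
    n_windows = 100L)
  opt <- optimal_window(normalize_and_aggregate(rising_flat), tolerance = 0.05)
  expect_equal(opt$optimum_ms, 80)
  expect_equal(opt$plateau_ms, c(80, 200))

  single_peak <- data.frame(
    window_ms = grid,
    information_bits = c(0.1, 0.3, 0.6, 0.9, 1.0, 0.9, 0.6, 0.3, 0.2, 0.1),
    n_windows = 100L)
  opt0 <- optimal_window(normalize_and_aggregate(single_peak), tolerance = 0)
  expect_equal(opt0$optimum_ms, 100)
  expect_equal(opt0$plateau_ms, c(100, 100))
})

test_that("a constant envelope leaves no extractable information", {
  p <- synth_params(envelope_fn = function(a) rep(1, length(a)),
                    noise_floor = 0, seed = 17)
  s <- generate_static_session(p, static_protocol(hold_duration = 10))
  cmp <- compare_techniques(s, 200, response_rule = "fixed",
                            response_bins = 5)
  expect_true(all(cmp$summary$mean_bits < 0.15))
})

test_that("technique comparison summarizes across sessions", {
  sessions <- lapply(41:43, quick_static)
  cmp <- compare_techniques(sessions, 200)
  expect_equal(nrow(cmp$results), 12L)
  expect_equal(cmp$summary$technique, c("RMS", "AMV", "DAMV", "VAR"))
  expect_equal(cmp$summary$n_sessions, rep(3L, 4))
  expect_true(all(cmp$summary$sd_bits >= 0))
  agg <- tapply(cmp$results$information_bits, cmp$results$technique, mean)
  expect_equal(as.vector(agg[cmp$summary$technique]), cmp$summary$mean_bits)
  # RMS and AMV share amplitude statistics here: similar information
  mu <- cmp$summary$mean_bits
  expect_equal(mu[1], mu[2], tolerance = 0.15)
})

test_that("direction analysis splits and pools windows consistently", {
  s <- generate_static_session(
    synth_params(seed = 23, hysteresis_gain = 0.8),
    static_protocol(direction = "both"))
  d <- direction_analysis(s, 200)
  expect_equal(d$direction, c("abduction", "adduction", "pooled"))
  expect_equal(d$n_windows[3], d$n_windows[1] + d$n_windows[2])

  # subset consistency: the abduction row equals a direct computation on
  # the abduction windows alone
  fs <- extract_features(s, 200, "RMS")
  sub <- as.data.frame(fs)[fs$direction == "abduction", ]
  expect_equal(d$information_bits[1], series_information(sub)$information)

  abd_only <- quick_static(seed = 23)
  expect_error(direction_analysis(abd_only, 200), "both abduction and adduction")
})

test_that("pooling branches with hysteresis inflates response variance at fixed angle", {
  s <- generate_static_session(
    synth_params(seed = 29, hysteresis_gain = 0.7),
    static_protocol(direction = "both", hold_duration = 5))
  fs <- extract_features(s, 200, "RMS")
  pos <- as.character(fs$stimulus)
  v_abd <- tapply(fs$value[fs$direction == "abduction"],
                  pos[fs$direction == "abduction"], var)
  v_add <- tapply(fs$value[fs$direction == "adduction"],
                  pos[fs$direction == "adduction"], var)
  v_pool <- tapply(fs$value, pos, var)
  shared <- names(v_pool)
  expect_true(mean(v_pool[shared] > pmax(v_abd[shared], v_add[shared])) > 0.7)
})

test_that("IED analysis scores each channel on the same windows", {
  # literally identical channels -> identical information
  base <- quick_dynamic(seed = 37)
  twin <- emg_session(cbind(base$emg[, 1], base$emg[, 1]), base$sample_rate,
                      base$stimulus, base$direction, base$metadata)
  res <- ied_analysis(twin, 300)
  for (dir in unique(res$direction)) {
    vals <- res$information_bits[res$direction == dir]
    expect_equal(vals[1], vals[2])
  }

  # a pure-noise channel carries far less information than a driven one
  p <- synth_params(channel_gains = c(1, 0), seed = 37)
  s2 <- generate_dynamic_session(p, dynamic_protocol())
  res2 <- ied_analysis(s2, 300, stim_bin_deg = 10,
                       response_rule = "fixed", response_bins = 5)
  pooled <- res2[res2$direction == "pooled", ]
  expect_lt(pooled$information_bits[2], 0.4)
  expect_lt(pooled$information_bits[2], 0.3 * pooled$information_bits[1])

  expect_error(ied_analysis(base, 300), "at least 2 channels")
})

test_that("higher-gain channels extract at least as much information (most seeds)", {
  wins <- 0L
  for (seed in 1:7) {
    p <- synth_params(channel_gains = c(0.5, 2), seed = seed)
    s <- generate_dynamic_session(p, dynamic_protocol())
    r <- ied_analysis(s, 300)
    pooled <- r[r$direction == "pooled", ]
    wins <- wins + (pooled$information_bits[2] >= pooled$information_bits[1])
  }
  expect_gte(wins, 4L)
})
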
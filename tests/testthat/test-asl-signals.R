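test_that("surround subtraction recovers a pure zig-zag and kills drift", {
  s <- asl_timeseries(c(10, 8, 10, 8, 10), alt_parity(5, "control"), 1)
  expect_equal(drop(surround_subtract(s)$values), rep(2, 5))

  # affine-in-time series: interior perfusion signal is exactly zero
  lin <- 5 + 0.3 * (0:9)
  sl <- asl_timeseries(lin, alt_parity(10, "label"), 1)
  p <- drop(surround_subtract(sl)$values)
  expect_equal(p[2:9], rep(0, 8))

  expect_error(surround_subtract(asl_timeseries(c(1, 2), c("label", "control"), 1)),
               "3 volumes")
})

test_that("surround operators match an elementwise brute-force oracle", {
  set.seed(21)
  n <- 41
  vals <- matrix(rnorm(2 * n, 100, 5), 2, n)
  s <- asl_timeseries(vals, alt_parity(n, "label"), 2)
  p <- surround_subtract(s)$values
  b <- surround_average(s)$values
  sg <- ifelse(s$parity == "control", 1, -1)
  for (d in 1:2) {
    for (i in seq_len(n)) {
      pe <- if (i == 1) vals[d, 1] - vals[d, 2]
      else if (i == n) vals[d, n] - vals[d, n - 1]
      else vals[d, i] - (vals[d, i - 1] + vals[d, i + 1]) / 2
      be <- if (i == 1) (vals[d, 1] + vals[d, 2]) / 2
      else if (i == n) (vals[d, n] + vals[d, n - 1]) / 2
      else vals[d, i] / 2 + (vals[d, i - 1] + vals[d, i + 1]) / 4
      expect_equal(p[d, i], sg[i] * pe)
      expect_equal(b[d, i], be)
    }
  }
})

test_that("surround averaging preserves constants and the zig-zag midpoint", {
  s <- asl_timeseries(c(10, 8, 10, 8, 10), alt_parity(5, "control"), 1)
  expect_equal(drop(surround_average(s)$values)[2:4], rep(9, 3))
  cs <- asl_timeseries(rep(7, 6), alt_parity(6), 1)
  expect_equal(drop(surround_average(cs)$values), rep(7, 6))
})

test_that("separation is linear and complementary at interior volumes", {
  set.seed(8)
  n <- 20
  vals <- matrix(rnorm(n, 50, 4), 1, n)
  s <- asl_timeseries(vals, alt_parity(n), 1)
  sa <- asl_timeseries(3 * vals, alt_parity(n), 1)
  expect_equal(surround_subtract(sa)$values, 3 * surround_subtract(s)$values)
  # b_i + sigma_i p_i / 2 reconstructs s_i
  p <- drop(surround_subtract(s)$values)
  b <- drop(surround_average(s)$values)
  sg <- ifelse(s$parity == "control", 1, -1)
  expect_equal((b + sg * p / 2)[2:(n - 1)], drop(vals)[2:(n - 1)])
})

test_that("noiseless generation round-trips through the separators", {
  d <- long_block_design()
  tru <- laminar_truth(baseline_signal = c(100, 120),
                       baseline_perfusion = c(2, 1.5),
                       bold_amplitude = c(0.03, 0.05),
                       perfusion_amplitude = c(0.5, 0.3),
                       drift_slope = 2e-4)
  s <- generate_laminar_asl(d, tru)
  p <- surround_subtract(s)$values
  b <- surround_average(s)$values
  h <- hrf_envelope(d)
  n <- ncol(p)
  interior <- intersect(c(envelope_interior(d, 0), envelope_interior(d, 1)),
                        2:(n - 1))
  for (dep in 1:2) {
    P <- tru$baseline_perfusion[dep] * (1 + tru$perfusion_amplitude[dep] * h)
    B <- tru$baseline_signal[dep] * (1 + tru$bold_amplitude[dep] * h)
    # perfusion recovered exactly where the envelope is locally constant
    expect_equal(p[dep, interior], P[interior], tolerance = 1e-10)
    # BOLD series equals envelope minus half the modulation there (drift is
    # linear, so it survives averaging but cancels in the second difference;
    # subtract it before comparing)
    drift <- tru$baseline_signal[dep] * tru$drift_slope * (seq_len(n) - 1)
    expect_equal(b[dep, interior] - drift[interior],
                 (B - P / 2)[interior], tolerance = 1e-10)
  }
  # everywhere: BOLD contamination of the perfusion series is bounded by the
  # largest second difference of the composite envelope
  for (dep in 1:2) {
    P <- tru$baseline_perfusion[dep] * (1 + tru$perfusion_amplitude[dep] * h)
    env <- tru$baseline_signal[dep] * (1 + tru$bold_amplitude[dep] * h) - P / 2
    eps <- max(abs(diff(diff(env))))
    expect_true(all(abs(p[dep, 2:(n - 1)] - P[2:(n - 1)]) <= eps + 1e-12))
  }
})

test_that("baseline perfusion uses complete rest pairs only", {
  d <- make_block_design(10, 1, 10, 10, 1, 31)
  tru <- flat_truth(n_depths = 2, baseline = 100, perfusion = 2,
                    perfusion_amplitude = 0.5)
  s <- generate_laminar_asl(d, tru)
  # rest-period pairs: activation excluded, recovers the truth, not the
  # elevated value
  expect_equal(baseline_perfusion(s, 1:10), rep(2, 2))
  # constant series: any selection gives the plain difference
  s0 <- generate_laminar_asl(d, flat_truth(n_depths = 1, perfusion = 2))
  expect_equal(baseline_perfusion(s0, c(4, 11, 12)), 2) # lone volume ignored
  expect_error(baseline_perfusion(s0, c(2, 5, 9)), "pair")
  # directional pairings agree on constant data
  expect_equal(baseline_perfusion(s0, 1:10, "control_with_preceding"), 2)
  expect_equal(baseline_perfusion(s0, 1:10, "control_with_following"), 2)
})

test_that("perfusion tSNR is mean over sd and rejects constants", {
  p <- structure(list(values = matrix(c(90, 100, 110), 1), tr = 1),
                 class = "perfusion_series")
  expect_equal(perfusion_tsnr(p), 10)
  pc <- structure(list(values = matrix(rep(2, 5), 1), tr = 1),
                  class = "perfusion_series")
  expect_error(perfusion_tsnr(pc), "variance")
})

test_that("tSNR matches the noise propagation of the three-point subtraction", {
  # white noise of sd sigma passes through the interior surround subtraction
  # with variance 1.5 sigma^2; with constant P = 2 the expected tSNR is
  # 2 / (sigma sqrt(1.5))
  d <- make_block_design(10, 0, 10, 10, 1, 4000)
  sigma <- 0.3
  tru <- flat_truth(n_depths = 1, baseline = 100, perfusion = 2,
                    noise_sd = sigma)
  s <- generate_laminar_asl(d, tru, seed = 4)
  expect_equal(perfusion_tsnr(surround_subtract(s)),
               2 / (sigma * sqrt(1.5)), tolerance = 0.05)
})
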
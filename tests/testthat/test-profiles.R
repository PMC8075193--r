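series_1d <- function(v, tr = 1) list(values = matrix(v, nrow = 1), tr = tr)

test_that("event-related averaging aligns and averages trials", {
  # three identical noiseless trials of shape [0,1,2,1,0]
  d <- make_block_design(2, 3, 1, 4, 1, 18)
  v <- rep(0, 18)
  for (i0 in c(3, 8, 13)) v[i0 + 0:4] <- c(0, 1, 2, 1, 0)
  era <- event_related_average(series_1d(v), d, c(0, 5))
  expect_equal(drop(era$mean), c(0, 1, 2, 1, 0))
  expect_equal(drop(era$sem), rep(0, 5))
  expect_equal(era$n_trials, 3)

  # two trials [0,2] and [2,0] -> mean [1,1], SEM 1 everywhere
  d2 <- make_block_design(1, 2, 1, 1, 1, 6)
  v2 <- c(9, 0, 2, 2, 0, 9)
  era2 <- event_related_average(series_1d(v2), d2, c(0, 2))
  expect_equal(drop(era2$mean), c(1, 1))
  expect_equal(drop(era2$sem), c(1, 1))

  # a window extending past the series end leaves no complete trial
  d3 <- make_block_design(2, 1, 1, 4, 1, 8)
  expect_error(event_related_average(series_1d(rep(0, 8)), d3, c(0, 10)),
               "complete window")
})

test_that("percent BOLD change rescales to the pre-stimulus baseline", {
  era <- structure(list(time = seq(-5, 10), n_trials = 2, tr = 1,
                        mean = matrix(c(rep(100, 5), rep(103, 11)), 1),
                        sem = matrix(0, 1, 16)), class = "event_average")
  pct <- percent_bold_change(era, 5)
  expect_equal(drop(pct$mean), c(rep(0, 5), rep(3, 11)))
  # constant series -> identically zero percent
  erac <- era
  erac$mean[] <- 42
  expect_true(all(percent_bold_change(erac, 5)$mean == 0))
})

test_that("absolute and relative perfusion changes follow their definitions", {
  era <- structure(list(time = seq(-5, 10), n_trials = 2, tr = 1,
                        mean = matrix(c(rep(2, 5), rep(2.6, 11)), 1),
                        sem = matrix(0, 1, 16)), class = "event_average")
  ab <- absolute_perfusion_change(era, 5, mean_epi = 100)
  expect_equal(drop(ab$mean)[6:16], rep(0.006, 11))
  rel <- relative_perfusion_change(era, 5)
  expect_equal(drop(rel$mean)[6:16], rep(30, 11))

  # homogeneity: scaling the raw series (and mean EPI) leaves abs unchanged;
  # relative is a ratio so it never sees the scale
  era_c <- era
  era_c$mean <- era$mean * 7
  ab_c <- absolute_perfusion_change(era_c, 5, mean_epi = 700)
  expect_equal(ab_c$mean, ab$mean)
  expect_equal(relative_perfusion_change(era_c, 5)$mean, rel$mean)
  expect_error(absolute_perfusion_change(era, 5, mean_epi = 0), "positive")
})

test_that("steady-state interval picks the expected onset-locked samples", {
  # onset at 28.5 s falls exactly on a volume; the half-open [14, 28) interval
  # then contains the five samples 14.25, 17.1, 19.95, 22.8, 25.65 s
  d <- make_block_design(28.5, 1, 20, 40, 2.85, 40)
  v <- rep(5, 40)
  era <- event_related_average(series_1d(v, 2.85), d, c(-8.55, 34.2))
  inside <- era$time >= 14 & era$time < 28
  expect_equal(sum(inside), 5)
  expect_equal(era$time[inside], c(14.25, 17.1, 19.95, 22.8, 25.65))
  prof <- steady_state_profile(era, 0.5, c(14, 28))
  expect_equal(prof$value, 5)
  expect_error(steady_state_profile(era, 0.5, c(200, 300)), "interval")
})

test_that("profile line fit matches closed forms and an independent oracle", {
  dep <- seq(0, 1, length.out = 11)
  f1 <- profile_linefit(laminar_profile(dep, dep))
  expect_equal(f1$slope, 1)
  expect_equal(f1$r_squared, 1)
  f0 <- profile_linefit(laminar_profile(dep, rep(4, 11)))
  expect_equal(f0$slope, 0)
  expect_equal(f0$r_squared, 0)
  expect_error(profile_linefit(laminar_profile(c(0, 1), c(1, 2))), "3 depths")

  set.seed(17)
  y <- rnorm(11)
  ft <- profile_linefit(laminar_profile(dep, y))
  # normal-equations oracle
  sl <- sum((dep - mean(dep)) * (y - mean(y))) / sum((dep - mean(dep))^2)
  ic <- mean(y) - sl * mean(dep)
  res <- y - ic - sl * dep
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(ft$slope, sl, tolerance = 1e-12)
  expect_equal(ft$r_squared, r2, tolerance = 1e-12)
})

test_that("pearson_r matches the textbook formula and degenerate rules", {
  dep <- seq(0, 1, length.out = 9)
  set.seed(23)
  a <- laminar_profile(dep, rnorm(9))
  expect_equal(pearson_r(a, laminar_profile(dep, 2 * a$value + 3)), 1)
  expect_equal(pearson_r(a, laminar_profile(dep, -a$value)), -1)
  b <- laminar_profile(dep, rnorm(9))
  num <- sum((a$value - mean(a$value)) * (b$value - mean(b$value)))
  den <- sqrt(sum((a$value - mean(a$value))^2) * sum((b$value - mean(b$value))^2))
  expect_equal(pearson_r(a, b), num / den, tolerance = 1e-12)
  expect_error(pearson_r(a, laminar_profile(dep, rep(1, 9))), "variance")
})

test_that("noiseless laminar generation round-trips to exact profiles", {
  # BOLD amplitude rising and perfusion amplitude falling across depths: the
  # recovered BOLD profile slope is positive, the relative-perfusion slope is
  # negative, and both match the generative expectation to 1e-6
  d <- long_block_design(n_blocks = 1)
  K <- 6
  ba <- seq(0.01, 0.05, length.out = K)
  pa <- seq(0.6, 0.3, length.out = K)
  bs <- rep(100, K)
  bp <- rep(2, K)
  tru <- laminar_truth(bs, bp, ba, pa)
  s <- generate_laminar_asl(d, tru)
  perf <- surround_subtract(s)
  bold <- surround_average(s)
  w <- c(-10, 60)
  ss <- c(35, 55) # fully developed plateau of the 60 s block
  dn <- seq(0, 1, length.out = K)
  pb <- steady_state_profile(
    percent_bold_change(event_related_average(bold, d, w), 10), dn, ss)
  pr <- steady_state_profile(
    relative_perfusion_change(event_related_average(perf, d, w), 10), dn, ss)
  expect_equal(pr$value, 100 * pa, tolerance = 1e-6)
  # BOLD series is B - P/2, so the percent change carries a small
  # perfusion-envelope correction
  expected_pct <- 100 * (bs * ba - bp * pa / 2) / (bs - bp / 2)
  expect_equal(pb$value, expected_pct, tolerance = 1e-6)
  expect_gt(profile_linefit(pb)$slope, 0)
  expect_lt(profile_linefit(pr)$slope, 0)
})

test_that("relative perfusion estimates are unbiased across replicates", {
  d <- long_block_design(n_blocks = 1, tr = 2)
  K <- 3
  pa <- c(0.5, 0.4, 0.3)
  tru <- laminar_truth(rep(100, K), rep(2, K), 0, pa, noise_sd = 0.1)
  dn <- seq(0, 1, length.out = K)
  nrep <- 50
  vals <- matrix(NA_real_, nrep, K)
  for (r in seq_len(nrep)) {
    s <- generate_laminar_asl(d, tru, seed = 1000 + r)
    era <- event_related_average(surround_subtract(s), d, c(-10, 60))
    vals[r, ] <- steady_state_profile(
      relative_perfusion_change(era, 10), dn, c(35, 55))$value
  }
  bias <- colMeans(vals) - 100 * pa
  sem <- apply(vals, 2, sd) / sqrt(nrep)
  expect_true(all(abs(bias) < 2 * sem))
})

test_that("group profiles average replicates with SEM", {
  dep <- c(0, 0.5, 1)
  g <- group_profile(list(laminar_profile(dep, c(1, 2, 3)),
                          laminar_profile(dep, c(3, 4, 5))))
  expect_equal(g$value, c(2, 3, 4))
  expect_equal(g$dispersion, rep(sd(c(1, 3)) / sqrt(2), 3))
})
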
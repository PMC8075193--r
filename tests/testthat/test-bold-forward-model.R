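test_that("CBF rescaling pins the depth mean to the central volume principle", {
  p <- physiology_params()
  # mean arbitrary baseline of 1 -> x = 1 and 60 mL/min/100 g
  r1 <- rescale_cbf(rep(1, 5), p)
  expect_equal(r1$x, 1)
  expect_equal(mean(r1$cbf0) * 60, 60)
  # inverse proportionality
  expect_equal(rescale_cbf(rep(0.5, 5), p)$x, 2)
  # algebraic identity on arbitrary input
  set.seed(2)
  arb <- runif(23, 0.5, 2)
  r <- rescale_cbf(arb, p)
  expect_equal(mean(r$cbf0), p$omega_v * p$cbv0_total / p$t_v0, tolerance = 1e-12)
  expect_error(rescale_cbf(c(1, -1), p), "positive")
})

test_that("baseline distributions split and ramp the stated volumes", {
  p <- physiology_params()
  b0 <- baseline_distributions(physiology_params(s_d = 1e-9), 2)
  expect_equal(b0$V0_vein, c(0.5, 0.5), tolerance = 1e-8)
  b <- baseline_distributions(p, 2)
  expect_equal(b$V0_vein, c(1 / 2.4, 1.4 / 2.4))
  # conservation across depths and compartments
  b23 <- baseline_distributions(p, 23)
  expect_equal(sum(b23$V0_venule) + sum(b23$V0_vein), p$cbv0_total)
  # cumulative vein flow
  expect_equal(b23$F0_vein, cumsum(b23$F0_venule))
  expect_error(baseline_distributions(p, 1), "K")
})

test_that("flow-metabolism coupling and the venule steady state check out", {
  expect_equal(cmro2_coupling(1, 3), 1)
  expect_equal(cmro2_coupling(2, 3), 4 / 3)
  expect_equal(cmro2_coupling(2, 1e9), 1, tolerance = 1e-8)
  p <- physiology_params()
  v1 <- venule_steady_state(1, p)
  expect_equal(v1$v, 1)
  expect_equal(v1$q, 1)
  v2 <- venule_steady_state(2, p)
  expect_equal(v2$v, 2^0.35, tolerance = 1e-12)
  expect_equal(v2$q, (4 / 3) * 2^0.35 / 2, tolerance = 1e-12)
  # dHb dilution whenever flow outruns metabolism
  fgrid <- seq(1.01, 3, by = 0.15)
  expect_true(all(venule_steady_state(fgrid, p)$q < 1))
})

test_that("vein drainage mixes fluxes with conservation", {
  p <- physiology_params()
  bl <- baseline_distributions(p, 3)
  null <- vein_drainage(rep(1, 3), bl, p)
  expect_equal(null$f_vein, rep(1, 3))
  expect_equal(null$v_vein, rep(1, 3))
  expect_equal(null$q_vein, rep(1, 3))

  # K = 2, uniform venule flows, f = (2, 1): hand-evaluated recursion
  bl2 <- baseline_distributions(p, 2)
  dr <- vein_drainage(c(2, 1), bl2, p)
  expect_equal(dr$f_vein, c(2, 1.5))
  conc1 <- (4 / 3) / 2                         # venule concentration, depth 1
  conc2 <- (1 * 0.5 * 1 + 2 * 0.5 * conc1) / (1.5 * 1)
  expect_equal(dr$q_vein[2], conc2 * 1.5^p$alpha_d, tolerance = 1e-12)

  # flux conservation at the surface: telescoping sum
  set.seed(6)
  f <- runif(7, 0.8, 2)
  bl7 <- baseline_distributions(p, 7)
  dr7 <- vein_drainage(f, bl7, p)
  expect_equal(dr7$f_vein[7] * bl7$F0_vein[7], sum(f * bl7$F0_venule),
               tolerance = 1e-12)
})

test_that("drainage recursion agrees with a brute-force steady-state solver", {
  skip_if_not_installed("pracma")
  p <- physiology_params()
  for (f in list(c(1.5, 1.2), c(2, 1, 1.4), c(1.1, 1.8, 1.3))) {
    K <- length(f)
    bl <- baseline_distributions(p, K)
    ven <- venule_steady_state(f, p)
    dr <- vein_drainage(f, bl, p)
    f_vein <- cumsum(f * bl$F0_venule) / bl$F0_vein
    v_vein <- f_vein^p$alpha_d
    # unknowns: q_venule (K) then q_vein (K); residuals are the dHb mass
    # balances of every compartment
    residual <- function(q) {
      qv <- q[1:K]
      qd <- q[(K + 1):(2 * K)]
      m <- cmro2_coupling(f, p$n)
      res_v <- f * qv / ven$v - m
      res_d <- numeric(K)
      inflow_prev <- c(0, (f_vein * bl$F0_vein * (qd / v_vein))[-K])
      res_d <- f_vein * bl$F0_vein * qd / v_vein -
        (f * bl$F0_venule * qv / ven$v + inflow_prev)
      c(res_v, res_d)
    }
    sol <- pracma::fsolve(residual, rep(1, 2 * K), tol = 1e-12)$x
    expect_equal(sol[1:K], ven$q, tolerance = 1e-8)
    expect_equal(sol[(K + 1):(2 * K)], dr$q_vein, tolerance = 1e-8)
  }
})

test_that("BOLD signal equation obeys null, sign and toy-value checks", {
  p <- physiology_params()
  K <- 4
  bl <- baseline_distributions(p, K)
  base_state <- list(
    venule = list(v = rep(1, K), q = rep(1, K), V0 = bl$V0_venule),
    vein = list(v = rep(1, K), q = rep(1, K), V0 = bl$V0_vein))
  expect_equal(bold_signal(base_state, p), rep(0, K))

  # dHb washout with fixed volume raises the signal
  washed <- base_state
  washed$venule$q <- rep(0.9, K)
  expect_true(all(bold_signal(washed, p) > 0))

  # single-compartment toy: hand-computed plug-in at q = 0.85, v = 1.27
  toy <- list(venule = list(v = 1.27, q = 0.85, V0 = 1, F0 = 1),
              vein = list(v = 1, q = 1, V0 = 0, F0 = 1))
  # K = 1 here: w = V0 / tissue_volume * K = 0.01
  cc <- p$signal_constants$venule
  k1 <- cc$c1 * p$e0 * p$te
  k2 <- cc$c2 * p$e0 * p$te
  k3 <- cc$c3
  hand <- 100 * 0.01 * ((k1 + k2) * (1 - 0.85) - (k2 + k3) * (1 - 1.27))
  expect_equal(bold_signal(toy, p), hand, tolerance = 1e-12)
  expect_error(bold_signal(list(venule = toy$venule), p), "both")
})

test_that("null activation gives a zero profile and scaling cancels", {
  K <- 23
  base <- runif(K, 0.8, 1.2)
  null <- simulate_bold_profile(laminar_perfusion_input(base, base))
  expect_equal(null$value, rep(0, K), tolerance = 1e-12)

  set.seed(9)
  act <- base * runif(K, 1.2, 1.6)
  p1 <- simulate_bold_profile(laminar_perfusion_input(base, act))
  p2 <- simulate_bold_profile(laminar_perfusion_input(5 * base, 5 * act))
  expect_equal(p1$value, p2$value, tolerance = 1e-12)
})

test_that("drainage biases the simulated BOLD profile toward the surface", {
  K <- 23
  # uniform relative flow: strictly increasing profile (vein accumulation
  # plus the rising vein baseline volume)
  uni <- simulate_bold_profile(laminar_perfusion_input(rep(1, K), rep(1.5, K)))
  expect_true(all(diff(uni$value) > 0))

  # the reconciliation: relative perfusion decreasing toward the surface
  # still yields a positive simulated BOLD slope
  f <- seq(1.6, 1.3, length.out = K)
  dec <- simulate_bold_profile(laminar_perfusion_input(rep(1, K), f))
  expect_gt(profile_linefit(dec)$slope, 0)
})
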
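p_ref <- example_params()

test_that("the equilibrium is a fixed point of the discrete scheme", {
  sim <- simulate_rd(p_ref, tau = 3, t_end = 50, M = 31,
                     init = c(N = 0.2, u = 0.2))
  expect_lt(max(abs(sim$N - 0.2)), 1e-8)
  expect_lt(max(abs(sim$u - 0.2)), 1e-8)
})

test_that("spatially constant data stays spatially constant", {
  sim <- simulate_rd(p_ref, tau = 4, t_end = 60, M = 21,
                     init = c(N = 0.5, u = 0.9))
  spread_N <- apply(sim$N, 2, function(col) diff(range(col)))
  spread_u <- apply(sim$u, 2, function(col) diff(range(col)))
  expect_lt(max(spread_N), 1e-10)
  expect_lt(max(spread_u), 1e-10)
})

test_that("the integrator matches an independent DDE solver on homogeneous data", {
  tau <- 3
  sim <- simulate_rd(p_ref, tau = tau, t_end = 100, M = 21,
                     init = c(N = 0.5, u = 0.9))
  ref <- dede_reference(p_ref, tau, c(N = 0.5, u = 0.9), sim$t)
  ip <- 11 # midpoint node
  expect_lt(max(abs(sim$N[ip, ] - ref[, 2])), 1e-4)
  expect_lt(max(abs(sim$u[ip, ] - ref[, 3])), 1e-4)
})

test_that("with frozen population the control relaxes exactly at rate a", {
  # r -> 0 freezes N, making the control equation a scalar linear ODE with
  # the exact solution u(t) = bN0/a + (u0 - bN0/a) exp(-a t)
  p <- rdlogistic:::validate_params(
    modifyList(unclass(p_ref), list(r = 1e-12)))
  N0 <- 0.3; u0 <- 0.9
  sim <- simulate_rd(p, tau = 1, t_end = 12, M = 21,
                     init = c(N = N0, u = u0))
  exact <- p$b * N0 / p$a + (u0 - p$b * N0 / p$a) * exp(-p$a * sim$t)
  expect_lt(max(abs(sim$u[11, ] - exact)), 1e-6)
})

test_that("nonnegativity and dissipative bounds hold for random histories", {
  bd <- dissipative_bounds(p_ref)
  withr::with_seed(606, {
    for (i in 1:50) {
      ampN <- runif(1, 0, 0.8)
      phase <- runif(1, 0, 2 * pi)
      hist_fn <- local({
        aN <- ampN; ph <- phase
        function(x, s) list(N = aN * (1 + sin(x / 2 + ph) * cos(s)) / 2 + 0.01,
                            u = rep(runif(1, 0, 0.8), length(x)))
      })
      sim <- simulate_rd(p_ref, tau = 1.5, t_end = 30, M = 21,
                         history = hist_fn)
      expect_gt(min(sim$N), -1e-12)
      expect_gt(min(sim$u), -1e-12)
    }
  })
  # long run: late-time fields respect the ultimate bounds
  sim <- simulate_rd(p_ref, tau = 50, t_end = 2000, M = 41)
  late <- sim$t > 0.8 * sim$grid$t_end
  expect_lt(max(sim$N[, late]), bd["N"] + 1e-2)
  expect_lt(max(sim$u[, late]), bd["u"] + 1e-2)
  expect_gt(min(sim$N), -1e-12)
})

test_that("history validation rejects negative data", {
  expect_error(simulate_rd(p_ref, 1, t_end = 5, M = 11,
                           init = c(N = -0.1, u = 0.5)),
               "nonnegative", class = "rdlf_sim_error")
  expect_error(simulate_rd(p_ref, 1, t_end = 5, M = 11,
                           history = function(x, s) list(N = 0 * x - 1, u = 0 * x + 1)),
               "nonnegative", class = "rdlf_sim_error")
})

test_that("the time step divides the delay exactly and respects stability", {
  sim <- simulate_rd(p_ref, tau = 2, t_end = 10, M = 41)
  g <- sim$grid
  expect_equal(g$k_delay * g$dt, 2)
  expect_lte(g$dt, g$h^2 / (2 * max(p_ref$d1, p_ref$d2)))
})

test_that("series classification distinguishes steady, periodic and relaxation shapes", {
  t <- seq(0, 300, by = 0.05)
  expect_identical(series_summary(t, rep(0.2, length(t)))$classification,
                   "steady")
  s <- series_summary(t, 0.2 + 0.05 * sin(2 * pi * t / 18.04))
  expect_identical(s$classification, "periodic")
  expect_rel_equal(s$period, 18.04, 0.01)
  # flat-topped square-ish wave (the large-delay regime shape)
  sq <- series_summary(t, 0.25 + 0.25 * tanh(5 * sin(2 * pi * t / 60)))
  expect_identical(sq$classification, "periodic")
  expect_rel_equal(sq$period, 60, 0.01)
  # short window: too few cycles
  expect_identical(series_summary(seq(0, 20, 0.1),
                                  0.2 + 0.1 * sin(2 * pi * seq(0, 20, 0.1) / 18))$classification,
                   "undetermined")
})

test_that("grid refinement leaves steady state and period essentially unchanged", {
  # steady case
  s_coarse <- simulate_rd(p_ref, 2, t_end = 300, M = 51)
  s_fine <- simulate_rd(p_ref, 2, t_end = 300, M = 101)
  err_c <- max(abs(s_coarse$N[, ncol(s_coarse$N)] - 0.2))
  err_f <- max(abs(s_fine$N[, ncol(s_fine$N)] - 0.2))
  expect_lt(abs(err_c - err_f), 1e-5)
  # periodic case: measured period changes by < 1%
  per <- vapply(c(51, 101), function(M) {
    sim <- simulate_rd(p_ref, 10, t_end = 1200, M = M)
    oscillation_summary(sim, 0.5)$period
  }, numeric(1))
  expect_rel_equal(per[1], per[2], 0.01)
})

test_that("the oscillation onset sits at the exact-coupling critical delay", {
  tau0 <- classify_stability(p_ref, 0, coupling = "exact")$tau0
  expect_equal(tau0, 8.602256, tolerance = 1e-5)
  below <- simulate_rd(p_ref, 0.9 * tau0, t_end = 2500, M = 21)
  above <- simulate_rd(p_ref, 1.15 * tau0, t_end = 2500, M = 21)
  s_below <- oscillation_summary(below, 0.3)
  s_above <- oscillation_summary(above, 0.3)
  expect_identical(s_below$classification, "steady")
  expect_identical(s_above$classification, "periodic")
  expect_gt(s_above$amplitude, 0.05)
})

test_that("the emergent period near onset matches the exact-coupling Hopf frequency", {
  hp <- critical_delays(p_ref, 0, coupling = "exact")[1, ]
  sim <- simulate_rd(p_ref, hp$tau + 0.25, t_end = 3000, M = 21)
  s <- oscillation_summary(sim, 0.3)
  expect_identical(s$classification, "periodic")
  expect_rel_equal(s$period, 2 * pi / hp$omega, 0.05)
})

test_that("oscillation amplitude grows with the delay past onset (supercritical)", {
  taus <- c(8.9, 9.6, 10.3)
  amps <- vapply(taus, function(tau) {
    oscillation_summary(simulate_rd(p_ref, tau, t_end = 2000, M = 21),
                        0.3)$amplitude
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("delay-independent parameters converge for small and large delays", {
  p <- model_params(d1 = 1, d2 = 0.5, r = 0.6, K = 1, a1 = 5, a2 = 1,
                    c = 1, b = 1, a = 1, l = 2)
  eq <- equilibria(p)
  for (tau in c(1, 10, 50)) {
    sim <- simulate_rd(p, tau, t_end = 400, M = 21)
    expect_lt(max(abs(sim$N[, ncol(sim$N)] - eq$N[2])), 1e-3)
    expect_lt(max(abs(sim$u[, ncol(sim$u)] - eq$u[2])), 1e-3)
  }
})

test_that("delay sweeps are deterministic and tabulate one row per delay", {
  sw1 <- delay_sweep(p_ref, c(2, 10), t_end = 600, M = 21,
                     window_fraction = 0.4)
  sw2 <- delay_sweep(p_ref, c(2, 10), t_end = 600, M = 21,
                     window_fraction = 0.4)
  expect_identical(sw1, sw2)
  expect_equal(sw1$tau, c(2, 10))
  expect_identical(sw1$classification[1], "steady")
})
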
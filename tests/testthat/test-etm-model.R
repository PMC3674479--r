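test_that("event-driven recursion agrees with dense ODE integration on all regimes", {
  times <- periodic_train(30, 5)
  tab <- regime_presets()
  for (i in seq_len(nrow(tab))) {
    p <- preset_params(tab$name[i])
    fast <- simulate_psps(p, times)
    dense <- euler_psps(p, times, dt = 1e-5)
    expect_lt(max(abs(fast - dense) / dense), 1e-3,
              label = paste("regime", tab$name[i]))
  }
})

test_that("single-spike and long-interval limits are exact", {
  p <- stp_params(D = 0.3, F = 0.4, U = 0.35, f = 0.2, A = 2.5)
  expect_equal(simulate_psps(p, 0), 2.5 * 0.35)
  # full recovery after 1000 s
  amps <- simulate_psps(p, c(0, 1000))
  expect_equal(amps[2], amps[1], tolerance = 1e-12)
})

test_that("amplitude scales the output linearly and exactly", {
  times <- poisson_train(20, 12, seed = 5)
  p1 <- stp_params(D = 0.4, F = 0.1, U = 0.3, f = 0.1, A = 1)
  p3 <- stp_params(D = 0.4, F = 0.1, U = 0.3, f = 0.1, A = 3.7)
  expect_identical(simulate_psps(p3, times), 3.7 * simulate_psps(p1, times))
})

test_that("model variants collapse onto each other as defined", {
  times <- poisson_train(30, 20, seed = 9)
  p <- stp_params(D = 0.6, F = 0.3, U = 0.4, f = 0.4)
  # eTM with f = U equals the facilitation-tied variant
  expect_identical(simulate_psps(p, times, "etm"),
                   simulate_psps(p, times, "tm_fac"))
  # depression-only variant: u pinned at U for any F, f
  p_dep <- stp_params(D = 0.6, F = 1.3, U = 0.4, f = 0.8)
  p_f0 <- stp_params(D = 0.6, F = 1.3, U = 0.4, f = 0)
  expect_equal(simulate_psps(p_dep, times, "tm"),
               simulate_psps(p_f0, times, "etm"), tolerance = 1e-14)
})

test_that("state stays in bounds for random parameters and trains", {
  set.seed(42)
  for (rep in 1:25) {
    p <- stp_params(D = runif(1, 0.01, 2), F = runif(1, 0.01, 2),
                    U = runif(1), f = runif(1))
    times <- cumsum(rexp(30, rate = runif(1, 5, 80)))
    amps <- simulate_psps(p, times)
    expect_true(all(amps > 0))
    expect_true(all(amps <= 1))  # A = 1, R <= 1, u <= 1
  }
})

test_that("periodic-train amplitudes converge to the closed-form steady state", {
  p <- preset_params("depression")
  ss <- steady_state(p, 30)
  amps <- simulate_psps(p, periodic_train(30, 10000))
  expect_equal(amps[10000], ss[["R_inf"]] * ss[["u_inf"]],
               tolerance = 1e-6)
})

test_that("steady state matches fixed-point iteration and its limits", {
  p <- preset_params("depression")
  expect_equal(unname(steady_state(p, 30)),
               unname(iterate_steady_state(p, 30)), tolerance = 1e-6)
  set.seed(11)
  for (rep in 1:20) {
    pr <- stp_params(D = runif(1, 0.01, 2), F = runif(1, 0.01, 2),
                     U = runif(1, 0.01, 1), f = runif(1))
    rate <- runif(1, 1, 100)
    expect_equal(unname(steady_state(pr, rate)),
                 unname(iterate_steady_state(pr, rate)), tolerance = 1e-6)
  }
  # vanishing rate: full recovery between spikes
  ss0 <- steady_state(p, 1e-6)
  expect_equal(ss0[["R_inf"]], 1, tolerance = 1e-9)
  expect_equal(ss0[["u_inf"]], p$U, tolerance = 1e-9)
  # f = 0: u never leaves its baseline
  pf0 <- stp_params(D = 0.5, F = 0.7, U = 0.33, f = 0)
  for (rate in c(1, 30, 200))
    expect_equal(steady_state(pf0, rate)[["u_inf"]], 0.33)
})

test_that("EPR and PPR compute ratio statistics and validate input", {
  expect_equal(epr(c(5, 5, 5)), 1)
  expect_equal(epr(c(1, 0.5, 0.25)), 0.5)
  expect_equal(ppr(c(2, 1, 5)), 0.5)
  expect_error(epr(3), "at least two")
  expect_error(epr(c(1, 0, 2)), "zero")
  expect_error(ppr(1.5), "at least two")
  # a strongly depressing regime has PPR < 1
  amps <- simulate_psps(preset_params("strong_depression"),
                        periodic_train(30, 5))
  expect_lt(ppr(amps), 1)
})

test_that("invalid parameters and trains are rejected", {
  expect_error(stp_params(D = 0, F = 0.1, U = 0.5, f = 0.1), "positive")
  expect_error(stp_params(D = 0.1, F = 1e-12, U = 0.5, f = 0.1),
               "positive")
  expect_error(stp_params(D = 0.1, F = 0.1, U = 1.4, f = 0.1), "U")
  expect_error(stp_params(D = 0.1, F = 0.1, U = 0.5, f = -0.2), "f")
  expect_error(stp_params(D = 0.1, F = 0.1, U = 0.5, f = 0.1, A = 0),
               "amplitude")
  p <- stp_params(D = 0.1, F = 0.1, U = 0.5, f = 0.1)
  expect_error(simulate_psps(p, c(0.2, 0.1)), "increasing")
  expect_error(simulate_psps(p, numeric(0)), "nonempty")
  expect_error(steady_state(p, 0), "positive")
})
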
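test_that("on/off time constants invert to the generating rates", {
  # forward-computed from k_on = 73 uM^-1 s^-1, k_off = 0.0062 s^-1 at
  # 0.25 nM toxin: tau_on = 40.90 s, tau_off = 161.3 s
  rs <- rates_from_on_off(tau_on = 40.90, tau_off = 161.3,
                          toxin_conc = 2.5e-4)
  expect_equal(rs$k_on, 73, tolerance = 5e-3)
  expect_equal(rs$k_off, 0.0062, tolerance = 5e-3)
  expect_equal(rs$k_d, 0.085, tolerance = 1e-2)
})

test_that("the irreversible-block limit gives k_off ~ 0", {
  rs <- rates_from_on_off(40, 1e9, 2.5e-4)
  expect_equal(rs$k_off, 1e-9)
  expect_equal(rs$k_on, 1 / (40 * 2.5e-4), tolerance = 1e-6)
})

test_that("equal on and off time constants violate the precondition", {
  expect_error(rates_from_on_off(100, 100, 1e-3), "slower than off")
  expect_error(rates_from_on_off(120, 100, 1e-3), "slower than off")
  expect_error(rates_from_on_off(40, 161, 0), "> 0")
})

test_that("on/off round trip reproduces rates to 10+ digits", {
  set.seed(1)
  for (i in 1:25) {
    k_on <- 10^runif(1, 0, 3)
    k_off <- 10^runif(1, -3, 1)
    tx <- 10^runif(1, -4, -1)
    tau_off <- 1 / k_off
    tau_on <- 1 / (k_on * tx + k_off)
    rs <- rates_from_on_off(tau_on, tau_off, tx)
    expect_equal(rs$k_on, k_on, tolerance = 1e-10)
    expect_equal(rs$k_off, k_off, tolerance = 1e-10)
  }
})

test_that("relaxation (tau, asymptote) inversion matches hand values", {
  rs <- rates_from_relaxation(tau = 0.1412, asymptote = 0.4266,
                              toxin_conc = 0.005)
  expect_equal(rs$k_off, 3.02, tolerance = 2e-3)
  expect_equal(rs$k_on, 812, tolerance = 2e-3)
})

test_that("relaxation inversion round trip holds to 10+ digits", {
  set.seed(2)
  for (i in 1:25) {
    k_on <- 10^runif(1, 1, 4)
    k_off <- 10^runif(1, -1, 1)
    tx <- 10^runif(1, -3, -2)
    lam <- k_on * tx + k_off
    rs <- rates_from_relaxation(1 / lam, k_off / lam, tx)
    expect_equal(rs$k_on, k_on, tolerance = 1e-10)
    expect_equal(rs$k_off, k_off, tolerance = 1e-10)
  }
})

test_that("relaxation inversion scaling: doubling [Tx] halves k_on only", {
  a <- rates_from_relaxation(0.14, 0.43, 0.005)
  b <- rates_from_relaxation(0.14, 0.43, 0.010)
  expect_equal(b$k_on, a$k_on / 2)
  expect_equal(b$k_off, a$k_off)
})

test_that("asymptote bounds are reported by name", {
  expect_error(rates_from_relaxation(0.1, 1, 0.005), "< 1")
  expect_error(rates_from_relaxation(0.1, 0, 0.005), "> 0")
})

test_that("proportional traces give a constant ratio", {
  t <- seq(0, 50, by = 0.1)
  ctrl <- 5 * (1 - exp(-t / 2))^4
  pair <- trace_pair(t, ctrl, 0.5 * ctrl, step_voltage = 0)
  rr <- trace_ratio(pair)
  expect_true(all(abs(rr$ratio - 0.5) < 1e-12))
  expect_true(min(rr$time) > 0)  # guard masks the earliest samples
})

test_that("the ratio of a modeled pair equals the analytic relaxation", {
  # block relaxing 0.30 -> 0.43 with tau = 141 ms on a 2-ms activation
  t <- seq(0, 600, by = 0.5)
  u <- 0.43 - 0.13 * exp(-t / 141)
  ctrl <- (1 - exp(-t / 2))
  pair <- trace_pair(t, ctrl, ctrl * u, step_voltage = 0)
  rr <- trace_ratio(pair, 0.1)
  expect_equal(rr$ratio, 0.43 - 0.13 * exp(-rr$time / 141),
               tolerance = 1e-12)
})

test_that("degenerate control traces are rejected", {
  t <- seq(0, 10, by = 0.1)
  pair <- trace_pair(t, rep(0, length(t)), rep(0, length(t)),
                     step_voltage = 0)
  expect_error(trace_ratio(pair), "no analyzable window")
})

test_that("voltage-dependence fit is exact on noiseless model rates", {
  co <- phys_constants()
  vt <- thermal_voltage(co)
  # two points constructed from k0 = 3.02, zd = 0.47: exact two-point fit
  v2 <- c(0, 50)
  vd2 <- fit_voltage_dependence(v2, 3.02 * exp(0.47 * v2 / vt), co)
  expect_equal(vd2$k_at_zero, 3.02, tolerance = 1e-10)
  expect_equal(vd2$z_delta, 0.47, tolerance = 1e-10)
  # any >= 2 noiseless voltages recover the law exactly
  set.seed(3)
  for (i in 1:10) {
    k0 <- 10^runif(1, -1, 3)
    zd <- runif(1, -1, 1)
    v <- sort(sample(seq(-80, 80, 10), sample(2:6, 1)))
    vd <- fit_voltage_dependence(v, k0 * exp(zd * v / vt), co)
    expect_equal(vd$k_at_zero, k0, tolerance = 1e-9)
    expect_equal(vd$z_delta, zd, tolerance = 1e-9)
  }
})

test_that("identical rates at all voltages give zero valence", {
  vd <- fit_voltage_dependence(c(-40, 0, 40), rep(2.5, 3))
  expect_equal(vd$z_delta, 0, tolerance = 1e-12)
  expect_equal(vd$k_at_zero, 2.5, tolerance = 1e-12)
})

test_that("a rate growing e-fold per 50 mV has valence ~0.5", {
  co <- phys_constants()
  v <- seq(-50, 100, 25)
  vd <- fit_voltage_dependence(v, 3 * exp(v / 50), co)
  expect_equal(vd$z_delta, thermal_voltage(co) / 50, tolerance = 1e-9)
  expect_lt(abs(vd$z_delta - 0.5), 0.05)
})

test_that("fewer than two distinct voltages is an error", {
  expect_error(fit_voltage_dependence(c(0, 0), c(1, 2)), "distinct")
})

test_that("average-then-solve matches hand-computed means", {
  pts <- data.frame(voltage = c(0, 0), tau = c(0.14, 0.15),
                    asymptote = c(0.42, 0.44))
  out <- average_then_solve(pts, toxin_conc = 0.005)
  by_hand <- rates_from_relaxation(0.145, 0.43, 0.005)
  expect_equal(out$k_on, by_hand$k_on)
  expect_equal(out$k_off, by_hand$k_off)
  expect_equal(out$n_cells, 2)
})

test_that("identical replicates reduce to a single-point solve", {
  pts <- data.frame(voltage = rep(20, 5), tau = rep(0.1, 5),
                    asymptote = rep(0.4, 5))
  out <- average_then_solve(pts, 0.005)
  one <- rates_from_relaxation(0.1, 0.4, 0.005)
  expect_equal(out$k_on, one$k_on)
  expect_equal(out$k_off, one$k_off)
})

test_that("mixed toxin concentrations within a voltage group error", {
  pts <- data.frame(voltage = c(0, 0), tau = c(0.1, 0.1),
                    asymptote = c(0.4, 0.4),
                    toxin_conc = c(0.005, 0.010))
  expect_error(average_then_solve(pts), "mixed toxin concentrations")
})
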
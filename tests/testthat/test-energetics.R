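test_that("Eyring inversion reproduces the printed barrier range", {
  expect_equal(signif(barrier_from_rate(3.3), 2), 70)
  expect_equal(barrier_from_rate(0.0061), 85, tolerance = 1e-2)
  expect_equal(barrier_from_rate(6e12), 0)
  expect_error(barrier_from_rate(7e12), "negative barrier")
})

test_that("barrier and rate are mutual inverses to 12+ digits", {
  set.seed(6)
  for (i in 1:25) {
    k <- 10^runif(1, -4, 2)
    expect_equal(rate_from_barrier(barrier_from_rate(k)), k,
                 tolerance = 1e-12)
    g <- runif(1, 0, 90)
    expect_equal(barrier_from_rate(rate_from_barrier(g)), g,
                 tolerance = 1e-12)
  }
})

test_that("equal partitioning over 10 contacts gives ~3 kT each", {
  lo <- per_contact_energy(70, 10)
  hi <- per_contact_energy(85, 10)
  expect_equal(lo$energy_kT, 2.8, tolerance = 1e-2)
  expect_equal(hi$energy_kT, 3.4, tolerance = 1e-2)
  # each contact unbound roughly 3-6% of the time
  expect_equal(lo$p_unbound, 0.06, tolerance = 2e-2)
  expect_equal(hi$p_unbound, 0.03, tolerance = 8e-2)
  # n = 1 composes with the Eyring inversion to k_off / A0
  k <- 0.37
  pc1 <- per_contact_energy(barrier_from_rate(k), 1)
  expect_equal(pc1$p_unbound, k / 6e12, tolerance = 1e-12)
})

test_that("contact equilibria reconcile k_eq with local rates", {
  cc <- contact_equilibrium(local_off = 1e3, local_on = 2e4,
                            valence = 0.47)
  expect_equal(cc$k_eq, 0.05)
  expect_error(contact_equilibrium(k_eq = 0.1, local_off = 1e3,
                                   local_on = 2e4),
               "inconsistent")
  expect_error(contact_equilibrium(), "supply")
})

test_that("contact K_j scales with voltage as exp(z F V / RT)", {
  co <- phys_constants()
  cc <- contact_equilibrium(k_eq = 0.05, valence = 0.4)
  expect_equal(contact_kj_voltage(cc, 0, co), 0.05)
  expect_equal(contact_kj_voltage(cc, 50, co) / 0.05, 2.18,
               tolerance = 2e-3)
  cz <- contact_equilibrium(k_eq = 0.05, valence = 0)
  expect_equal(contact_kj_voltage(cz, c(-100, 0, 100), co), rep(0.05, 3))
})

test_that("composite k_off multiplies contact equilibria and voltage", {
  co <- phys_constants()
  ones <- replicate(5, contact_equilibrium(k_eq = 1), simplify = FALSE)
  expect_equal(composite_koff(contact_network(ones, 1e4), co), 1e4)
  ten <- replicate(10, contact_equilibrium(k_eq = exp(-2.824)),
                   simplify = FALSE)
  expect_equal(composite_koff(contact_network(ten, 6e12), co), 3.3,
               tolerance = 2e-2)
  one_v <- contact_network(
    list(contact_equilibrium(k_eq = 0.05, valence = 0.47)),
    escape_frequency = 1e4, voltage = 50
  )
  one_0 <- contact_network(
    list(contact_equilibrium(k_eq = 0.05, valence = 0.47)),
    escape_frequency = 1e4, voltage = 0
  )
  expect_equal(composite_koff(one_v, co) / composite_koff(one_0, co),
               2.50, tolerance = 2e-3)
})

test_that("barrier additivity equals the product of contact constants", {
  co <- phys_constants()
  set.seed(7)
  for (i in 1:10) {
    e_kt <- runif(sample(2:8, 1), 0.5, 4)
    ks <- exp(-e_kt)
    net <- contact_network(
      lapply(ks, function(k) contact_equilibrium(k_eq = k)), 1e4
    )
    total_kj <- sum(e_kt) * rt_kj(co)
    expect_equal(composite_koff(net, co),
                 1e4 * exp(-total_kj / rt_kj(co)), tolerance = 1e-12)
  }
})

test_that("simulated lifetimes match the dense first-passage oracle", {
  net <- contact_network(
    replicate(3, contact_equilibrium(local_off = 2e3, local_on = 1e4),
              simplify = FALSE),
    escape_frequency = 1e4
  )
  sim <- simulate_contact_network(net, 400, seed = 11,
                                  min_separation = 10)
  exact <- mfpt_contact_oracle(rep(2e3, 3), rep(1e4, 3), 1e4)
  expect_lt(abs(sim$mean_lifetime - exact), 3 * sim$se_mean_lifetime)
})

test_that("a single contact gives exponential lifetimes at the
           quasi-equilibrium rate", {
  net <- contact_network(
    contact_equilibrium(local_off = 1e4, local_on = 1e5),
    escape_frequency = 1e3
  )
  sim <- simulate_contact_network(net, 500, seed = 3,
                                  min_separation = 10)
  rate <- 1e3 * 0.1 / 1.1  # escape * K/(1+K)
  ks <- suppressWarnings(stats::ks.test(sim$lifetimes, "pexp", rate))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sim$exposure_fraction, 0.1 / 1.1, tolerance = 0.05)
})

test_that("per-contact exposure matches ergodic two-state occupancy", {
  net <- contact_network(
    list(contact_equilibrium(local_off = 2e3, local_on = 1e4),
         contact_equilibrium(local_off = 1e3, local_on = 1e4)),
    escape_frequency = 1e3
  )
  sim <- simulate_contact_network(net, 300, seed = 9,
                                  min_separation = 10)
  expect_equal(sim$exposure_fraction[1], 0.2 / 1.2, tolerance = 0.05)
  expect_equal(sim$exposure_fraction[2], 0.1 / 1.1, tolerance = 0.05)
})

test_that("simulation is reproducible under a fixed seed", {
  net <- contact_network(
    contact_equilibrium(local_off = 1e4, local_on = 1e5),
    escape_frequency = 1e3
  )
  s1 <- simulate_contact_network(net, 100, seed = 21,
                                 min_separation = 10)
  s2 <- simulate_contact_network(net, 100, seed = 21,
                                 min_separation = 10)
  expect_identical(s1$lifetimes, s2$lifetimes)
  expect_error(simulate_contact_network(net, 100), "mandatory")
})

test_that("the timescale-separation precondition is enforced", {
  slow <- contact_network(
    contact_equilibrium(local_off = 10, local_on = 100),
    escape_frequency = 1e3
  )
  expect_error(simulate_contact_network(slow, 100, seed = 1),
               "timescale separation")
})

test_that("voltage on the rebinding rate speeds simulated unbinding", {
  co <- phys_constants()
  mk <- function(v) contact_network(
    list(contact_equilibrium(local_off = 1e4, local_on = 1e5,
                             valence = 0.47)),
    escape_frequency = 1e3, voltage = v
  )
  s0 <- simulate_contact_network(mk(0), 300, seed = 2,
                                 min_separation = 1)
  s50 <- simulate_contact_network(mk(50), 300, seed = 2,
                                  min_separation = 1)
  k_ratio <- s50$composite_koff / s0$composite_koff
  expect_equal(k_ratio, exp(0.47 * 50 / thermal_voltage(co)),
               tolerance = 1e-9)
  expect_lt(s50$mean_lifetime, s0$mean_lifetime)
})
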
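ref <- ctx_reference_params()

test_that("noiseless wash-in reaches the closed-form equilibrium", {
  # k_on = 73, k_off = 0.0062, [Tx] = 0.25 nM: unblocked fraction at
  # equilibrium is k_off/(k_on [Tx] + k_off) = 0.254, onset tau = 40.9 s
  sched <- data.frame(start = 0, end = 900, tx_conc = 2.5e-4)
  tc <- gen_block_timecourse(73, 0.0062, sched, t_end = 900)
  expect_equal(min(tc$amplitudes), 0.0062 / (73 * 2.5e-4 + 0.0062),
               tolerance = 1e-3)
  fit <- fit_monoexponential(tc$times, tc$amplitudes)
  expect_equal(fit$tau, 40.9, tolerance = 1e-3)
})

test_that("on/off phases of a generated time course are exactly
           mono-exponential and round-trip through the rate solver", {
  sched <- data.frame(start = 30, end = 330, tx_conc = 2.5e-4)
  tc <- gen_block_timecourse(73, 0.0062, sched, t_end = 1200)
  on_fit <- fit_monoexponential(tc$times, tc$amplitudes,
                                window = c(30, 330))
  off_fit <- fit_monoexponential(tc$times, tc$amplitudes,
                                 window = c(330, 1200))
  expect_lt(on_fit$rss, 1e-12)
  expect_lt(off_fit$rss, 1e-12)
  rs <- rates_from_on_off(on_fit$tau, off_fit$tau, 2.5e-4)
  expect_equal(rs$k_on, 73, tolerance = 1e-4)
  expect_equal(rs$k_off, 0.0062, tolerance = 1e-4)
})

test_that("zero toxin gives a flat unity trace (plus noise only)", {
  sched <- data.frame(start = 30, end = 330, tx_conc = 0)
  tc0 <- gen_block_timecourse(73, 0.0062, sched, t_end = 600)
  expect_equal(tc0$amplitudes, rep(1, length(tc0$times)))
  tcn <- gen_block_timecourse(73, 0.0062, sched, t_end = 600,
                              noise_sd = 0.01, seed = 8)
  expect_equal(mean(tcn$amplitudes), 1, tolerance = 5e-3)
  expect_gt(stats::sd(tcn$amplitudes), 0.005)
})

test_that("recovery kinetics switch instantly with the perfused
           condition in an alternating-solution schedule", {
  # wash-out monitored first in a slow-off condition, then switched to a
  # fast-off condition: each piece relaxes with its own k_off only
  k_slow <- 0.0062
  k_fast <- 0.013
  sched <- data.frame(
    start = c(0, 300, 600),
    end = c(300, 600, 1200),
    tx_conc = c(2.5e-4, 0, 0),
    k_on = c(73, 73, 28),
    k_off = c(k_slow, k_slow, k_fast)
  )
  tc <- gen_block_timecourse(73, k_slow, sched, t_end = 1200)
  f1 <- fit_monoexponential(tc$times, tc$amplitudes,
                            window = c(300, 600))
  f2 <- fit_monoexponential(tc$times, tc$amplitudes,
                            window = c(600, 1200))
  expect_equal(f1$tau, 1 / k_slow, tolerance = 1e-4)
  expect_equal(f2$tau, 1 / k_fast, tolerance = 1e-4)
})

test_that("overlapping schedule segments are rejected", {
  bad <- data.frame(start = c(0, 100), end = c(200, 300),
                    tx_conc = c(1e-4, 0))
  expect_error(gen_block_timecourse(73, 0.0062, bad, t_end = 400),
               "overlap")
})

test_that("a perfusion lag slows the apparent onset but not the
           equilibrium", {
  sched <- data.frame(start = 0, end = 900, tx_conc = 2.5e-4)
  fast <- gen_block_timecourse(73, 0.0062, sched, t_end = 900)
  lag <- gen_block_timecourse(73, 0.0062, sched, t_end = 900,
                              perfusion_tau = 10)
  expect_equal(min(lag$amplitudes), min(fast$amplitudes),
               tolerance = 1e-3)
  expect_gt(lag$amplitudes[10], fast$amplitudes[10])
})

test_that("noiseless trace families round-trip through the ratio
           pipeline to high precision", {
  lr <- ref$low_ionic$k10
  co <- phys_constants()
  vt <- thermal_voltage(co)
  pairs <- gen_trace_family(
    50, 2, lr$kon0, lr$zd_on, lr$koff0, lr$zd_off,
    toxin_conc = 0.005, kdc = 1.84, z_gate = 3.9, v_half = -66,
    t_end = 100
  )
  rr <- trace_ratio(pairs[[1]], 0.1)
  ff <- fit_monoexponential(rr$time, rr$ratio)
  koff_v <- lr$koff0 * exp(lr$zd_off * 50 / vt)
  kon_v <- lr$kon0 * exp(lr$zd_on * 50 / vt)
  lam <- kon_v * 0.005 + koff_v
  expect_equal(ff$tau, 1000 / lam, tolerance = 1e-6)
  expect_equal(ff$baseline, koff_v / lam, tolerance = 1e-6)
})

test_that("zero toxin concentration is rejected by the trace generator
           while a tiny one gives ratio ~1", {
  lr <- ref$low_ionic$k10
  expect_error(gen_trace_family(50, 2, lr$kon0, lr$zd_on, lr$koff0,
                                lr$zd_off, 0, 1.84, 3.9, -66),
               "> 0")
  pairs <- gen_trace_family(50, 2, lr$kon0, lr$zd_on, lr$koff0,
                            lr$zd_off, 1e-9, 1.84, 3.9, -66)
  rr <- trace_ratio(pairs[[1]])
  expect_equal(stats::median(rr$ratio), 1, tolerance = 1e-3)
})

test_that("holding voltage changes the relaxation start point but not
           the open-channel kinetics", {
  lr <- ref$low_ionic$k10
  mk <- function(vh) gen_trace_family(
    50, 2, lr$kon0, lr$zd_on, lr$koff0, lr$zd_off, 0.005, 1.84,
    3.9, -66, holding_voltage = vh, t_end = 100
  )[[1]]
  f120 <- fit_monoexponential(trace_ratio(mk(-120))[, 1:2])
  f60 <- fit_monoexponential(trace_ratio(mk(-60))[, 1:2])
  expect_equal(f120$tau, f60$tau, tolerance = 1e-3)
  expect_equal(f120$baseline, f60$baseline, tolerance = 1e-3)
  # start points: resting unblocked fraction differs between holdings
  u0_120 <- f120$baseline + f120$amplitude
  u0_60 <- f60$baseline + f60$amplitude
  expect_gt(abs(u0_120 - u0_60), 0.005)
})

test_that("the ratio analysis is insensitive to the activation exponent", {
  lr <- ref$low_ionic$k10
  for (pw in c(1, 4)) {
    pairs <- gen_trace_family(50, 2, lr$kon0, lr$zd_on, lr$koff0,
                              lr$zd_off, 0.005, 1.84, 3.9, -66,
                              t_end = 100, power = pw)
    ff <- fit_monoexponential(trace_ratio(pairs[[1]])[, 1:2])
    expect_equal(ff$tau, 28.0, tolerance = 0.02)
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  p <- ref$titration$k_off
  t1 <- gen_titration_table(p, replicates = 3, noise_sd = 0.1, seed = 13)
  t2 <- gen_titration_table(p, replicates = 3, noise_sd = 0.1, seed = 13)
  expect_identical(t1, t2)
  t3 <- gen_titration_table(p, replicates = 3, noise_sd = 0.1, seed = 14)
  expect_false(identical(t1$value, t3$value))
  g1 <- gen_tonic_table(ref$scheme$k10, noise_sd = 0.03, seed = 13)
  g2 <- gen_tonic_table(ref$scheme$k10, noise_sd = 0.03, seed = 13)
  expect_identical(g1, g2)
  expect_error(gen_titration_table(p, noise_sd = 0.1), "mandatory")
  expect_error(gen_tonic_table(ref$scheme$k10, noise_sd = 0.03),
               "mandatory")
})

test_that("noiseless tonic tables evaluate the model exactly and the
           resting limb is voltage independent", {
  co <- phys_constants()
  sch <- ref$scheme$k10
  tab <- gen_tonic_table(sch)
  expect_equal(tab$i_ratio,
               unblocked_fraction(tab$v_mV, sch, co))
  # Po at -120 mV contributes < 1e-3 to I/Io
  u_floor <- 1 / (1 + sch$toxin_conc / sch$kdc)
  expect_lt(abs(tab$i_ratio[tab$v_mV == -120] - u_floor), 1e-3)
})
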
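# Network assembly, canal resistance, and the integrator's physics.

test_that("Poiseuille resistance matches a hand unit conversion", {
  seg <- canal_segments(length_mm = 100, diameter_mm = 5, viscosity_mPa_s = 1)
  # hand oracle: R = 128 mu L / (pi d^4) in SI, then Pa/(m^3/s) -> mmHg/(ml/min)
  r_si <- 128 * 1e-3 * 0.1 / (pi * 0.005^4)
  oracle <- r_si * (1e-6 / 60) / 133.322387415
  expect_equal(seg$r_mmHg_per_ml_min, oracle, tolerance = 1e-12)
  expect_equal(seg$r_mmHg_per_ml_min, 8.15e-4, tolerance = 1e-3)
  # linear in length, inverse fourth power in diameter
  expect_equal(
    canal_segments(200, 5)$r_mmHg_per_ml_min,
    2 * seg$r_mmHg_per_ml_min
  )
  expect_equal(
    canal_segments(100, 10)$r_mmHg_per_ml_min,
    seg$r_mmHg_per_ml_min / 16
  )
})

test_that("assembly builds the configured compliance budget", {
  net <- default_twin()
  p0 <- 760 + 12.68
  expect_equal(compliance_at(net$cranial_chamber, p0), 0.31, tolerance = 1e-12)
  expect_equal(compliance_at(net$spinal_chamber, p0), 0.84, tolerance = 1e-12)
  expect_equal(net$r_canal, sum(net$canal$r_mmHg_per_ml_min))
  expect_equal(nrow(net$canal), 3)
  # a chamber cannot be doubly specified
  cfg <- default_config()
  cfg$chambers$cranial$v0_air_ml <- 300
  expect_error(assemble(cfg), "not both")
  # an explicit air volume alone is accepted
  cfg2 <- list(chambers = list(cranial = list(v0_air_ml = 335.3)))
  net2 <- assemble(cfg2)
  expect_equal(net2$cranial_chamber$v0_air, 335.3)
})

test_that("operating point is a true equilibrium", {
  net <- default_twin()
  op <- operating_point(net)
  expect_equal(op$p_gauge_mmHg, 12.68)
  expect_equal(
    chamber_pressure(net$cranial_chamber, op$v_air_cranial_ml) - 760,
    12.68,
    tolerance = 1e-12
  )
  expect_true(all(op$q_ml_min == 0))
  # zero pump input leaves every series flat at baseline
  zero <- waveform(rep(0, 256), period = 60 / 70)
  sim <- simulate_network(net, zero, n_cycles = 2, warmup_cycles = 0)
  expect_equal(range(sim$icp_mmHg), c(12.68, 12.68), tolerance = 1e-10)
  expect_true(all(abs(sim$q_spinal_ml_min) < 1e-10))
})

test_that("simulation refuses drift-inducing inputs and bad grids", {
  net <- default_twin()
  leaky <- waveform(rep(1, 256), period = 60 / 70) # 1 ml/min net inflow
  expect_error(simulate_network(net, leaky), "net cycle volume")
  pump <- default_pump()
  expect_error(
    simulate_network(net, pump, dt = wf_period(pump) / 1000.5),
    "divide"
  )
})

test_that("small-signal response matches the linearized RC closed form", {
  # oracle: linearize both chambers at the operating point
  # (C = V0/(lambda p_abs)); for a sinusoidal pump of amplitude A at
  # angular frequency w, the spinal-flow amplitude is
  # A / (60 Cc Rt) / sqrt(w^2 + (k/Rt)^2), k = 1/(60 Cc) + 1/(60 Cs)
  net <- default_twin()
  period <- 60 / 70
  amp <- 2 # ml/min, small signal
  t <- period * (0:511) / 512
  pump <- waveform(amp * sin(2 * pi * t / period), period = period)
  sim <- simulate_network(net, pump, n_cycles = 3, warmup_cycles = 4)
  p_abs <- 760 + net$baseline_icp_mmHg
  cc <- net$cranial_chamber$v0_air / (net$cranial_chamber$lam * p_abs)
  cs <- net$spinal_chamber$v0_air / (net$spinal_chamber$lam * p_abs)
  r_par <- 1 / (1 / net$r_valve1_path + 1 / net$r_valve2)
  rt <- r_par + net$r_canal
  k <- 1 / (60 * cc) + 1 / (60 * cs)
  w <- 2 * pi / period
  oracle_amp <- amp / (60 * cc * rt) / sqrt(w^2 + (k / rt)^2)
  sim_amp <- (max(sim$q_spinal_ml_min) - min(sim$q_spinal_ml_min)) / 2
  expect_equal(sim_amp, oracle_amp, tolerance = 0.01)
})

test_that("the integrator conserves volume and reaches a periodic steady state", {
  sim <- calibrated_sim()
  marks <- attr(sim, "cycle_marks")
  n_div <- marks[2] - marks[1]
  q <- matrix(sim$q_spinal_ml_min, nrow = n_div)
  # net spinal volume per cycle vanishes
  net_vol <- colSums(q) * attr(sim, "dt") / 60
  expect_true(all(abs(net_vol) < 1e-3))
  # cycle-to-cycle mean ICP is stationary
  icp <- matrix(sim$icp_mmHg, nrow = n_div)
  expect_lt(diff(range(colMeans(icp))), 1e-3)
})

test_that("resistance and compliance move the flow the physical way", {
  net <- default_twin()
  pump <- default_pump()
  quick <- function(n) {
    s <- simulate_network(n, pump,
      n_cycles = 2, warmup_cycles = 2,
      dt = wf_period(pump) / 512
    )
    q <- cycle_mean_flow(s)
    c(max(q$flow_ml_min), stroke_volume(q))
  }
  base <- quick(net)
  # larger canal resistance -> smaller caudal maximum
  net_hi_r <- net
  net_hi_r$r_canal <- net$r_canal * 20
  expect_lt(quick(net_hi_r)[1], base[1])
  # larger spinal compliance -> larger spinal stroke volume
  cfg <- default_config()
  cfg$chambers$spinal$c_target_ml_per_mmHg <- 1.68
  expect_gt(quick(assemble(cfg))[2], base[2])
})
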
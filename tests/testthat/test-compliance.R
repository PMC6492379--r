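# Isentropic chamber physics and compliance budgets.

test_that("chamber pressure follows the isentropic invariant", {
  ch <- air_chamber(v0_air = 335.3, p0_abs = 772.68)
  expect_equal(chamber_pressure(ch, 335.3), 772.68)
  # independent log-domain evaluation of the gas law as oracle
  oracle <- exp(log(772.68) + 1.4 * log(335.3 / 334.3))
  expect_equal(chamber_pressure(ch, 334.3), oracle, tolerance = 1e-12)
  expect_equal(oracle, 775.9, tolerance = 1e-4)
  # p * V^lam is invariant across states
  v <- c(300, 320, 335.3, 350)
  pv <- chamber_pressure(ch, v) * v^1.4
  expect_equal(max(pv) / min(pv) - 1, 0, tolerance = 1e-12)
  # Boyle limit: lam = 1, halving the volume doubles the pressure
  iso <- air_chamber(v0_air = 100, p0_abs = 760, lam = 1)
  expect_equal(chamber_pressure(iso, 50), 1520)
  expect_error(chamber_pressure(ch, -1), "positive")
})

test_that("chamber_volume inverts chamber_pressure", {
  ch <- air_chamber(v0_air = 908.7, p0_abs = 772.68)
  for (v in c(850, 908.7, 950)) {
    expect_equal(chamber_volume(ch, chamber_pressure(ch, v)), v, tolerance = 1e-12)
  }
})

test_that("compliance matches the finite difference of the gas law", {
  ch <- air_chamber(v0_air = 335.3, p0_abs = 772.68)
  # closed-form collapse at the reference state
  expect_equal(compliance_at(ch, 772.68), 335.3 / (1.4 * 772.68), tolerance = 1e-12)
  expect_equal(compliance_at(ch, 772.68), 0.310, tolerance = 1e-3)
  # property: analytic compliance equals central finite difference of the
  # volume-pressure relation for random chambers
  set.seed(42)
  for (i in 1:20) {
    chr <- air_chamber(
      v0_air = runif(1, 50, 2000),
      p0_abs = runif(1, 700, 900),
      lam = runif(1, 1, 1.67)
    )
    p1 <- runif(1, 700, 900)
    v1 <- chamber_volume(chr, p1)
    dv <- 1e-5 * chr$v0_air
    # C = -dV/dp; central difference via the pressure at v1 +/- dv
    dp <- chamber_pressure(chr, v1 - dv) - chamber_pressure(chr, v1 + dv)
    c_fd <- 2 * dv / dp
    expect_equal(compliance_at(chr, p1), c_fd, tolerance = 1e-6)
  }
  # monotone decrease with pressure
  ps <- seq(700, 900, by = 10)
  expect_true(all(diff(compliance_at(ch, ps)) < 0))
})

test_that("isothermal limit reproduces C = V0 p0 / p1^2", {
  ch <- air_chamber(v0_air = 500, p0_abs = 800, lam = 1)
  for (p1 in c(700, 800, 900)) {
    expect_equal(compliance_at(ch, p1), 500 * 800 / p1^2, tolerance = 1e-12)
  }
})

test_that("air-volume sizing round-trips through compliance_at", {
  p_op <- 760 + 12.68
  v_cr <- size_air_volume(0.31, p_op)
  v_sp <- size_air_volume(0.84, p_op)
  expect_equal(v_cr, 335.3, tolerance = 1e-3)
  expect_equal(v_sp, 908.7, tolerance = 1e-3)
  for (c_t in c(0.1, 0.31, 0.84, 2)) {
    v0 <- size_air_volume(c_t, p_op)
    ch <- air_chamber(v0_air = v0, p0_abs = p_op)
    expect_equal(compliance_at(ch, p_op), c_t, tolerance = 1e-12)
  }
  expect_error(size_air_volume(-0.1, p_op), "positive")
})

test_that("compliance budget sums compartments and computes shares", {
  budget <- total_compliance(c(cranial = 0.31, spinal = 0.84))
  expect_equal(attr(budget, "c_total"), 1.15)
  expect_equal(budget$share_pct[budget$compartment == "cranial"], 27)
  # the spinal share computed from the values is 73%, not the often-quoted 68%
  expect_equal(budget$share_pct[budget$compartment == "spinal"], 73)
  expect_equal(sum(budget$share_pct), 100)
  single <- total_compliance(c(only = 0.5))
  expect_equal(single$share_pct, 100)
  expect_error(total_compliance(numeric(0)), "at least one")
  expect_error(total_compliance(c(0.3, -0.1)), "positive")
})
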
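# Flow and pressure metrics.

test_that("stroke volume integrates the caudal lobe", {
  expect_equal(stroke_volume(rect_waveform(60, 0.3)), 0.3, tolerance = 1e-12)
  neg <- waveform(rep(-10, 64), period = 0.8)
  expect_equal(stroke_volume(neg), 0)
  # invariance under circular shift
  av <- default_pump()
  v <- av$flow_ml_min
  shifted <- waveform(c(v[101:256], v[1:100]), period = wf_period(av))
  expect_equal(stroke_volume(shifted), stroke_volume(av), tolerance = 1e-12)
  # zero net volume: positive lobe equals negative lobe
  expect_equal(
    stroke_volume(av),
    -sum(pmin(v, 0)) * wf_dt(av) / 60,
    tolerance = 1e-9
  )
})

test_that("flow extrema follow the caudal-positive convention", {
  t <- 2 * pi * (0:255) / 256
  sine <- waveform(40 * sin(t), period = 0.8)
  ex <- flow_extrema(sine)
  expect_equal(ex$max_caudal, 40, tolerance = 1e-6)
  expect_equal(ex$max_cranial, -40, tolerance = 1e-6)
  flat <- waveform(rep(7, 64), period = 0.8)
  exf <- flow_extrema(flat)
  expect_equal(exf$max_caudal, exf$max_cranial)
})

test_that("phase of the cranial maximum is anchor-invariant", {
  t <- 2 * pi * (0:255) / 256
  # -cos: caudal max at t = pi (antipodal minimum at 0 <-> 50% away)
  wf <- waveform(-cos(t) * 50, period = 0.8)
  expect_equal(phase_of_cranial_max(wf), 50)
  # any circular shift leaves the anchored phase unchanged
  v <- default_pump()$flow_ml_min
  base <- phase_of_cranial_max(waveform(v, period = 0.857))
  for (k in c(17, 100, 200)) {
    shifted <- waveform(c(v[(k + 1):256], v[1:k]), period = 0.857)
    expect_equal(phase_of_cranial_max(shifted), base)
  }
  # tie between two equal minima: the earlier one is reported
  vt <- rep(0, 64)
  vt[1] <- 10
  vt[20] <- -5
  vt[40] <- -5
  tie <- waveform(vt, period = 0.8)
  expect_equal(phase_of_cranial_max(tie), 100 * 19 / 64)
  expect_warning(ph <- phase_of_cranial_max(waveform(rep(1, 64), period = 0.8)), "Flat")
  expect_true(is.na(ph))
})

test_that("phase and extrema are stable under resampling", {
  q <- cycle_mean_flow(calibrated_sim())
  q512 <- resample_waveform(q, 512)
  expect_equal(
    flow_extrema(q512)$max_caudal, flow_extrema(q)$max_caudal,
    tolerance = 0.005
  )
  expect_equal(
    phase_of_cranial_max(q512), phase_of_cranial_max(q),
    tolerance = 0.005
  )
})

test_that("cycle splitting produces one segment per cycle", {
  sim <- calibrated_sim()
  seg <- cycle_split(sim, what = "icp")
  expect_equal(dplyr::n_distinct(seg$cycle), 9)
  # deterministic periodic input: segments are identical
  wide <- tidyr::pivot_wider(seg, names_from = "cycle", values_from = "value")
  mat <- as.matrix(wide[, -1])
  expect_lt(max(apply(mat, 1, function(r) diff(range(r)))), 1e-5)
})

test_that("minimum-to-minimum splitting finds cycle boundaries", {
  # four synthetic pressure cycles sampled at 100 Hz
  t <- seq(0, 4, by = 0.01)[-401]
  p <- 12 + 2 * sin(2 * pi * t - pi / 2) # interior minima at t = 1, 2, 3
  seg <- cycle_split(p, n_phase = 101)
  expect_gte(dplyr::n_distinct(seg$cycle), 2)
  # boundaries sit at local minima: segment endpoints are near the trace min
  firsts <- dplyr::filter(seg, .data$phase_pct == 0)
  expect_true(all(firsts$value < 10.2))
  expect_error(cycle_split(p[1:50]), "fewer than two")
})

test_that("ICP statistics recover constructed pulse features", {
  # constant trace: degenerate statistics, flagged peaks
  const <- tibble::tibble(
    cycle = 1L, phase_pct = seq(0, 100, length.out = 101),
    value = 12.68
  )
  s <- icp_stats(const)
  expect_equal(s$mean_icp, 12.68)
  expect_equal(s$max_icp, 12.68)
  expect_equal(s$min_icp, 12.68)
  expect_true(is.na(s$mwa))
  # two-Gaussian pulse with heights 1.0 and 0.792 above baseline
  phase <- seq(0, 100, length.out = 201)
  pulse <- 10 +
    1.0 * exp(-0.5 * ((phase - 25) / 6)^2) +
    0.792 * exp(-0.5 * ((phase - 60) / 8)^2)
  seg <- tibble::tibble(cycle = 1L, phase_pct = phase, value = pulse)
  s2 <- icp_stats(seg)
  expect_equal(s2$mwa, 1.0, tolerance = 0.02)
  expect_equal(s2$p2_to_p1, 0.792, tolerance = 0.02)
})

test_that("cohort comparison reports differences and the timing offset", {
  tmpl <- template_cervical_flow()
  cohort <- purrr::map_dfr(synth_cohort(cohort_spec(seed = 2)), flow_metrics)
  rec <- flow_metrics(tmpl)
  cmp <- compare_flow(rec, cohort)
  expect_setequal(
    cmp$metric,
    c("sv_ml", "max_caudal", "max_cranial", "phase_cranial_max_pct")
  )
  # a recording equal to the cohort mean has zero differences
  mean_rec <- dplyr::summarise(cohort, dplyr::across(dplyr::everything(), mean))
  cmp0 <- compare_flow(mean_rec, cohort)
  expect_true(all(abs(cmp0$diff) < 1e-9))
  # single-member cohort: envelope equals that member
  cmp1 <- compare_flow(rec, cohort[1, ])
  expect_equal(cmp1$cohort_min, cmp1$cohort_max)
  # timing offset between an early (25%) and a late (63%) cranial maximum
  a <- tibble::tibble(phase_cranial_max_pct = 25)
  b <- tibble::tibble(phase_cranial_max_pct = 63)
  dt_row <- compare_flow(a, b)
  expect_equal(dt_row$diff, -38)
})
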
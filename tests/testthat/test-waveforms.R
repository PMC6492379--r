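# Waveform construction, AV synthesis, volume bookkeeping.

test_that("waveform constructor validates its grid and invariants", {
  wf <- waveform(rep(1, 64), period = 0.5)
  expect_s3_class(wf, "csf_waveform")
  expect_equal(nrow(wf), 64)
  expect_equal(wf$time_s[2] - wf$time_s[1], 0.5 / 64)
  expect_error(waveform(rep(1, 16)), "32")
  expect_error(waveform(rep(1, 64), period = -1), "positive")
  expect_error(waveform(c(rep(1, 63), NA)), "finite")
})

test_that("arterial generator: degenerate peak gives a constant waveform", {
  wf <- generate_arterial(peak_flow = 0, baseline = 100)
  expect_true(all(wf$flow_ml_min == 100))
})

test_that("arterial generator peaks at the systolic time", {
  wf <- generate_arterial(systolic_time = 0.3)
  expect_equal(wf$time_s[which.max(wf$flow_ml_min)], 0.3, tolerance = wf_dt(wf) / 0.3)
})

test_that("gaussian lobe volume matches the closed form", {
  # oracle: integral of the lobe is peak * width * sqrt(2*pi) / 60 ml, with
  # negligible circular-wrap truncation for width << period; checked against
  # adaptive quadrature of the continuous lobe
  for (p in list(c(300, 0.08), c(150, 0.05), c(500, 0.1))) {
    peak <- p[1]; width <- p[2]
    wf <- generate_arterial(
      peak_flow = peak, width = width, baseline = 50,
      systolic_time = 0.4, n_samples = 1024
    )
    lobe_ml <- (sum(wf$flow_ml_min) * wf_dt(wf) - 50 * wf_period(wf)) / 60
    closed_form <- peak * width * sqrt(2 * pi) / 60
    quad <- stats::integrate(
      function(t) peak * exp(-0.5 * (t / width)^2) / 60,
      -wf_period(wf) / 2, wf_period(wf) / 2
    )$value
    # nearest-image wrapping truncates the lobe at half a period, so the
    # quadrature oracle integrates the same window; the closed form over the
    # full line agrees up to the (tiny) tail mass
    expect_equal(lobe_ml, quad, tolerance = 1e-9)
    expect_equal(closed_form, quad, tolerance = 1e-4)
  }
})

test_that("venous derivation is volume-conserving and shifts as requested", {
  art <- generate_arterial()
  expect_equal(
    derive_venous(art, delay = 0, smoothing_width = 0)$flow_ml_min,
    art$flow_ml_min
  )
  for (delay in c(0.1, 0.3)) {
    for (sw in c(0, 0.05, 0.2)) {
      ven <- derive_venous(art, delay = delay, smoothing_width = sw)
      expect_equal(wf_net_volume(ven), wf_net_volume(art), tolerance = 1e-12)
    }
  }
  # quarter-cycle delay moves the peak by a quarter cycle
  shift <- wf_period(art) / 4
  ven <- derive_venous(art, delay = shift, smoothing_width = 0)
  t_peak_art <- art$time_s[which.max(art$flow_ml_min)]
  t_peak_ven <- ven$time_s[which.max(ven$flow_ml_min)]
  expect_equal((t_peak_ven - t_peak_art) %% wf_period(art), shift, tolerance = 1e-9)
  expect_error(derive_venous(art, delay = 0, smoothing_width = 2), "smoothing_width")
  expect_error(derive_venous(art, delay = -0.1), "delay")
})

test_that("volume matching scales the venous cycle volume exactly", {
  art <- rect_waveform(60, 0.5)
  ven <- rect_waveform(30, 0.5)
  matched <- match_venous_volume(art, ven)
  expect_equal(matched$flow_ml_min, 2 * ven$flow_ml_min)
  expect_equal(wf_net_volume(matched), wf_net_volume(art), tolerance = 1e-12)
  # already matched is a fixed point
  again <- match_venous_volume(art, matched)
  expect_equal(again$flow_ml_min, matched$flow_ml_min)
  zero <- waveform(rep(0, 256), period = 0.8)
  expect_error(match_venous_volume(art, zero), "zero")
})

test_that("AV flow has zero net volume and the documented sign structure", {
  art <- generate_arterial()
  ven <- match_venous_volume(art, derive_venous(art))
  av <- av_flow(art, ven)
  expect_lt(abs(wf_net_volume(av)), 1e-9)
  # identical inputs cancel exactly
  expect_true(all(av_flow(art, art)$flow_ml_min == 0))
  # positive during the systolic interval of the default shape
  sys_idx <- which(abs(av$time_s - 0.15) < 0.04)
  expect_true(all(av$flow_ml_min[sys_idx] > 0))
  # mismatched grids are refused
  art2 <- generate_arterial(n_samples = 128)
  expect_error(av_flow(art2, ven), "grid")
  # unmatched volumes are refused
  expect_error(av_flow(art, derive_venous(art) |> (\(v) {
    v$flow_ml_min <- v$flow_ml_min * 1.05
    v
  })()), "volume-matched")
})

test_that("stroke-volume scaling is an exact linear operation", {
  av <- av_waveform()
  expect_equal(wf_positive_volume(av), 0.8, tolerance = 1e-12)
  half <- scale_to_stroke_volume(av, 0.4)
  expect_equal(half$flow_ml_min, av$flow_ml_min / 2)
  expect_equal(wf_positive_volume(half), 0.4, tolerance = 1e-12)
  same <- scale_to_stroke_volume(av, wf_positive_volume(av))
  expect_equal(same$flow_ml_min, av$flow_ml_min)
  neg <- waveform(rep(-5, 64), period = 0.8)
  expect_error(scale_to_stroke_volume(neg, 0.8), "positive lobe")
})

test_that("volume bookkeeping survives tiling and resampling", {
  av <- av_waveform()
  # tiling k cycles multiplies the integral exactly by k
  k <- 3
  tiled <- waveform(rep(av$flow_ml_min, k), period = k * wf_period(av))
  expect_equal(wf_net_volume(tiled), k * wf_net_volume(av), tolerance = 1e-12)
  expect_equal(wf_positive_volume(tiled), k * wf_positive_volume(av), tolerance = 1e-12)
  # periodic resampling preserves extrema and volumes to first order
  fine <- resample_waveform(av, 512)
  expect_equal(wf_net_volume(fine), wf_net_volume(av), tolerance = 1e-9)
  expect_equal(max(fine$flow_ml_min), max(av$flow_ml_min), tolerance = 1e-3)
})
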
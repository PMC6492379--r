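# Shared fixtures. The calibrated twin is expensive enough to build once and
# reuse across test files.

.twin_cache <- new.env(parent = emptyenv())

# rectangular single-cycle waveform with sample-aligned edges
rect_waveform <- function(level = 60, on_s = 0.3, period = 0.8, n = 256) {
  dt <- period / n
  k <- round(on_s / dt)
  stopifnot(abs(k * dt - on_s) < 1e-12) # keep test fixtures exactly aligned
  waveform(c(rep(level, k), rep(0, n - k)), period = period)
}

default_twin <- function() {
  if (is.null(.twin_cache$net)) {
    .twin_cache$net <- assemble(default_config())
  }
  .twin_cache$net
}

default_pump <- function() {
  if (is.null(.twin_cache$pump)) {
    .twin_cache$pump <- av_waveform()
  }
  .twin_cache$pump
}

# valve calibration against the reference bidirectional extrema, memoized
calibrated_twin <- function() {
  if (is.null(.twin_cache$cal)) {
    .twin_cache$cal <- calibrate_resistances(
      default_twin(), default_pump(),
      target_caudal_max = 133.60, target_cranial_max = -68.01
    )
  }
  .twin_cache$cal
}

calibrated_sim <- function() {
  if (is.null(.twin_cache$sim)) {
    .twin_cache$sim <- simulate_network(calibrated_twin()$network, default_pump())
  }
  .twin_cache$sim
}
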
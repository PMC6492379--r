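# Time-domain integration of the hydraulic network.

#' Simulate the craniospinal network
#'
#' Integrates the two-state system (the air volumes of the cranial and spinal
#' chambers) with a fixed-step classical 4th-order Runge--Kutta scheme. The
#' cistern node N3 carries no storage, so its pressure follows algebraically
#' from the chamber pressures:
#' `p3 = (G p1 + p4 / R_canal) / (G + 1 / R_canal)` with
#' `G = 1/R_valve1_path + 1/R_valve2`. The spinal flow is
#' `Q_sc = (p3 - p4) / R_canal` and the ICP is reported at the sensor node
#' inside the valve-1 path, `ICP = p1 - f (p1 - p3)` with `f` the
#' `valve1_fraction` of the path resistance upstream of the sensor.
#'
#' The pump waveform must carry zero net cycle volume; otherwise the sealed
#' model would drift monotonically and the run is refused. The fixed step
#' (`period / dt_divisor`) keeps cycle boundaries exactly on grid points and
#' makes runs bit-reproducible. Warm-up cycles (two by default, like the
#' bench's two priming rotations) are integrated and discarded.
#'
#' Baseline referencing: over a cycle the piston's cumulative displaced
#' volume has a non-zero time average, which raises the sealed system's mean
#' pressure by that average divided by the total compliance. Like a bench
#' zeroed while running, the simulation starts both chambers at the common
#' pressure `baseline - mean(stored pump volume)/C_total`, so the cycle-mean
#' ICP in the periodic steady state equals the configured baseline (to well
#' within 0.05 mmHg; the residual is the second-order effect of the
#' chambers' nonlinearity).
#'
#' @param net A `csf_network` from [assemble()].
#' @param pump A zero-net-volume `csf_waveform` driving flow (ml/min into the
#'   cranial node positive).
#' @param n_cycles Number of recorded cycles (>= 1).
#' @param warmup_cycles Cycles integrated and discarded before recording.
#' @param dt Optional fixed step in seconds; must divide the period exactly.
#'   Defaults to `period / net$sim$dt_divisor`.
#' @return A `csf_simulation`: a tibble with columns `time_s`, `icp_mmHg`,
#'   `p_cistern_mmHg`, `p_cranial_chamber_mmHg`, `p_spinal_chamber_mmHg`,
#'   `q_spinal_ml_min` (gauge pressures, caudal-positive flow), with
#'   attributes `period`, `cycle_marks` (row indices of cycle starts) and
#'   `network`.
#' @export
#' @examples
#' net <- assemble(default_config())
#' sim <- simulate_network(net, av_waveform(), n_cycles = 3)
simulate_network <- function(net, pump,
                             n_cycles = net$sim$record_cycles,
                             warmup_cycles = net$sim$warmup_cycles,
                             dt = NULL) {
  period <- wf_period(pump)
  if (n_cycles < 1) stop("`n_cycles` must be at least 1.", call. = FALSE)
  if (abs(wf_net_volume(pump)) > 1e-6) {
    stop(
      "Pump waveform has non-zero net cycle volume (",
      format(wf_net_volume(pump), digits = 3),
      " ml): the sealed model would drift. Volume-match the waveform first.",
      call. = FALSE
    )
  }
  if (is.null(dt)) {
    n_div <- net$sim$dt_divisor
  } else {
    n_div <- period / dt
    if (abs(n_div - round(n_div)) > 1e-9) {
      stop("`dt` must divide the cycle period exactly.", call. = FALSE)
    }
    n_div <- as.integer(round(n_div))
  }
  h <- period / n_div

  # pump samples on the half-step grid of one cycle (periodic linear interp)
  two_n <- 2L * n_div
  fine <- resample_waveform(pump, two_n)$flow_ml_min

  ch_c <- net$cranial_chamber
  ch_s <- net$spinal_chamber
  lp0c <- log(ch_c$p0_abs); lv0c <- log(ch_c$v0_air); lamc <- ch_c$lam
  lp0s <- log(ch_s$p0_abs); lv0s <- log(ch_s$v0_air); lams <- ch_s$lam
  g_par <- 1 / net$r_valve1_path + 1 / net$r_valve2
  rc <- net$r_canal
  denom <- g_par + 1 / rc

  # piston neutral-position correction: cycle-mean of the cumulative pump
  # volume (ml), referenced to the piston position at t = 0
  q_step <- fine[seq.int(1L, two_n, by = 2L)]
  cum_ml <- (h / 60) * (cumsum(q_step) - q_step / 2 - q_step[1] / 2)
  v_bar <- mean(cum_ml)
  p_base_abs <- MMHG_ATM + net$baseline_icp_mmHg
  c_tot <- compliance_at(ch_c, p_base_abs) + compliance_at(ch_s, p_base_abs)
  p_init_abs <- p_base_abs - v_bar / c_tot

  n_steps <- (warmup_cycles + n_cycles) * n_div
  va_c <- numeric(n_steps + 1)
  va_s <- numeric(n_steps + 1)
  va_c[1] <- chamber_volume(ch_c, p_init_abs)
  va_s[1] <- chamber_volume(ch_s, p_init_abs)

  yc <- va_c[1]; ys <- va_s[1]
  for (k in seq_len(n_steps)) {
    base <- (2L * (k - 1L)) %% two_n # 0-based index of q(t_k) in fine grid
    q0 <- fine[base + 1L]
    qm <- fine[(base + 1L) %% two_n + 1L]
    q1 <- fine[(base + 2L) %% two_n + 1L]

    # derivative of (va_c, va_s); inlined for speed
    f1c <- exp(lp0c + lamc * (lv0c - log(yc)))
    f1s <- exp(lp0s + lams * (lv0s - log(ys)))
    p3 <- (g_par * f1c + f1s / rc) / denom
    qsc <- (p3 - f1s) / rc
    k1c <- -(q0 - qsc) / 60; k1s <- -qsc / 60

    y2c <- yc + h / 2 * k1c; y2s <- ys + h / 2 * k1s
    f1c <- exp(lp0c + lamc * (lv0c - log(y2c)))
    f1s <- exp(lp0s + lams * (lv0s - log(y2s)))
    p3 <- (g_par * f1c + f1s / rc) / denom
    qsc <- (p3 - f1s) / rc
    k2c <- -(qm - qsc) / 60; k2s <- -qsc / 60

    y3c <- yc + h / 2 * k2c; y3s <- ys + h / 2 * k2s
    f1c <- exp(lp0c + lamc * (lv0c - log(y3c)))
    f1s <- exp(lp0s + lams * (lv0s - log(y3s)))
    p3 <- (g_par * f1c + f1s / rc) / denom
    qsc <- (p3 - f1s) / rc
    k3c <- -(qm - qsc) / 60; k3s <- -qsc / 60

    y4c <- yc + h * k3c; y4s <- ys + h * k3s
    f1c <- exp(lp0c + lamc * (lv0c - log(y4c)))
    f1s <- exp(lp0s + lams * (lv0s - log(y4s)))
    p3 <- (g_par * f1c + f1s / rc) / denom
    qsc <- (p3 - f1s) / rc
    k4c <- -(q1 - qsc) / 60; k4s <- -qsc / 60

    yc <- yc + h / 6 * (k1c + 2 * k2c + 2 * k3c + k4c)
    ys <- ys + h / 6 * (k1s + 2 * k2s + 2 * k3s + k4s)
    va_c[k + 1] <- yc
    va_s[k + 1] <- ys
  }

  # recorded closed-open window [warmup*T, (warmup+n)*T)
  idx <- seq.int(warmup_cycles * n_div + 1L, n_steps) # state indices (1-based)
  vc <- va_c[idx]
  vs <- va_s[idx]
  p1 <- chamber_pressure(ch_c, vc) - MMHG_ATM
  p4 <- chamber_pressure(ch_s, vs) - MMHG_ATM
  p3 <- (g_par * p1 + p4 / rc) / denom
  q_sc <- (p3 - p4) / rc
  icp <- p1 - net$valve1_fraction * (p1 - p3)

  out <- tibble::tibble(
    time_s = h * (seq_along(idx) - 1),
    icp_mmHg = icp,
    p_cistern_mmHg = p3,
    p_cranial_chamber_mmHg = p1,
    p_spinal_chamber_mmHg = p4,
    q_spinal_ml_min = q_sc
  )
  structure(
    out,
    period = period,
    dt = h,
    cycle_marks = 1L + (seq_len(n_cycles) - 1L) * n_div,
    network = net,
    class = c("csf_simulation", class(tibble::tibble()))
  )
}

#' @export
print.csf_simulation <- function(x, ...) {
  cat(sprintf(
    "<csf_simulation: %d cycles of %.4f s at dt = %.2e s>\n",
    length(attr(x, "cycle_marks")), attr(x, "period"), attr(x, "dt")
  ))
  NextMethod()
}

#' Cycle-mean spinal flow of a simulation
#'
#' Averages the recorded spinal-flow samples across cycles into a
#' single-cycle `csf_waveform` (the analogue of the bench's mean flow over
#' nine cycles).
#'
#' @param sim A `csf_simulation`.
#' @return A `csf_waveform` (caudal positive).
#' @export
cycle_mean_flow <- function(sim) {
  marks <- attr(sim, "cycle_marks")
  n_div <- if (length(marks) > 1) marks[2] - marks[1] else nrow(sim)
  m <- matrix(sim$q_spinal_ml_min, nrow = n_div)
  waveform(rowMeans(m), period = attr(sim, "period"))
}

#' Cycle-mean ICP trace of a simulation
#'
#' @param sim A `csf_simulation`.
#' @return A tibble with `time_s` and `icp_mmHg` over one cycle.
#' @export
cycle_mean_icp <- function(sim) {
  marks <- attr(sim, "cycle_marks")
  n_div <- if (length(marks) > 1) marks[2] - marks[1] else nrow(sim)
  m <- matrix(sim$icp_mmHg, nrow = n_div)
  tibble::tibble(
    time_s = attr(sim, "period") * (seq_len(n_div) - 1) / n_div,
    icp_mmHg = rowMeans(m)
  )
}
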
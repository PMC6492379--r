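# One-cardiac-cycle flow waveforms: construction, AV synthesis, cohort emulation.

#' Construct a single-cycle sampled flow waveform
#'
#' A `csf_waveform` is a tibble with columns `time_s` (uniform closed-open grid
#' on `[0, period)`) and `flow_ml_min`, carrying the cycle period and the sign
#' convention as attributes. Flow directed caudally (out of the cranium, down
#' the spinal canal) is positive.
#'
#' @param flow_ml_min Numeric vector of flow samples in ml/min, at least 32 per
#'   cycle (the temporal resolution of cardiac-gated cine PC-MRI).
#' @param period Cycle duration in seconds (default one beat at 70 bpm).
#' @param sign_convention Either `"caudal_positive"` (cervical flow) or
#'   `"into_cranium_positive"` (AV blood inflow); informational.
#' @return A `csf_waveform` tibble.
#' @export
#' @examples
#' wf <- waveform(sin(2 * pi * seq(0, 1, length.out = 257)[-257]) * 50)
#' wf_stats <- flow_extrema(wf)
waveform <- function(flow_ml_min, period = 60 / 70,
                     sign_convention = c("caudal_positive", "into_cranium_positive")) {
  sign_convention <- match.arg(sign_convention)
  if (!is.numeric(period) || length(period) != 1 || !is.finite(period) || period <= 0) {
    stop("`period` must be a single positive number of seconds.", call. = FALSE)
  }
  if (!is.numeric(flow_ml_min) || length(flow_ml_min) < 32) {
    stop("A waveform needs at least 32 uniform samples per cycle.", call. = FALSE)
  }
  if (any(!is.finite(flow_ml_min))) {
    stop("Flow samples must all be finite.", call. = FALSE)
  }
  n <- length(flow_ml_min)
  out <- tibble::tibble(
    time_s = period * (seq_len(n) - 1) / n,
    flow_ml_min = as.numeric(flow_ml_min)
  )
  new_csf_waveform(out, period = period, sign_convention = sign_convention)
}

new_csf_waveform <- function(x, period, sign_convention = "caudal_positive") {
  structure(
    x,
    period = period,
    sign_convention = sign_convention,
    class = c("csf_waveform", class(tibble::tibble()))
  )
}

#' @export
print.csf_waveform <- function(x, ...) {
  cat(sprintf(
    "<csf_waveform: %d samples, period %.4f s (%.1f bpm), %s>\n",
    nrow(x), wf_period(x), 60 / wf_period(x), attr(x, "sign_convention")
  ))
  NextMethod()
}

#' Waveform accessors
#'
#' Small helpers for `csf_waveform` objects: the cycle period (s), the sample
#' spacing (s), and the net and positive-lobe cycle volumes (ml).
#'
#' @param wf A `csf_waveform`.
#' @return A single numeric value.
#' @export
wf_period <- function(wf) {
  p <- attr(wf, "period")
  if (is.null(p)) stop("Not a csf_waveform: missing period attribute.", call. = FALSE)
  p
}

#' @rdname wf_period
#' @export
wf_dt <- function(wf) wf_period(wf) / nrow(wf)

#' @rdname wf_period
#' @export
wf_net_volume <- function(wf) {
  # Periodic closed-open grid: the Riemann sum IS the trapezoid of the
  # periodic extension. min -> s conversion.
  sum(wf$flow_ml_min) * wf_dt(wf) / 60
}

#' @rdname wf_period
#' @export
wf_positive_volume <- function(wf) {
  sum(pmax(wf$flow_ml_min, 0)) * wf_dt(wf) / 60
}

assert_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || abs(wf_period(a) - wf_period(b)) > 1e-9) {
    stop("Waveform grid mismatch: operands must share sample count and period.",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

# circular distance from each grid time to a reference time
circ_dist <- function(t, t0, period) {
  d <- (t - t0) %% period
  pmin(d, period - d)
}

# Default generator parameters. The parametric shapes emulate cervical
# PC-MRI blood-flow morphology: a sharp systolic arterial lobe riding on the
# mean cerebral inflow, and a venous return that is delayed and flattened by
# the cranial venous reservoir. The arterial lobe amplitude is fixed so that
# the matched AV waveform carries a 0.8 ml stroke volume per cycle.
AV_DEFAULTS <- list(
  peak_flow = 601.40678, # ml/min above baseline; yields SV 0.8 ml after venous matching
  systolic_time = 0.15, # s after cycle start
  width = 0.08, # s, Gaussian sigma of the systolic lobe
  baseline = 700, # ml/min, mean arterial inflow to the cranium
  venous_delay = 0.09, # s, arteriovenous transit delay
  venous_smoothing = 0.13 # s, Gaussian sigma of venous flattening
)

#' Generate a parametric arterial inflow waveform
#'
#' Mean cerebral inflow plus a circularly wrapped Gaussian systolic lobe:
#' `q(t) = baseline + peak_flow * exp(-d(t, systolic_time)^2 / (2 width^2))`
#' with `d` the circular time distance. The defaults reproduce the morphology
#' of cervical PC-MRI arterial recordings and, combined with
#' [derive_venous()] and [av_flow()], an AV stroke volume of 0.8 ml.
#'
#' @param peak_flow Systolic lobe amplitude above baseline, ml/min.
#' @param systolic_time Time of the systolic peak within the cycle, s.
#' @param width Gaussian sigma of the systolic lobe, s.
#' @param baseline Mean inflow level, ml/min.
#' @param period Cycle duration, s (70 bpm default).
#' @param n_samples Samples per cycle (power of two eases resampling).
#' @return A `csf_waveform` (sign convention: into the cranium positive).
#' @export
generate_arterial <- function(peak_flow = AV_DEFAULTS$peak_flow,
                              systolic_time = AV_DEFAULTS$systolic_time,
                              width = AV_DEFAULTS$width,
                              baseline = AV_DEFAULTS$baseline,
                              period = 60 / 70,
                              n_samples = 256) {
  if (!is.finite(period) || period <= 0) {
    stop("`period` must be positive.", call. = FALSE)
  }
  if (!is.finite(width) || width <= 0) {
    stop("`width` must be positive.", call. = FALSE)
  }
  if (systolic_time < 0 || systolic_time >= period) {
    stop("`systolic_time` must lie in [0, period).", call. = FALSE)
  }
  t <- period * (seq_len(n_samples) - 1) / n_samples
  d <- circ_dist(t, systolic_time, period)
  q <- baseline + peak_flow * exp(-0.5 * (d / width)^2)
  waveform(q, period = period, sign_convention = "into_cranium_positive")
}

#' Derive a venous outflow waveform from an arterial one
#'
#' The venous return is modelled as the arterial waveform circularly shifted
#' by an arteriovenous transit delay and flattened by circular Gaussian
#' smoothing (the venous reservoir's low-pass effect). Both operations
#' conserve the cycle volume exactly; the shift is rounded to a whole number
#' of samples so that grids stay aligned.
#'
#' @param arterial A `csf_waveform` of arterial inflow.
#' @param delay Transit delay in seconds, `0 <= delay < period`.
#' @param smoothing_width Gaussian sigma of the smoothing kernel in seconds;
#'   must be smaller than the period. `0` disables smoothing.
#' @return A `csf_waveform` of venous outflow (same sign convention and grid).
#' @export
derive_venous <- function(arterial,
                          delay = AV_DEFAULTS$venous_delay,
                          smoothing_width = AV_DEFAULTS$venous_smoothing) {
  period <- wf_period(arterial)
  if (delay < 0 || delay >= period) {
    stop("`delay` must lie in [0, period).", call. = FALSE)
  }
  if (smoothing_width < 0 || smoothing_width >= period) {
    stop("`smoothing_width` must lie in [0, period).", call. = FALSE)
  }
  v <- arterial$flow_ml_min
  n <- length(v)
  dt <- period / n
  shift <- as.integer(round(delay / dt)) %% n
  if (shift > 0) {
    v <- c(v[(n - shift + 1):n], v[1:(n - shift)])
  }
  if (smoothing_width > 0) {
    v <- circular_gaussian_smooth(v, sigma_samples = smoothing_width / dt)
  }
  out <- arterial
  out$flow_ml_min <- v
  out
}

# Circular convolution with a normalized discrete Gaussian kernel.
# Kernel weights sum to one, so the sample mean (hence cycle volume) is
# conserved exactly.
circular_gaussian_smooth <- function(v, sigma_samples) {
  n <- length(v)
  j <- seq_len(n) - 1
  d <- pmin(j, n - j)
  k <- exp(-0.5 * (d / sigma_samples)^2)
  k <- k / sum(k)
  # circular convolution via FFT would be fastest, but n <= a few thousand:
  # do it exactly in the real domain to avoid round-off asymmetry
  idx <- outer(seq_len(n), j, function(i, s) ((i - 1 - s) %% n) + 1)
  as.numeric(matrix(v[idx], n, n) %*% k)
}

#' Match the venous cycle volume to the arterial one
#'
#' Scales the venous waveform by a single factor so that its cycle volume
#' equals the arterial cycle volume (to well below 1e-9 ml), the condition
#' under which the AV difference carries zero net volume and the pump neither
#' fills nor drains the model.
#'
#' @param arterial,venous `csf_waveform`s on the same grid.
#' @return The rescaled venous `csf_waveform`.
#' @export
match_venous_volume <- function(arterial, venous) {
  assert_same_grid(arterial, venous)
  va <- wf_net_volume(arterial)
  vv <- wf_net_volume(venous)
  if (abs(vv) < 1e-12) {
    stop("Cannot match volumes: venous cycle volume is zero.", call. = FALSE)
  }
  out <- venous
  out$flow_ml_min <- venous$flow_ml_min * (va / vv)
  out
}

#' Arteriovenous (AV) flow waveform
#'
#' Pointwise arterial minus venous flow. Under the Monro--Kellie doctrine the
#' rigid cranium forces this net blood volume load to displace CSF, so the AV
#' waveform is the driving flow of the pulsatile pump. Requires the venous
#' waveform to be volume-matched: the result then has exactly zero net cycle
#' volume, and its positive-lobe volume is the AV stroke volume.
#'
#' @param arterial,venous `csf_waveform`s on the same grid, venous
#'   volume-matched (see [match_venous_volume()]).
#' @return A `csf_waveform` (into the cranium positive).
#' @export
av_flow <- function(arterial, venous) {
  assert_same_grid(arterial, venous)
  if (abs(wf_net_volume(arterial) - wf_net_volume(venous)) > 1e-9) {
    stop(
      "Venous waveform is not volume-matched to the arterial one; ",
      "apply match_venous_volume() first.",
      call. = FALSE
    )
  }
  out <- arterial
  out$flow_ml_min <- arterial$flow_ml_min - venous$flow_ml_min
  attr(out, "sign_convention") <- "into_cranium_positive"
  out
}

#' Scale a waveform to a target stroke volume
#'
#' Multiplies all samples by one scalar so that the positive-lobe cycle volume
#' equals `target_sv`. Zero net volume, if present, is preserved (linearity).
#'
#' @param wf A `csf_waveform` with a non-empty positive lobe.
#' @param target_sv Target stroke volume in ml per cycle.
#' @return The rescaled `csf_waveform`.
#' @export
scale_to_stroke_volume <- function(wf, target_sv) {
  sv <- wf_positive_volume(wf)
  if (sv <= 0) {
    stop("Cannot scale: waveform has no positive lobe.", call. = FALSE)
  }
  out <- wf
  out$flow_ml_min <- wf$flow_ml_min * (target_sv / sv)
  out
}

#' Default AV driving waveform
#'
#' Convenience pipeline: [generate_arterial()] with defaults, [derive_venous()],
#' [match_venous_volume()], [av_flow()], then an exact rescale to `target_sv`
#' (0.8 ml, the physiological AV stroke volume into the cranium).
#'
#' @param target_sv AV stroke volume in ml (default 0.8).
#' @param heart_rate_bpm Heart rate; the cycle period is `60/heart_rate_bpm`.
#' @param n_samples Samples per cycle.
#' @return A zero-net-volume `csf_waveform`.
#' @export
av_waveform <- function(target_sv = 0.8, heart_rate_bpm = 70, n_samples = 256) {
  period <- 60 / heart_rate_bpm
  art <- generate_arterial(period = period, n_samples = n_samples)
  ven <- match_venous_volume(art, derive_venous(art))
  scale_to_stroke_volume(av_flow(art, ven), target_sv)
}

#' Resample a waveform to a new sample count
#'
#' Periodic linear interpolation onto a finer or coarser uniform grid.
#'
#' @param wf A `csf_waveform`.
#' @param n_samples New number of samples per cycle (>= 32).
#' @return A `csf_waveform` on the new grid.
#' @export
resample_waveform <- function(wf, n_samples) {
  period <- wf_period(wf)
  v <- wf$flow_ml_min
  n <- length(v)
  t_old <- c(wf$time_s, period)
  v_wrap <- c(v, v[1])
  t_new <- period * (seq_len(n_samples) - 1) / n_samples
  out <- stats::approx(t_old, v_wrap, xout = t_new, method = "linear")$y
  waveform(out, period = period, sign_convention = attr(wf, "sign_convention"))
}
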
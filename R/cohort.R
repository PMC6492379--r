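# Synthetic cardiac-gated cervical CSF flow cohorts (PC-MRI emulation).

#' Template cervical CSF flow waveform
#'
#' A parametric single-cycle cervical (C2--C3) CSF flow curve shaped like
#' cardiac-gated PC-MRI recordings of healthy young adults: an early sharp
#' caudal lobe followed by a broader cranial return, with zero net cycle
#' volume. Lobe amplitudes are iteratively adjusted so that the sampled
#' extrema equal `caudal_max` and `cranial_max` despite lobe overlap; lobe
#' widths then follow from volume balance, giving a stroke volume close to
#' the healthy-cohort value (about 0.39 ml at the defaults).
#'
#' @param caudal_max Caudal (positive) flow maximum, ml/min.
#' @param cranial_max Cranial flow maximum, ml/min (negative).
#' @param caudal_time Time of the caudal peak, s.
#' @param cranial_phase_pct Phase of the cranial peak, percent of the cycle
#'   after the caudal peak (in vivo about 63%).
#' @param sv Target caudal-lobe stroke volume, ml (sets the caudal lobe
#'   width; the cranial width follows from zero net volume).
#' @param period Cycle duration, s.
#' @param n_samples Samples per cycle.
#' @return A `csf_waveform` (caudal positive).
#' @export
#' @examples
#' flow_extrema(template_cervical_flow())
template_cervical_flow <- function(caudal_max = 122.82,
                                   cranial_max = -77.86,
                                   caudal_time = 0.15,
                                   cranial_phase_pct = 63,
                                   sv = 0.385,
                                   period = 60 / 70,
                                   n_samples = 256) {
  if (!(caudal_max > 0 && cranial_max < 0)) {
    stop("`caudal_max` must be positive and `cranial_max` negative.", call. = FALSE)
  }
  t <- period * (seq_len(n_samples) - 1) / n_samples
  t_cr <- (caudal_time + cranial_phase_pct / 100 * period) %% period
  dt <- period / n_samples
  w_ca <- sv * 60 / (caudal_max * sqrt(2 * pi))
  lobe <- function(t0, w) exp(-0.5 * (circ_dist(t, t0, period) / w)^2)
  a_ca <- caudal_max
  a_cr <- -cranial_max
  build <- function() {
    v <- a_ca * lobe(caudal_time, w_ca) - a_cr * lobe(t_cr, a_ca * w_ca / a_cr)
    v - mean(v) # exact zero net volume on the sampled grid
  }
  for (i in 1:12) {
    # fixed point: cranial width from volume balance, lobe amplitudes from
    # the sampled extrema (shifted by lobe overlap), caudal width from the
    # realized stroke volume
    v <- build()
    a_ca <- a_ca * caudal_max / max(v)
    a_cr <- a_cr * cranial_max / min(v)
    w_ca <- w_ca * sv / (sum(pmax(v, 0)) * dt / 60)
  }
  waveform(build(), period = period)
}

#' Cohort specification for synthetic cervical flow subjects
#'
#' Describes a virtual cohort of cardiac-gated cervical flow recordings:
#' a template waveform plus per-subject relative amplitude jitter on the two
#' lobes and timing jitter as a fraction of the cycle. Defaults emulate the
#' spread reported for healthy young volunteers (bidirectional extrema
#' deviations of roughly 20--30% and per-subject timing scatter of a few
#' percent of the cycle).
#'
#' @param n_subjects Number of subjects (>= 1, default 9).
#' @param template A `csf_waveform`; default [template_cervical_flow()].
#' @param amplitude_jitter Relative (Gaussian) SD of each lobe's amplitude.
#' @param phase_jitter SD of the per-subject circular time shift, as a
#'   fraction of the cycle.
#' @param seed Integer seed making the cohort reproducible.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 9,
                        template = template_cervical_flow(),
                        amplitude_jitter = 0.15,
                        phase_jitter = 0.03,
                        seed = 1L) {
  if (n_subjects < 1) stop("`n_subjects` must be at least 1.", call. = FALSE)
  if (amplitude_jitter < 0 || phase_jitter < 0) {
    stop("Jitter parameters must be non-negative.", call. = FALSE)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      template = template,
      amplitude_jitter = amplitude_jitter,
      phase_jitter = phase_jitter,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# run code under a local RNG state (leaves the caller's RNG untouched)
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthesize a cohort of cervical flow waveforms
#'
#' Draws `n_subjects` waveforms around the template: each subject's caudal
#' and cranial lobe amplitudes are scaled by independent factors
#' `1 + N(0, amplitude_jitter)` (positive part is scaled by the caudal
#' factor, negative part by the cranial factor, then the cycle mean is
#' removed to restore zero net volume) and the whole cycle is circularly
#' shifted by `N(0, phase_jitter) * period`. Bitwise reproducible for a
#' given seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `csf_waveform`s of length `n_subjects`.
#' @export
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tmpl <- spec$template
  n <- nrow(tmpl)
  with_local_seed(spec$seed, {
    purrr::map(seq_len(spec$n_subjects), function(i) {
      f_ca <- 1 + stats::rnorm(1, 0, spec$amplitude_jitter)
      f_cr <- 1 + stats::rnorm(1, 0, spec$amplitude_jitter)
      shift <- stats::rnorm(1, 0, spec$phase_jitter)
      f_ca <- max(f_ca, 0.1)
      f_cr <- max(f_cr, 0.1)
      v <- ifelse(tmpl$flow_ml_min >= 0,
        tmpl$flow_ml_min * f_ca,
        tmpl$flow_ml_min * f_cr
      )
      v <- v - mean(v)
      k <- as.integer(round(shift * n)) %% n
      if (k > 0) v <- c(v[(n - k + 1):n], v[1:(n - k)])
      out <- tmpl
      out$flow_ml_min <- v
      out
    })
  })
}

#' Add flow-sensor measurement noise
#'
#' Emulates an ultrasonic transit-time flow sensor: additive zero-mean
#' Gaussian noise whose standard deviation is `accuracy / 2`, reading the
#' manufacturer's accuracy figure as a plus/minus half-width of about two
#' standard deviations. Reproducible per seed.
#'
#' @param wf A `csf_waveform`.
#' @param accuracy Sensor accuracy in ml/min (>= 0); 6 ml/min for the
#'   reference ultrasound sensor.
#' @param seed Integer seed.
#' @return A noisy `csf_waveform`.
#' @export
add_sensor_noise <- function(wf, accuracy = 6, seed = 1L) {
  if (!is.finite(accuracy) || accuracy < 0) {
    stop("`accuracy` must be non-negative.", call. = FALSE)
  }
  if (accuracy == 0) {
    return(wf)
  }
  out <- wf
  with_local_seed(seed, {
    out$flow_ml_min <- wf$flow_ml_min + stats::rnorm(nrow(wf), 0, accuracy / 2)
  })
  out
}
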
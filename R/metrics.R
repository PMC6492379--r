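# Validation metrics: stroke volume, bidirectional extrema, flow timing,
# ICP pulse statistics, cohort comparison.

#' Stroke volume of a flow waveform
#'
#' Integral of the positive (caudal) lobe over one cycle, in ml per cardiac
#' cycle. For a zero-net-volume waveform this equals the magnitude of the
#' negative-lobe volume, so the caudal-lobe definition is used as canonical.
#'
#' @param wf A single-cycle `csf_waveform` (or the cycle-mean of several).
#' @return Stroke volume in ml/CC.
#' @export
#' @examples
#' stroke_volume(av_waveform()) # 0.8
stroke_volume <- function(wf) {
  wf_positive_volume(wf)
}

#' Bidirectional flow extrema
#'
#' Maximum caudally and cranially directed flows of a cycle, in the
#' caudal-positive sign convention (so the cranial maximum is reported as a
#' negative number, as in bidirectional Doppler or PC-MRI tables).
#'
#' @param wf A `csf_waveform`.
#' @return A one-row tibble with `max_caudal` and `max_cranial` (ml/min).
#' @export
flow_extrema <- function(wf) {
  tibble::tibble(
    max_caudal = max(wf$flow_ml_min),
    max_cranial = min(wf$flow_ml_min)
  )
}

#' Phase of the cranial-flow maximum
#'
#' Re-anchors the cycle so the caudal-flow maximum sits at 0% and reports
#' the position of the global flow minimum (the cranially directed maximum)
#' as a percentage of the cycle. Ties in either extremum break to the
#' earliest sample. Returns `NA` (with a warning) for a flat waveform.
#'
#' @param wf A `csf_waveform`.
#' @return Phase in percent of the cardiac cycle, in `[0, 100)`.
#' @export
phase_of_cranial_max <- function(wf) {
  v <- wf$flow_ml_min
  if (diff(range(v)) == 0) {
    warning("Flat waveform: phase of the cranial maximum is undefined.")
    return(NA_real_)
  }
  n <- length(v)
  i_max <- which.max(v) # earliest on ties
  rot <- c(v[i_max:n], v[seq_len(i_max - 1)])
  100 * (which.min(rot) - 1) / n
}

#' Split a recorded series into single-cycle segments
#'
#' Flow and pressure recordings are analyzed per cardiac cycle. For a
#' simulation the exact cycle marks are known; for a measured pressure trace
#' cycles run from ICP minimum to minimum. Each segment is resampled by
#' linear interpolation onto a common 0--100% cycle grid so that envelope
#' and mean-curve statistics can be formed across cycles.
#'
#' @param x Either a `csf_simulation` or a numeric vector / two-column tibble
#'   (`time_s`, value) of a recorded series.
#' @param what For simulations: which column to split, `"icp"` or `"flow"`.
#' @param markers Optional integer sample indices of cycle starts. If
#'   omitted for a plain series, cycle boundaries are detected as local
#'   minima separated by at least `min_sep` samples.
#' @param n_phase Number of points on the common phase grid.
#' @param min_sep Minimum samples between detected minima (default a quarter
#'   of the series length divided by the apparent cycle count).
#' @return A tibble with columns `cycle`, `phase_pct`, `value`.
#' @export
cycle_split <- function(x, what = c("icp", "flow"), markers = NULL,
                        n_phase = 201, min_sep = NULL) {
  what <- match.arg(what)
  if (inherits(x, "csf_simulation")) {
    v <- if (what == "icp") x$icp_mmHg else x$q_spinal_ml_min
    markers <- attr(x, "cycle_marks")
    segments <- split_by_markers(v, markers, wrap = TRUE)
  } else {
    v <- if (is.numeric(x)) x else x[[2]]
    if (is.null(markers)) {
      markers <- detect_minima(v, min_sep = min_sep)
      if (length(markers) < 2) {
        stop("Cannot split: fewer than two cycle minima detected.", call. = FALSE)
      }
      segments <- split_by_markers(v, markers, wrap = FALSE)
    } else {
      if (length(markers) < 2) {
        stop("Cannot split: need at least two cycle markers.", call. = FALSE)
      }
      segments <- split_by_markers(v, markers, wrap = FALSE)
    }
  }
  phase <- seq(0, 100, length.out = n_phase)
  purrr::imap_dfr(segments, function(seg, i) {
    m <- length(seg)
    tibble::tibble(
      cycle = as.integer(i),
      phase_pct = phase,
      value = stats::approx(
        x = 100 * (seq_len(m) - 1) / (m - 1), y = seg,
        xout = phase
      )$y
    )
  })
}

# segments between successive markers; wrap = TRUE treats the series as
# exactly tiled cycles (simulation) and closes each segment with the next
# cycle's first sample
split_by_markers <- function(v, markers, wrap = FALSE) {
  n <- length(v)
  bounds <- c(markers, if (wrap) n + 1 else NULL)
  out <- list()
  for (i in seq_len(length(bounds) - 1)) {
    hi <- bounds[i + 1]
    seg <- v[bounds[i]:min(hi - 1, n)]
    if (wrap) seg <- c(seg, v[if (hi > n) 1 else hi]) # close the cycle
    out[[i]] <- seg
  }
  out
}

# merge neighboring extrema separated by a barrier of insufficient
# prominence, keeping the stronger one; `maxima = FALSE` prunes minima
prune_extrema <- function(v, idx, thresh, maxima = TRUE) {
  if (length(idx) < 2) {
    return(idx)
  }
  sgn <- if (maxima) 1 else -1
  keep <- idx[1]
  for (i in idx[-1]) {
    last <- keep[length(keep)]
    barrier <- min(v[last:i] * sgn)
    prom <- min(v[last] * sgn, v[i] * sgn) - barrier
    if (prom < thresh) {
      if (v[i] * sgn > v[last] * sgn) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  keep
}

# local minima with prominence filtering (5% of the trace range) and a
# minimum separation; returns indices
detect_minima <- function(v, min_sep = NULL) {
  n <- length(v)
  cand <- which(diff(sign(diff(v))) > 0) + 1
  cand <- prune_extrema(v, cand, thresh = 0.05 * diff(range(v)), maxima = FALSE)
  if (is.null(min_sep)) min_sep <- max(3, floor(n / (2 * max(1, length(cand)))))
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 || i - keep[length(keep)] >= min_sep) {
      keep <- c(keep, i)
    } else if (v[i] < v[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  keep
}

#' ICP pulse statistics
#'
#' Computes, from per-cycle ICP segments (see [cycle_split()]):
#' the arithmetic mean over all samples, the global maximum and minimum, the
#' largest cycle-to-cycle spread of the per-cycle extrema, and — on the mean
#' cycle curve — the mean wave amplitude (MWA, height of the first pulse
#' peak above the cycle-start minimum) and the P2:P1 ratio of the first two
#' pulse peaks' heights. Peaks are located after moving-average smoothing
#' with a window of 5% of the cycle, and peaks whose prominence is below 5%
#' of the pulse range are treated as ripple and ignored; if fewer than one
#' (two) peaks remain, `mwa` (`p2_to_p1`) is `NA`.
#'
#' @param segments A tibble from [cycle_split()] (columns `cycle`,
#'   `phase_pct`, `value`).
#' @return A one-row tibble: `mean_icp`, `max_icp`, `min_icp`, `mwa`,
#'   `p2_to_p1`, `extrema_spread`, `n_cycles` (pressures in mmHg).
#' @export
icp_stats <- function(segments) {
  stopifnot(all(c("cycle", "phase_pct", "value") %in% names(segments)))
  per_cycle <- dplyr::summarise(
    dplyr::group_by(segments, .data$cycle),
    cyc_max = max(.data$value), cyc_min = min(.data$value),
    .groups = "drop"
  )
  mean_curve <- dplyr::summarise(
    dplyr::group_by(segments, .data$phase_pct),
    value = mean(.data$value),
    .groups = "drop"
  )
  v <- mean_curve$value
  base_min <- v[1]
  win <- max(3, round(0.05 * length(v)))
  if (win %% 2 == 0) win <- win + 1
  vs <- as.numeric(stats::filter(v, rep(1 / win, win), sides = 2, circular = TRUE))
  peaks <- which(diff(sign(diff(vs))) < 0) + 1
  peaks <- peaks[vs[peaks] > base_min]
  rng <- diff(range(vs))
  if (rng > 0) peaks <- prune_extrema(vs, peaks, thresh = 0.05 * rng)
  mwa <- if (length(peaks) >= 1) v[peaks[1]] - base_min else NA_real_
  p2p1 <- if (length(peaks) >= 2) {
    (v[peaks[2]] - base_min) / (v[peaks[1]] - base_min)
  } else {
    NA_real_
  }
  tibble::tibble(
    mean_icp = mean(segments$value),
    max_icp = max(segments$value),
    min_icp = min(segments$value),
    mwa = mwa,
    p2_to_p1 = p2p1,
    extrema_spread = max(
      diff(range(per_cycle$cyc_max)),
      diff(range(per_cycle$cyc_min))
    ),
    n_cycles = nrow(per_cycle)
  )
}

#' Flow metrics of a recording
#'
#' Summary statistics of a single-cycle (or cycle-mean) cervical flow
#' waveform: stroke volume, bidirectional extrema and the phase of the
#' cranial-flow maximum.
#'
#' @param wf A `csf_waveform`.
#' @return A one-row tibble: `sv_ml`, `max_caudal`, `max_cranial`,
#'   `phase_cranial_max_pct`.
#' @export
flow_metrics <- function(wf) {
  ex <- flow_extrema(wf)
  tibble::tibble(
    sv_ml = stroke_volume(wf),
    max_caudal = ex$max_caudal,
    max_cranial = ex$max_cranial,
    phase_cranial_max_pct = phase_of_cranial_max(wf)
  )
}

#' Per-cycle flow envelope
#'
#' Min/mean/max flow across cycles on a common phase grid (the analogue of a
#' shaded-range flow plot over repeated cycles).
#'
#' @param sim A `csf_simulation`.
#' @param n_phase Points on the phase grid.
#' @return A tibble with `phase_pct`, `q_min`, `q_mean`, `q_max` (ml/min).
#' @export
cycle_envelope <- function(sim, n_phase = 201) {
  seg <- cycle_split(sim, what = "flow", n_phase = n_phase)
  dplyr::summarise(
    dplyr::group_by(seg, .data$phase_pct),
    q_min = min(.data$value),
    q_mean = mean(.data$value),
    q_max = max(.data$value),
    .groups = "drop"
  )
}

#' Compare a flow recording against a reference cohort
#'
#' Per-metric differences between one recording (e.g. the simulated twin)
#' and a cohort of reference recordings (e.g. synthetic PC-MRI subjects):
#' recording value, cohort mean and min--max envelope, difference from the
#' mean, and an envelope-membership flag. The row
#' `phase_cranial_max_pct` doubles as the timing offset `dt` between the
#' recording's and the cohort's cranial-flow maxima.
#'
#' @param recording A one-row tibble from [flow_metrics()].
#' @param cohort A tibble of cohort metrics (one row per subject, same
#'   columns), or a list of `csf_waveform`s to be summarized first.
#' @return A tibble with one row per metric: `metric`, `recording`,
#'   `cohort_mean`, `cohort_min`, `cohort_max`, `diff`, `within_envelope`.
#' @export
compare_flow <- function(recording, cohort) {
  if (is.list(cohort) && !is.data.frame(cohort)) {
    cohort <- purrr::map_dfr(cohort, flow_metrics)
  }
  if (nrow(cohort) == 0) stop("Reference cohort is empty.", call. = FALSE)
  long_rec <- tidyr::pivot_longer(recording,
    cols = dplyr::everything(),
    names_to = "metric", values_to = "recording"
  )
  long_coh <- tidyr::pivot_longer(cohort,
    cols = dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
  coh_sum <- dplyr::summarise(
    dplyr::group_by(long_coh, .data$metric),
    cohort_mean = mean(.data$value),
    cohort_min = min(.data$value),
    cohort_max = max(.data$value),
    .groups = "drop"
  )
  out <- dplyr::left_join(long_rec, coh_sum, by = "metric")
  dplyr::mutate(out,
    diff = .data$recording - .data$cohort_mean,
    within_envelope = .data$recording >= .data$cohort_min &
      .data$recording <= .data$cohort_max
  )
}
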
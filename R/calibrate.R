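# Valve-resistance calibration against target spinal-flow extrema.

#' Calibrate valve resistances against spinal-flow extrema
#'
#' The bench's two adjustable valves were tuned by hand until the measured
#' spinal flow matched the physiological picture; their settings are not part
#' of the published record. This routine recovers resistances by a bounded,
#' deterministic least-squares fit: an 8x8 log-spaced grid scan over both
#' resistances followed by a Nelder--Mead refinement in log space, minimizing
#' the summed squared relative mismatch between the simulated spinal-flow
#' extrema and the supplied targets.
#'
#' Note on identifiability: the valve-1 path and valve 2 connect the same two
#' network nodes, so the spinal-flow dynamics depend on the two resistances
#' only through their parallel combination `R_par`. The fit is therefore
#' well-determined in `R_par` but degenerate along the split between the two
#' valves; `R_par` is the quantity to compare across runs (exposed in
#' [tidy.csf_calibration()] output and in `$r_parallel`).
#'
#' @param net A `csf_network`; its valve resistances serve as bounds' context
#'   only, the fit starts from the grid scan.
#' @param pump A zero-net-volume driving `csf_waveform`.
#' @param target_caudal_max Target maximum caudal spinal flow, ml/min (> 0).
#' @param target_cranial_max Target maximum cranial spinal flow, ml/min
#'   (< 0 by the caudal-positive convention).
#' @param bounds Length-2 lower/upper bounds on each resistance,
#'   mmHg/(ml/min).
#' @param n_grid Grid points per axis in the initial scan.
#' @param tol_rel Relative tolerance on each extremum below which the fit is
#'   declared converged. A fit that stays above it returns normally with
#'   `converged = FALSE` and the residuals (not an error).
#' @param fit_cycles,fit_divisor Reduced simulation settings used inside the
#'   objective (the final reported extrema always come from a full-resolution
#'   run at the network's own `sim` settings).
#' @return A `csf_calibration` object: fitted resistances (`r_valve1_path`,
#'   `r_valve2`, `r_parallel`), achieved full-resolution extrema, relative
#'   residuals, `converged`, the updated network in `$network`, and the
#'   objective evaluation count. Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
calibrate_resistances <- function(net, pump,
                                  target_caudal_max,
                                  target_cranial_max,
                                  bounds = c(1e-4, 1),
                                  n_grid = 8,
                                  tol_rel = 0.05,
                                  fit_cycles = 2,
                                  fit_divisor = 512) {
  if (!(target_caudal_max > 0 && target_cranial_max < 0)) {
    stop(
      "Targets must have opposite signs: caudal maximum positive, ",
      "cranial maximum negative (caudal-positive convention).",
      call. = FALSE
    )
  }
  n_eval <- 0L
  extrema_for <- function(r1, r2, full = FALSE) {
    net2 <- net
    net2$r_valve1_path <- r1
    net2$r_valve2 <- r2
    sim <- if (full) {
      simulate_network(net2, pump)
    } else {
      simulate_network(net2, pump,
        n_cycles = fit_cycles, warmup_cycles = 2,
        dt = wf_period(pump) / fit_divisor
      )
    }
    q <- cycle_mean_flow(sim)$flow_ml_min
    c(max(q), min(q))
  }
  objective <- function(logr) {
    n_eval <<- n_eval + 1L
    ex <- extrema_for(exp(logr[1]), exp(logr[2]))
    ((ex[1] - target_caudal_max) / target_caudal_max)^2 +
      ((ex[2] - target_cranial_max) / target_cranial_max)^2
  }

  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_grid))
  scan <- expand.grid(r1 = grid, r2 = grid)
  scan$obj <- vapply(
    seq_len(nrow(scan)),
    function(i) objective(log(c(scan$r1[i], scan$r2[i]))),
    numeric(1)
  )
  best <- scan[which.min(scan$obj), ]

  fit <- stats::optim(
    par = log(c(best$r1, best$r2)),
    fn = objective,
    method = "Nelder-Mead",
    control = list(maxit = 400, reltol = 1e-10)
  )
  r_fit <- pmin(pmax(exp(fit$par), bounds[1]), bounds[2])

  achieved <- extrema_for(r_fit[1], r_fit[2], full = TRUE)
  resid <- c(
    caudal = (achieved[1] - target_caudal_max) / target_caudal_max,
    cranial = (achieved[2] - target_cranial_max) / target_cranial_max
  )
  net_out <- net
  net_out$r_valve1_path <- r_fit[1]
  net_out$r_valve2 <- r_fit[2]
  structure(
    list(
      r_valve1_path = r_fit[1],
      r_valve2 = r_fit[2],
      r_parallel = 1 / (1 / r_fit[1] + 1 / r_fit[2]),
      achieved = c(max_caudal = achieved[1], max_cranial = achieved[2]),
      targets = c(
        max_caudal = target_caudal_max,
        max_cranial = target_cranial_max
      ),
      residual_rel = resid,
      converged = all(abs(resid) <= tol_rel),
      tol_rel = tol_rel,
      n_eval = n_eval,
      network = net_out
    ),
    class = "csf_calibration"
  )
}

#' @export
print.csf_calibration <- function(x, ...) {
  cat("<csf_calibration>\n")
  cat(sprintf(
    "  R parallel = %.5g mmHg/(ml/min)  [valve-1 path %.5g | valve 2 %.5g]\n",
    x$r_parallel, x$r_valve1_path, x$r_valve2
  ))
  cat(sprintf(
    "  extrema achieved: %.2f / %.2f ml/min (targets %.2f / %.2f)\n",
    x$achieved[1], x$achieved[2], x$targets[1], x$targets[2]
  ))
  cat(sprintf(
    "  residuals: %+.2f%% / %+.2f%%; converged: %s (%d objective evaluations)\n",
    100 * x$residual_rel[1], 100 * x$residual_rel[2], x$converged, x$n_eval
  ))
  invisible(x)
}

#' Tidy a valve calibration
#'
#' @param x A `csf_calibration`.
#' @param ... Unused.
#' @return `tidy()`: one row per fitted quantity with columns `term` and
#'   `estimate` (mmHg per ml/min). `glance()`: a one-row fit summary.
#' @exportS3Method generics::tidy
tidy.csf_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("r_valve1_path", "r_valve2", "r_parallel"),
    estimate = c(x$r_valve1_path, x$r_valve2, x$r_parallel)
  )
}

#' @rdname tidy.csf_calibration
#' @exportS3Method generics::glance
glance.csf_calibration <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    max_caudal = unname(x$achieved[1]),
    max_cranial = unname(x$achieved[2]),
    target_caudal = unname(x$targets[1]),
    target_cranial = unname(x$targets[2]),
    resid_caudal_rel = unname(x$residual_rel[1]),
    resid_cranial_rel = unname(x$residual_rel[2]),
    n_eval = x$n_eval
  )
}
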
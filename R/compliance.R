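# Static air-chamber compliance: isentropic gas law and chamber sizing.

#' Atmospheric reference pressure (mmHg)
#'
#' Gas-law computations run on absolute pressures; measured and reported
#' craniospinal pressures are gauge. `MMHG_ATM` is the conversion offset.
#' @export
MMHG_ATM <- 760

#' Air-chamber compliance element
#'
#' A sealed chamber partly filled with trapped air above the working fluid.
#' For an adiabatic (isentropic) compression of an ideal gas,
#' `p0 * V0^lam = p * V^lam`, so the chamber presents a pressure-dependent
#' compliance `C(p) = (1/lam) * p0^(1/lam) * V0 * p^(-(1+lam)/lam)` to the
#' liquid side. All pressures here are absolute.
#'
#' @param v0_air Initial (reference-state) air volume, ml; > 0.
#' @param p0_abs Absolute pressure at the reference state, mmHg; > 0.
#' @param lam Isentropic exponent, dimensionless, in `[1, 1.67]`; 1.4 for air
#'   under adiabatic pulsation, 1 in the isothermal (slow) limit.
#' @return An `air_chamber` object.
#' @export
#' @examples
#' ch <- air_chamber(v0_air = 335.3, p0_abs = 760 + 12.68)
#' compliance_at(ch, 760 + 12.68)
air_chamber <- function(v0_air, p0_abs, lam = 1.4) {
  if (!is.finite(v0_air) || v0_air <= 0) {
    stop("`v0_air` must be a positive air volume in ml.", call. = FALSE)
  }
  if (!is.finite(p0_abs) || p0_abs <= 0) {
    stop("`p0_abs` must be a positive absolute pressure in mmHg.", call. = FALSE)
  }
  if (!is.finite(lam) || lam < 1 || lam > 1.67) {
    stop("`lam` must lie in [1, 1.67].", call. = FALSE)
  }
  structure(
    list(v0_air = v0_air, p0_abs = p0_abs, lam = lam),
    class = "air_chamber"
  )
}

#' @export
print.air_chamber <- function(x, ...) {
  cat(sprintf(
    "<air_chamber: V0 = %.4g ml air at p0 = %.5g mmHg abs, lambda = %.3g; C(p0) = %.4g ml/mmHg>\n",
    x$v0_air, x$p0_abs, x$lam, compliance_at(x, x$p0_abs)
  ))
  invisible(x)
}

#' Absolute chamber pressure at a given air volume
#'
#' Evaluates the isentropic invariant `p = p0 * (V0 / V)^lam` (log-domain for
#' numerical robustness at large exponent arguments).
#'
#' @param ch An [air_chamber()].
#' @param v_air Current air volume, ml; > 0. Vectorized.
#' @return Absolute pressure(s), mmHg.
#' @export
chamber_pressure <- function(ch, v_air) {
  if (any(!is.finite(v_air)) || any(v_air <= 0)) {
    stop("Air volume must stay positive: the chamber would be flooded.", call. = FALSE)
  }
  exp(log(ch$p0_abs) + ch$lam * (log(ch$v0_air) - log(v_air)))
}

#' Air volume at a given absolute chamber pressure
#'
#' Inverse of [chamber_pressure()]: `V = V0 * (p0 / p)^(1/lam)`.
#'
#' @inheritParams chamber_pressure
#' @param p_abs Absolute pressure(s), mmHg; > 0.
#' @return Air volume(s), ml.
#' @export
chamber_volume <- function(ch, p_abs) {
  if (any(!is.finite(p_abs)) || any(p_abs <= 0)) {
    stop("Absolute pressure must be positive.", call. = FALSE)
  }
  exp(log(ch$v0_air) + (log(ch$p0_abs) - log(p_abs)) / ch$lam)
}

#' Chamber compliance at an operating pressure
#'
#' `C(p1) = (1/lam) * p0^(1/lam) * V0 * p1^(-(1+lam)/lam)`, the (negative of
#' the) derivative of air volume with respect to pressure — equivalently the
#' liquid volume stored per unit pressure rise. At the reference state this
#' collapses to `C(p0) = V0 / (lam * p0)`.
#'
#' @inheritParams chamber_pressure
#' @param p1_abs Absolute operating pressure(s), mmHg; > 0. Vectorized.
#' @return Compliance(s) in ml/mmHg.
#' @export
compliance_at <- function(ch, p1_abs) {
  if (any(!is.finite(p1_abs)) || any(p1_abs <= 0)) {
    stop("Absolute pressure must be positive.", call. = FALSE)
  }
  (1 / ch$lam) * ch$p0_abs^(1 / ch$lam) * ch$v0_air * p1_abs^(-(1 + ch$lam) / ch$lam)
}

#' Size a chamber's air volume for a target compliance
#'
#' The bench adjusts each compartment's compliance solely through the initial
#' trapped-air volume. Inverting `C(p_op) = V0 / (lam * p_op)` for a chamber
#' referenced at its operating pressure gives `V0 = C * lam * p_op`.
#'
#' @param c_target Target compliance, ml/mmHg; > 0.
#' @param p_op_abs Absolute operating pressure, mmHg; > 0.
#' @param lam Isentropic exponent.
#' @return Initial air volume V0 in ml.
#' @export
#' @examples
#' size_air_volume(0.31, 760 + 12.68) # cranial chamber, ~335 ml of air
size_air_volume <- function(c_target, p_op_abs, lam = 1.4) {
  if (!is.finite(c_target) || c_target <= 0) {
    stop("`c_target` must be a positive compliance in ml/mmHg.", call. = FALSE)
  }
  if (!is.finite(p_op_abs) || p_op_abs <= 0) {
    stop("`p_op_abs` must be a positive absolute pressure.", call. = FALSE)
  }
  c_target * lam * p_op_abs
}

# round-half-up at 0 decimals (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Craniospinal compliance budget
#'
#' Sums compartment compliances (`C_total = sum(C_i)`, e.g. cranial + spinal)
#' and reports each compartment's percentage share, rounded half-up to whole
#' percent. Shares are always computed from the values; printed distributions
#' in the literature occasionally disagree with their own values, and this
#' function will flag (via a `share_note` attribute) any set of rounded
#' shares that does not sum to 100.
#'
#' @param parts Named or unnamed numeric vector (or list) of compartment
#'   compliances in ml/mmHg, all positive.
#' @return A tibble with columns `compartment`, `c_ml_per_mmHg`, `share_pct`,
#'   with the total compliance in attribute `c_total` (also printed).
#' @export
#' @examples
#' total_compliance(c(cranial = 0.31, spinal = 0.84))
total_compliance <- function(parts) {
  parts <- unlist(parts)
  if (length(parts) == 0) {
    stop("Need at least one compartment compliance.", call. = FALSE)
  }
  if (any(!is.finite(parts)) || any(parts <= 0)) {
    stop("All compartment compliances must be positive.", call. = FALSE)
  }
  nm <- names(parts)
  if (is.null(nm)) nm <- paste0("compartment_", seq_along(parts))
  total <- sum(parts)
  shares <- round_half_up(100 * parts / total)
  out <- tibble::tibble(
    compartment = nm,
    c_ml_per_mmHg = as.numeric(parts),
    share_pct = as.numeric(shares)
  )
  attr(out, "c_total") <- total
  if (sum(shares) != 100) {
    attr(out, "share_note") <- sprintf(
      "rounded shares sum to %d%%, not 100%%", sum(shares)
    )
  }
  out
}
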
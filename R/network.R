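# Hydraulic network: topology, canal resistance, assembly, equilibrium state.
#
# Fixed topology (pump-driven four-node network):
#
#   pump --> N1 (cranial compliance chamber)
#   N1 --> N2 --> N3   valve-1 path: valve 1 in series with the aqueduct /
#                      parenchyma path; the ICP sensor sits at N2
#   N1 --> N3          valve 2 (resistance of the cranial SAS)
#   N3 --> N4          spinal canal (series Poiseuille segments);
#                      N4 carries the spinal compliance chamber
#
# N3 is the cistern node; the spinal flow is tapped in the first canal
# segment (C2--C3 level equivalent).

#' Spinal canal segments
#'
#' Builds a tibble of canal segments. The spinal subarachnoid space is an
#' annular channel whose hydraulic diameter varies along the canal between
#' roughly 5 and 15 mm; the model represents it as a series of circular ducts
#' with those hydraulic diameters. The default three-segment canal spans a
#' characteristic anatomical length of 60 cm, narrowest (most resistive) in
#' its distal portion.
#'
#' @param length_mm Segment lengths, mm; > 0.
#' @param diameter_mm Hydraulic diameters, mm; within the physiological 5--15
#'   mm range for defaults, any positive value accepted.
#' @param viscosity_mPa_s Dynamic viscosity of the working fluid, mPa*s
#'   (1.0 for water, a faithful CSF surrogate).
#' @return A tibble with one row per segment and a `r_mmHg_per_ml_min` column.
#' @export
canal_segments <- function(length_mm = c(200, 250, 150),
                           diameter_mm = c(15, 10, 5),
                           viscosity_mPa_s = 1.0) {
  if (length(length_mm) != length(diameter_mm)) {
    stop("`length_mm` and `diameter_mm` must have equal length.", call. = FALSE)
  }
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop("Segment lengths must be positive.", call. = FALSE)
  }
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0)) {
    stop("Hydraulic diameters must be positive.", call. = FALSE)
  }
  seg <- tibble::tibble(
    length_mm = as.numeric(length_mm),
    diameter_mm = as.numeric(diameter_mm),
    viscosity_mPa_s = viscosity_mPa_s
  )
  seg$r_mmHg_per_ml_min <- poiseuille_resistance(seg)
  seg
}

#' Hagen--Poiseuille resistance of canal segments
#'
#' Laminar fully-developed flow resistance `R = 128 mu L / (pi d^4)`,
#' converted from SI to the model's working units, mmHg per (ml/min). Peak
#' Reynolds numbers in the canal stay in the laminar range (about 500--700 at
#' 134 ml/min in a 5 mm duct), so no turbulent or entrance-loss corrections
#' are applied.
#'
#' @param seg A tibble from [canal_segments()] (columns `length_mm`,
#'   `diameter_mm`, `viscosity_mPa_s`).
#' @return Numeric vector of resistances, mmHg/(ml/min).
#' @export
poiseuille_resistance <- function(seg) {
  mu <- seg$viscosity_mPa_s * 1e-3 # Pa s
  len <- seg$length_mm * 1e-3 # m
  d <- seg$diameter_mm * 1e-3 # m
  r_si <- 128 * mu * len / (pi * d^4) # Pa / (m^3/s)
  # 1 ml/min = 1e-6/60 m^3/s; 1 mmHg = 133.322387415 Pa
  r_si * (1e-6 / 60) / 133.322387415
}

#' Assemble the craniospinal hydraulic network
#'
#' Builds a `csf_network` from a validated configuration (see
#' [default_config()]). Chambers given as compliance targets are sized via
#' [size_air_volume()] at the baseline operating pressure; chambers given as
#' air volumes are taken as-is. Both valve resistances must be positive
#' (each parallel cranial path needs finite resistance, otherwise the cistern
#' node would short-circuit).
#'
#' @param config A configuration list, e.g. from [default_config()] or
#'   [load_config()]; partial lists are completed with defaults.
#' @return A `csf_network` object.
#' @export
#' @examples
#' net <- assemble(default_config())
assemble <- function(config = default_config()) {
  cfg <- validate_config(config)
  p_op_abs <- MMHG_ATM + cfg$baseline_icp_mmHg
  mk_chamber <- function(ch, label) {
    has_v <- !is.null(ch$v0_air_ml)
    has_c <- !is.null(ch$c_target_ml_per_mmHg)
    if (has_v && has_c) {
      stop(sprintf(
        "Chamber '%s': give either v0_air_ml or c_target_ml_per_mmHg, not both.",
        label
      ), call. = FALSE)
    }
    if (!has_v && !has_c) {
      stop(sprintf("Chamber '%s': no size given.", label), call. = FALSE)
    }
    v0 <- if (has_v) ch$v0_air_ml else size_air_volume(ch$c_target_ml_per_mmHg, p_op_abs, ch$lambda)
    air_chamber(v0_air = v0, p0_abs = p_op_abs, lam = ch$lambda)
  }
  canal <- canal_segments(
    length_mm = cfg$canal$segments$length_mm,
    diameter_mm = cfg$canal$segments$diameter_mm,
    viscosity_mPa_s = cfg$canal$viscosity_mPa_s
  )
  r_canal <- sum(canal$r_mmHg_per_ml_min)
  if (r_canal <= 0) stop("Total canal resistance must be positive.", call. = FALSE)
  if (cfg$valves$r_valve1_path_mmHg_per_ml_min <= 0 ||
    cfg$valves$r_valve2_mmHg_per_ml_min <= 0) {
    stop("Valve resistances must be positive (no zero-resistance loop).", call. = FALSE)
  }
  structure(
    list(
      cranial_chamber = mk_chamber(cfg$chambers$cranial, "cranial"),
      spinal_chamber = mk_chamber(cfg$chambers$spinal, "spinal"),
      r_valve1_path = cfg$valves$r_valve1_path_mmHg_per_ml_min,
      r_valve2 = cfg$valves$r_valve2_mmHg_per_ml_min,
      valve1_fraction = cfg$valves$valve1_fraction,
      canal = canal,
      r_canal = r_canal,
      baseline_icp_mmHg = cfg$baseline_icp_mmHg,
      heart_rate_bpm = cfg$heart_rate_bpm,
      sim = cfg$sim
    ),
    class = "csf_network"
  )
}

#' @export
print.csf_network <- function(x, ...) {
  cc <- compliance_at(x$cranial_chamber, x$cranial_chamber$p0_abs)
  cs <- compliance_at(x$spinal_chamber, x$spinal_chamber$p0_abs)
  cat("<csf_network>\n")
  cat(sprintf(
    "  chambers: cranial C = %.3g, spinal C = %.3g ml/mmHg at baseline %.4g mmHg\n",
    cc, cs, x$baseline_icp_mmHg
  ))
  cat(sprintf(
    "  valves: R_v1 path = %.4g, R_v2 = %.4g mmHg/(ml/min); canal R = %.4g over %d segments\n",
    x$r_valve1_path, x$r_valve2, x$r_canal, nrow(x$canal)
  ))
  invisible(x)
}

#' Baseline operating point of the network
#'
#' The equilibrium state: every node pressure equals the configured baseline
#' ICP (gauge), both chamber air volumes are consistent with that pressure,
#' and all flows vanish. Simulations start from this state.
#'
#' @param net A `csf_network`.
#' @return A list with `p_gauge_mmHg`, `v_air_cranial_ml`, `v_air_spinal_ml`,
#'   and `q_ml_min` (all zero flows).
#' @export
operating_point <- function(net) {
  p_abs <- MMHG_ATM + net$baseline_icp_mmHg
  list(
    p_gauge_mmHg = net$baseline_icp_mmHg,
    v_air_cranial_ml = chamber_volume(net$cranial_chamber, p_abs),
    v_air_spinal_ml = chamber_volume(net$spinal_chamber, p_abs),
    q_ml_min = c(valve1_path = 0, valve2 = 0, spinal = 0)
  )
}
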
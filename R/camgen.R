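# Cam-disc synthesis: from a pump flow waveform to a polar cam contour.

#' Piston displacement profile for a flow waveform
#'
#' Maps one flow cycle onto one cam revolution: the piston displacement at
#' cam angle `theta = 2 pi t / period` is the cumulative displaced volume
#' divided by the piston area, normalized so its minimum is zero. The
#' cumulative volume is formed with the trapezoidal rule, whose central
#' difference returns the original flow samples to second order (see
#' [profile_to_flow()]). The waveform must carry zero net cycle volume,
#' otherwise the profile would not close after a revolution.
#'
#' @param pump A zero-net-volume `csf_waveform`.
#' @param piston_area Piston cross-section in mm^2; default a 9 mm bore
#'   (2 ml syringe class), `pi * 4.5^2`.
#' @return A tibble with `theta_rad` (uniform on `[0, 2 pi)`) and `x_mm`.
#' @export
#' @examples
#' disp <- displacement_profile(av_waveform())
#' max(disp$x_mm) # about 12.6 mm of lift for 0.8 ml over 63.6 mm^2
displacement_profile <- function(pump, piston_area = pi * 4.5^2) {
  if (!is.finite(piston_area) || piston_area <= 0) {
    stop("`piston_area` must be positive (mm^2).", call. = FALSE)
  }
  if (abs(wf_net_volume(pump)) > 1e-6) {
    stop(
      "Open cam profile: the waveform's net cycle volume is not zero, ",
      "so the contour would not close after one revolution.",
      call. = FALSE
    )
  }
  v <- pump$flow_ml_min
  n <- length(v)
  dt <- wf_dt(pump)
  # cumulative trapezoid, ml -> mm^3 (1 ml = 1000 mm^3), min -> s
  cum_ml <- (dt / 60) * (cumsum(v) - v / 2 - v[1] / 2)
  x <- cum_ml * 1000 / piston_area
  x <- x - min(x)
  structure(
    tibble::tibble(
      theta_rad = 2 * pi * (seq_len(n) - 1) / n,
      x_mm = x
    ),
    piston_area = piston_area,
    period = wf_period(pump)
  )
}

#' Cam contour from a displacement profile
#'
#' Radial knife-edge follower model: the cam radius at angle `theta` is the
#' base-circle radius plus the piston displacement, `r = base_radius + x`.
#' Roller-radius compensation is deliberately not applied (the follower is
#' idealized as a knife edge); `roller_radius` is accepted as a hook and
#' must currently be zero.
#'
#' @param x A displacement tibble from [displacement_profile()].
#' @param base_radius Base-circle radius in mm (> 0).
#' @param roller_radius Must be 0; reserved for a future roller-offset
#'   correction.
#' @return A `csf_cam_profile` tibble with `theta_rad`, `r_mm`, `x_mm`,
#'   `y_mm` (Cartesian contour), and attributes `base_radius`,
#'   `piston_area`, `period`.
#' @export
cam_profile <- function(x, base_radius = 20, roller_radius = 0) {
  if (!is.finite(base_radius) || base_radius <= 0) {
    stop("`base_radius` must be positive (mm).", call. = FALSE)
  }
  if (roller_radius != 0) {
    stop("Roller-radius compensation is not implemented; use 0.", call. = FALSE)
  }
  r <- base_radius + x$x_mm
  out <- tibble::tibble(
    theta_rad = x$theta_rad,
    r_mm = r,
    x_mm = r * cos(x$theta_rad),
    y_mm = r * sin(x$theta_rad)
  )
  structure(
    out,
    base_radius = base_radius,
    piston_area = attr(x, "piston_area"),
    period = attr(x, "period"),
    class = c("csf_cam_profile", class(tibble::tibble()))
  )
}

#' Export / import a cam profile as CSV
#'
#' Writes `theta_rad,r_mm,x_mm,y_mm` rows at full double precision, preceded
#' by `#`-prefixed metadata lines (base radius, piston area, cycle period,
#' stroke volume). Export followed by import reproduces the radii bitwise.
#'
#' @param p A `csf_cam_profile`.
#' @param path Output file path.
#' @return `export_profile()` returns `path` invisibly; `read_cam_profile()`
#'   returns the `csf_cam_profile`.
#' @export
export_profile <- function(p, path) {
  sv_ml <- (max(p$r_mm) - attr(p, "base_radius")) * attr(p, "piston_area") / 1000
  header <- c(
    sprintf("# cam profile: %d samples, one revolution per cardiac cycle", nrow(p)),
    sprintf("# base_radius_mm=%.17g", attr(p, "base_radius")),
    sprintf("# piston_area_mm2=%.17g", attr(p, "piston_area")),
    sprintf("# period_s=%.17g", attr(p, "period")),
    sprintf("# peak_lift_ml=%.17g", sv_ml),
    "theta_rad,r_mm,x_mm,y_mm"
  )
  rows <- sprintf(
    "%.17g,%.17g,%.17g,%.17g",
    p$theta_rad, p$r_mm, p$x_mm, p$y_mm
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' @rdname export_profile
#' @export
read_cam_profile <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    ln <- meta[grepl(paste0("# ", key, "="), meta, fixed = TRUE)]
    if (length(ln) != 1) stop("Missing cam metadata: ", key, call. = FALSE)
    as.numeric(sub(paste0("# ", key, "="), "", ln, fixed = TRUE))
  }
  body <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  structure(
    tibble::as_tibble(body),
    base_radius = get_meta("base_radius_mm"),
    piston_area = get_meta("piston_area_mm2"),
    period = get_meta("period_s"),
    class = c("csf_cam_profile", class(tibble::tibble()))
  )
}

#' Recover the flow waveform encoded by a cam profile
#'
#' Inverse of the displacement mapping: differentiates the lift
#' `r - base_radius` with central differences at the configured rotation
#' speed (one revolution per cycle) and converts back to ml/min. Used as the
#' round-trip check that a manufactured contour reproduces its target flow.
#'
#' @param p A `csf_cam_profile`.
#' @return A `csf_waveform`.
#' @export
profile_to_flow <- function(p) {
  period <- attr(p, "period")
  lift <- p$r_mm - attr(p, "base_radius")
  n <- length(lift)
  dt <- period / n
  nxt <- c(lift[-1], lift[1])
  prv <- c(lift[n], lift[-n])
  dxdt <- (nxt - prv) / (2 * dt) # mm/s
  q <- dxdt * attr(p, "piston_area") / 1000 * 60 # ml/min
  waveform(q, period = period, sign_convention = "into_cranium_positive")
}
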
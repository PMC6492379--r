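# Configuration: defaults, schema validation, JSON round trip.

#' Default model configuration
#'
#' The configuration describing the reference bench: 70 bpm heart rate,
#' baseline ICP 12.68 mmHg, a cranial/spinal compliance split of 0.31/0.84
#' ml/mmHg realized by air chambers, calibrated valve resistances, a
#' three-segment spinal canal (hydraulic diameters 15/10/5 mm), and the
#' simulation grid (fixed step period/2048, two warm-up cycles, nine recorded
#' cycles).
#'
#' Chambers may be specified either by `c_target_ml_per_mmHg` (sized at the
#' baseline operating point via [size_air_volume()]) or directly by
#' `v0_air_ml`; the two are mutually exclusive.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    heart_rate_bpm = 70,
    baseline_icp_mmHg = 12.68,
    chambers = list(
      cranial = list(c_target_ml_per_mmHg = 0.31, lambda = 1.4),
      spinal = list(c_target_ml_per_mmHg = 0.84, lambda = 1.4)
    ),
    valves = list(
      # default resistances: the values recovered by calibrate_resistances()
      # against the reference bidirectional flow extrema (see vignette)
      r_valve1_path_mmHg_per_ml_min = 0.0240,
      r_valve2_mmHg_per_ml_min = 0.0153,
      valve1_fraction = 0.5
    ),
    canal = list(
      viscosity_mPa_s = 1.0,
      segments = list(
        length_mm = c(200, 250, 150),
        diameter_mm = c(15, 10, 5)
      )
    ),
    pump = list(target_sv_ml = 0.8, n_samples = 256),
    sim = list(dt_divisor = 2048, warmup_cycles = 2, record_cycles = 9)
  )
}

# schema: allowed keys and leaf checks. Each leaf is a function(value, path).
num_leaf <- function(lo = -Inf, hi = Inf, len = 1, integerish = FALSE) {
  force(lo); force(hi); force(len); force(integerish)
  function(x, path) {
    if (!is.numeric(x) || (!is.na(len) && length(x) != len) || any(!is.finite(x))) {
      stop(sprintf("Config key '%s' must be numeric (length %s).", path, len),
        call. = FALSE
      )
    }
    if (any(x < lo) || any(x > hi)) {
      stop(sprintf("Config key '%s' out of range [%g, %g].", path, lo, hi),
        call. = FALSE
      )
    }
    if (integerish && any(abs(x - round(x)) > 1e-9)) {
      stop(sprintf("Config key '%s' must be a whole number.", path), call. = FALSE)
    }
    x
  }
}

config_schema <- function() {
  chamber <- list(
    c_target_ml_per_mmHg = num_leaf(lo = 1e-6),
    v0_air_ml = num_leaf(lo = 1e-6),
    lambda = num_leaf(lo = 1, hi = 1.67)
  )
  list(
    heart_rate_bpm = num_leaf(lo = 1, hi = 300),
    baseline_icp_mmHg = num_leaf(lo = -50, hi = 100),
    chambers = list(cranial = chamber, spinal = chamber),
    valves = list(
      r_valve1_path_mmHg_per_ml_min = num_leaf(lo = 0),
      r_valve2_mmHg_per_ml_min = num_leaf(lo = 0),
      valve1_fraction = num_leaf(lo = 0, hi = 1)
    ),
    canal = list(
      viscosity_mPa_s = num_leaf(lo = 1e-6),
      segments = list(
        length_mm = num_leaf(lo = 1e-9, len = NA),
        diameter_mm = num_leaf(lo = 1e-9, len = NA)
      )
    ),
    pump = list(
      target_sv_ml = num_leaf(lo = 1e-9),
      n_samples = num_leaf(lo = 32, integerish = TRUE)
    ),
    sim = list(
      dt_divisor = num_leaf(lo = 32, integerish = TRUE),
      warmup_cycles = num_leaf(lo = 0, integerish = TRUE),
      record_cycles = num_leaf(lo = 1, integerish = TRUE)
    )
  )
}

#' Validate and complete a configuration
#'
#' Checks a (possibly partial) configuration against the schema — unknown keys
#' are rejected by name, leaves are range-checked — and fills missing entries
#' from [default_config()]. Within a chamber, a user-supplied `v0_air_ml`
#' suppresses the default compliance target (the two are alternatives).
#'
#' @param config A nested list.
#' @return The completed, validated configuration list.
#' @export
validate_config <- function(config) {
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("Configuration must be a list.", call. = FALSE)
  walk <- function(user, schema, defaults, path) {
    unknown <- setdiff(names(user), names(schema))
    if (length(unknown) > 0) {
      stop(sprintf(
        "Unknown configuration key: '%s'.",
        paste0(path, unknown[1])
      ), call. = FALSE)
    }
    out <- list()
    for (key in names(schema)) {
      kp <- paste0(path, key)
      sc <- schema[[key]]
      if (is.function(sc)) {
        if (!is.null(user[[key]])) {
          out[[key]] <- sc(user[[key]], kp)
        } else if (!is.null(defaults[[key]])) {
          out[[key]] <- defaults[[key]]
        }
      } else {
        out[[key]] <- walk(
          user[[key]] %||% list(), sc, defaults[[key]] %||% list(),
          paste0(kp, ".")
        )
      }
    }
    out
  }
  cfg <- walk(config, config_schema(), default_config(), "")
  # chamber sizing alternatives: an explicit air volume replaces the default target
  for (side in c("cranial", "spinal")) {
    user_ch <- config$chambers[[side]]
    if (!is.null(user_ch$v0_air_ml) && is.null(user_ch$c_target_ml_per_mmHg)) {
      cfg$chambers[[side]]$c_target_ml_per_mmHg <- NULL
    }
  }
  if (length(cfg$canal$segments$length_mm) != length(cfg$canal$segments$diameter_mm)) {
    stop("Config: canal.segments length_mm and diameter_mm must have equal length.",
      call. = FALSE
    )
  }
  cfg
}

#' Read / write a configuration file
#'
#' JSON on disk. An empty (or whitespace-only) file yields the full default
#' configuration. `write_config()` and `load_config()` round-trip exactly.
#'
#' @param path File path.
#' @return `load_config()`: a validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("Configuration file not found: '%s'.", path), call. = FALSE)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) txt <- "{}"
  raw <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  validate_config(raw)
}

#' @rdname load_config
#' @param config A configuration list (validated before writing).
#' @export
write_config <- function(config, path) {
  cfg <- validate_config(config)
  jsonlite::write_json(cfg, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
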
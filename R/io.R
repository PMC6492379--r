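# CSV time-series I/O and run manifests.

#' Read / write a single-cycle waveform CSV
#'
#' The on-disk dialect is a two-column CSV `time_s,flow_ml_min` (header
#' mandatory, comma separator, dot decimal, UTF-8) holding exactly one cycle
#' on a uniform closed-open grid. The reader validates uniform spacing to a
#' tolerance of 1e-6 s and reports the first offending row; the writer emits
#' full double precision so that a write/read round trip is bitwise exact.
#' The period is inferred as `n * dt` (the grid does not repeat the cycle
#' start at the end).
#'
#' @param path File path.
#' @param sign_convention Stored with the waveform on read (the CSV itself
#'   is convention-agnostic).
#' @return `read_waveform_csv()`: a `csf_waveform`.
#' @export
read_waveform_csv <- function(path, sign_convention = "caudal_positive") {
  df <- utils::read.csv(path, header = TRUE)
  if (!identical(names(df), c("time_s", "flow_ml_min"))) {
    stop(
      "Waveform CSV must have exactly the header 'time_s,flow_ml_min'; got: ",
      paste(names(df), collapse = ","),
      call. = FALSE
    )
  }
  if (nrow(df) < 2) {
    stop("Waveform CSV needs at least two rows to establish the time grid.",
      call. = FALSE
    )
  }
  dt <- df$time_s[2] - df$time_s[1]
  if (dt <= 0) stop("Time column must be strictly increasing.", call. = FALSE)
  gaps <- which(abs(diff(df$time_s) - dt) > 1e-6)
  if (length(gaps) > 0) {
    stop(sprintf(
      "Non-uniform time grid at row %d (spacing %.9g s, expected %.9g s).",
      gaps[1] + 1, df$time_s[gaps[1] + 1] - df$time_s[gaps[1]], dt
    ), call. = FALSE)
  }
  waveform(df$flow_ml_min,
    period = nrow(df) * dt,
    sign_convention = sign_convention
  )
}

#' @rdname read_waveform_csv
#' @param wf A `csf_waveform`.
#' @export
write_waveform_csv <- function(wf, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "time_s,flow_ml_min",
    sprintf("%.17g,%.17g", wf$time_s, wf$flow_ml_min)
  ), con)
  invisible(path)
}

#' Write a simulation result CSV
#'
#' Five documented columns: `time_s`, `icp_mmHg`, `p_cistern_mmHg`,
#' `p_cranial_chamber_mmHg`, `q_spinal_ml_min` (gauge pressures,
#' caudal-positive flow).
#'
#' @param sim A `csf_simulation`.
#' @param path Output path.
#' @export
write_simulation_csv <- function(sim, path) {
  out <- sim[, c(
    "time_s", "icp_mmHg", "p_cistern_mmHg",
    "p_cranial_chamber_mmHg", "q_spinal_ml_min"
  )]
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation result CSV
#'
#' Reconstructs the cycle structure from an explicit cycle count (rows must
#' tile into equal cycles).
#'
#' @param path Path written by [write_simulation_csv()].
#' @param n_cycles Number of recorded cycles in the file.
#' @return A `csf_simulation`-like tibble with `cycle_marks` and `period`
#'   attributes.
#' @export
read_simulation_csv <- function(path, n_cycles) {
  df <- tibble::as_tibble(utils::read.csv(path))
  if (nrow(df) %% n_cycles != 0) {
    stop("Row count does not divide into the stated number of cycles.",
      call. = FALSE
    )
  }
  n_div <- nrow(df) %/% n_cycles
  dt <- df$time_s[2] - df$time_s[1]
  structure(
    df,
    period = n_div * dt,
    dt = dt,
    cycle_marks = 1L + (seq_len(n_cycles) - 1L) * n_div,
    class = c("csf_simulation", class(tibble::tibble()))
  )
}

#' Build and write a run manifest
#'
#' A JSON record sufficient to reproduce a run: the validated configuration
#' snapshot, all seeds, the package version, MD5 digests of the input files
#' and the list of outputs written.
#'
#' @param config A configuration list (validated before storing).
#' @param seeds Named list/vector of seeds used (may be empty).
#' @param inputs Character vector of input file paths (digested).
#' @param outputs Character vector of output file paths.
#' @param path Where to write the manifest JSON.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, seeds = list(), inputs = character(),
                           outputs = character(), path) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    stats::setNames(list(), character())
  }
  manifest <- list(
    package = "csftwin",
    version = as.character(utils::packageVersion("csftwin")),
    config = validate_config(config),
    seeds = seeds,
    input_digests = digests,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
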
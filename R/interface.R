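# Fixed-width settings-frame layout. The firmware <-> GUI link lines multiple
# numeric settings up in a single fixed-width string; this documented layout
# (27 characters, leading type character) is the package's frozen convention.
frame_layout <- function() {
  data.frame(
    field = c("bpm", "pip_target", "ti", "tidal_volume", "peep", "mode_code",
              "simv", "trigger_flow", "tv_alarm_low", "tv_alarm_high",
              "pip_alarm_high", "peep_alarm_low"),
    width = c(2L, 2L, 4L, 3L, 2L, 1L, 1L, 2L, 3L, 3L, 2L, 1L),
    decimals = c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Encode a settings telemetry frame
#'
#' Packs ventilator settings into the fixed-width 27-character frame used on
#' the firmware <-> GUI serial link: a leading type character (`"v"` for a
#' settings frame) followed by zero-padded decimal fields in this order
#' (widths in parentheses): bpm (2), pip_target (2), ti (4, one decimal
#' place), tidal_volume (3, ml), peep (2), mode_code (1; 0 = PRVC, 1 = PCV),
#' simv flag (1), trigger_flow (2, ml/s), tv_alarm_low (3, ml),
#' tv_alarm_high (3, ml), pip_alarm_high (2, cmH2O), peep_alarm_low (1,
#' cmH2O). Values must be non-negative and fit their field width; `ti` is
#' carried to one decimal place.
#'
#' @param values Named list or vector with the twelve fields above.
#' @param type Frame type character (default `"v"`).
#' @return A 27-character frame string.
#' @examples
#' f <- encode_frame(list(bpm = 12, pip_target = 20, ti = 2, tidal_volume = 350,
#'   peep = 5, mode_code = 0, simv = 0, trigger_flow = 20, tv_alarm_low = 175,
#'   tv_alarm_high = 525, pip_alarm_high = 45, peep_alarm_low = 0))
#' nchar(f) # 27
#' @export
encode_frame <- function(values, type = "v") {
  lay <- frame_layout()
  if (nchar(type) != 1L) stop("frame `type` must be a single character")
  missing <- setdiff(lay$field, names(values))
  if (length(missing))
    stop("missing frame fields: ", paste(missing, collapse = ", "))
  parts <- character(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    v <- as.numeric(values[[lay$field[i]]])
    if (!is.finite(v) || v < 0)
      stop(sprintf("field '%s' must be a finite non-negative number",
                   lay$field[i]))
    if (lay$decimals[i] == 0L) {
      if (abs(v - round(v)) > 1e-9)
        stop(sprintf("field '%s' must be an integer", lay$field[i]))
      s <- formatC(round(v), width = lay$width[i], flag = "0", format = "d")
    } else {
      s <- formatC(v, width = lay$width[i], flag = "0", format = "f",
                   digits = lay$decimals[i])
    }
    if (nchar(s) > lay$width[i])
      stop(sprintf("field '%s' value %g overflows its width-%d field",
                   lay$field[i], v, lay$width[i]))
    parts[i] <- s
  }
  paste0(type, paste(parts, collapse = ""))
}

#' Decode a settings telemetry frame
#'
#' Segments a received frame string by the preset field lengths documented in
#' [encode_frame()] and parses each field. Malformed frames (wrong length,
#' unknown type character, non-numeric field) raise an error naming the
#' offence; settings are never partially applied.
#'
#' @param s A frame string.
#' @param types Accepted type characters.
#' @return Named list of the decoded numeric fields plus `type`.
#' @examples
#' decode_frame("v061502.0042090050025150702")$bpm # 6
#' @export
decode_frame <- function(s, types = "v") {
  lay <- frame_layout()
  want <- 1L + sum(lay$width)
  if (!is.character(s) || length(s) != 1L)
    stop("frame must be a single string")
  if (nchar(s) != want)
    stop(sprintf("wrong frame length: expected %d characters, got %d",
                 want, nchar(s)))
  type <- substr(s, 1L, 1L)
  if (!type %in% types)
    stop(sprintf("unknown frame type '%s'", type))
  out <- list(type = type)
  pos <- 2L
  for (i in seq_len(nrow(lay))) {
    chunk <- substr(s, pos, pos + lay$width[i] - 1L)
    v <- suppressWarnings(as.numeric(chunk))
    if (is.na(v))
      stop(sprintf("field '%s' is not numeric: '%s'", lay$field[i], chunk))
    out[[lay$field[i]]] <- v
    pos <- pos + lay$width[i]
  }
  out
}

# Format numeric columns at full double precision so that written CSVs
# round-trip exactly through read.csv.
format_full_precision <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  df
}

#' Write run waveforms and breath records to CSV
#'
#' Writes the per-sample waveforms and per-breath records of a [run_ventilator()]
#' result as two UTF-8 CSV files with header rows and stable column order.
#' Numeric columns are written at full precision, so re-reading reproduces
#' the in-memory values exactly.
#'
#' @param run A `vent_run`.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, a named character vector with the `samples` and
#'   `breaths` file paths.
#' @export
write_waveforms <- function(run, dir = ".", prefix = "vent") {
  stopifnot(inherits(run, "vent_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(samples = file.path(dir, paste0(prefix, "_samples.csv")),
             breaths = file.path(dir, paste0(prefix, "_breaths.csv")))
  utils::write.csv(format_full_precision(run$samples), paths["samples"],
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(format_full_precision(run$breaths), paths["breaths"],
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' Read a run configuration from YAML or JSON
#'
#' A run configuration carries four blocks: `settings` (arguments of
#' [vent_settings()]), `lung` ([lung_params()]), `scenario`
#' ([make_scenario()]; `compliance_events` may be given as a list of
#' `{time, factor}` pairs) and `run` (n_breaths, dt, seed). Missing blocks
#' fall back to package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `run_config` with `settings`, `lung`, `scenario`
#'   and `run` ready to splice into [run_ventilator()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param x A plain list with the blocks described above.
#' @export
as_run_config <- function(x) {
  stopifnot(is.list(x))
  settings <- do.call(vent_settings, as.list(x$settings %||% list()))
  lung <- do.call(lung_params, as.list(x$lung %||% list()))
  sc <- as.list(x$scenario %||% list(kind = "normal"))
  if (!is.null(sc$compliance_events) && !is.data.frame(sc$compliance_events))
    sc$compliance_events <- do.call(rbind, lapply(sc$compliance_events,
                                                  as.data.frame))
  scenario <- do.call(make_scenario, sc)
  run <- as.list(x$run %||% list())
  run$n_breaths <- run$n_breaths %||% 20
  run$dt <- run$dt %||% 0.001
  run$seed <- run$seed %||% 1
  structure(list(settings = settings, lung = lung, scenario = scenario,
                 run = run),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise a run as a plain list (JSON-ready)
#'
#' @param object A `vent_run`.
#' @param last_n Number of trailing breaths to average for the steady-state
#'   figures.
#' @param ... Unused.
#' @return A list of summary quantities: steady-state tidal volume, PIP and
#'   minimum pressure, trigger counts, alarm log, energy figures and the
#'   worst pressure-balance residual.
#' @export
summary.vent_run <- function(object, last_n = 5, ...) {
  b <- object$breaths
  nb <- nrow(b)
  tail_idx <- max(1, nb - last_n + 1):nb
  s <- object$samples
  list(
    mode = object$settings$mode,
    n_breaths = nb,
    simulated_s = nrow(s) * object$dt,
    tidal_volume_ml = mean(b$delivered_volume[tail_idx]),
    pip_cmH2O = mean(b$pip[tail_idx]),
    min_pressure_cmH2O = mean(b$min_pressure[tail_idx]),
    patient_triggers = sum(b$trigger_type == "patient"),
    breaths_with_alarms = sum(nzchar(b$alarms)),
    max_balance_residual = max(abs(s$p1 - (s$p2 + s$p3 + s$p4))),
    max_airway_cmH2O = max(s$airway),
    energy_wh = object$energy$energy_wh,
    avg_power_w = object$energy$avg_power_w
  )
}
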
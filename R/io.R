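#' Write a gait recording to CSV
#'
#' Schema: header `time_s,L1,L2,L3,R1,R2,R3`, one row per sample, voltages
#' in volts, decimal point, UTF-8.
#'
#' @param recording A `gait_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "gait_recording"))
  d <- data.frame(time_s = recording$time, recording$voltages,
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gait recording from CSV
#'
#' Validates the schema (a `time_s` column plus the six channel columns,
#' in any order — channels are reordered to canonical L1..R3) and infers
#' the sampling rate from the time column, which must be uniform within 1%
#' jitter.
#'
#' @param path CSV file written by [write_recording()] or following the
#'   same schema.
#' @return A `gait_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE)
  needed <- c("time_s", gait_channels())
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop(sprintf("recording CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  t <- d$time_s
  if (length(t) < 2L) stop("recording must contain at least 2 samples",
                           call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 0.01 * stats::median(dt))
    stop("time column is not uniformly sampled (jitter above 1%)",
         call. = FALSE)
  rec <- gait_recording(as.matrix(d[gait_channels()]),
                        sampling_rate = 1 / stats::median(dt),
                        start_time = t[1])
  rec
}

#' Write a gait-parameter table as tidy CSV
#'
#' Columns `foot,channel,step_index,parameter,value` (seconds for
#' durations/shifts, volts for amplitudes).
#'
#' @param params A `gait_parameters` object or compatible data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  d <- as.data.frame(params)[c("foot", "channel", "step_index",
                               "parameter", "value")]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gait-parameter table from tidy CSV
#' @param path File written by [write_parameters()].
#' @return A `gait_parameters` data frame (without pulse attributes).
#' @export
read_parameters <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("foot", "channel", "step_index", "parameter", "value")
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop(sprintf("parameter CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(d, class = c("gait_parameters", "data.frame"))
}

#' Read / write the gait-mode rulebook as CSV
#' @param path CSV file with the [default_rulebook()] columns.
#' @return `read_rulebook`: the rulebook data frame.
#' @export
read_rulebook <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- names(default_rulebook())
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop(sprintf("rulebook is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  d$imbalance <- as.logical(d$imbalance)
  d[needed]
}

#' @rdname read_rulebook
#' @param rulebook Rulebook data frame.
#' @export
write_rulebook <- function(rulebook, path) {
  utils::write.csv(rulebook, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- flat key-value configuration ------------------------------------------

#' Read a flat key-value configuration file
#'
#' Minimal YAML-style format: one `key: value` per line, `#` comments and
#' blank lines ignored, dotted keys for sections (e.g.
#' `simulation.noise_sd: 0.05`). Values are parsed as numbers or
#' `true`/`false` where possible, otherwise kept as strings. Writing and
#' re-reading a config is round-trip stable.
#'
#' @param path Config file path.
#' @return Named list (names are the full dotted keys).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    key <- trimws(m[2]); val <- trimws(m[3])
    parsed <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(parsed)) parsed
                  else if (val %in% c("true", "false")) val == "true"
                  else val
  }
  out
}

#' Write a flat key-value configuration file
#' @param config Named list of scalar values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  fmt <- vapply(config, function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.numeric(v)) format(v, digits = 15, scientific = FALSE)
    else as.character(v)
  }, character(1))
  writeLines(paste0(names(config), ": ", fmt), path, useBytes = TRUE)
  invisible(path)
}

# Subset a config by dotted section prefix, stripping the prefix.
config_section <- function(config, section) {
  pre <- paste0(section, ".")
  keys <- names(config)[startsWith(names(config), pre)]
  out <- config[keys]
  names(out) <- substring(names(out), nchar(pre) + 1L)
  out
}
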
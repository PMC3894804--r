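# Session container: a two-file pair `<stem>.oesb.json` (human-readable
# JSON header: version, channels, sampling rate, units) plus `<stem>.oesb`
# (little-endian 32-bit float payload, channels concatenated: voltage in
# microvolts, then the TTL command stream as 0/1). Round trips are lossless
# at 32-bit precision.

OESB_VERSION <- 1L

oesb_paths <- function(path) {
  stem <- sub("\\.oesb(\\.json)?$", "", path)
  list(header = paste0(stem, ".oesb.json"), payload = paste0(stem, ".oesb"))
}

#' Write a recording session to disk
#'
#' @param trace A [voltage_trace()].
#' @param ttl A `ttl` interval table (stored as a sampled command stream at
#'   the trace's rate).
#' @param path Destination path; the `.oesb`/`.oesb.json` pair is derived
#'   from it.
#' @return The payload path, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(trace, ttl, path) {
  stopifnot(inherits(trace, "voltage_trace"), inherits(ttl, "ttl"))
  p <- oesb_paths(path)
  fs <- sampling_rate(trace)
  n <- nrow(trace)
  header <- list(
    format = "oesb", version = OESB_VERSION,
    sampling_rate_hz = fs, n_samples = n,
    channels = list(
      list(label = attr(trace, "channel_label") %||% "ch1", units = "uV"),
      list(label = "ttl", units = "binary")
    ),
    start_time_s = if (n) trace$time_s[1] else 0
  )
  jsonlite::write_json(header, p$header, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(p$payload, "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace$uv), con, size = 4L, endian = "little")
  writeBin(as.numeric(ttl_to_wave(ttl, fs, n)), con, size = 4L, endian = "little")
  invisible(p$payload)
}

#' Read a recording session from disk
#'
#' @param path Path to the `.oesb` payload (or its `.oesb.json` header).
#' @return A list with elements `trace` ([voltage_trace()]) and `ttl`
#'   (interval table recovered from the stored command stream).
#' @export
read_session <- function(path) {
  p <- oesb_paths(path)
  if (!file.exists(p$header)) abort(sprintf("missing header file '%s'", p$header))
  if (!file.exists(p$payload)) abort(sprintf("missing payload file '%s'", p$payload))
  header <- jsonlite::read_json(p$header, simplifyVector = TRUE)
  if (!identical(header$format, "oesb") || is.null(header$version)) {
    abort("not an oesb session header", class = "optrode_format_error")
  }
  if (header$version > OESB_VERSION) {
    abort(sprintf("unsupported oesb version %s", header$version),
          class = "optrode_format_error")
  }
  n <- as.integer(header$n_samples)
  expected <- 4 * n * 2
  actual <- file.size(p$payload)
  if (!identical(as.numeric(expected), as.numeric(actual))) {
    abort(sprintf("corrupt session: header promises %d payload bytes, file has %d",
                  expected, actual),
          class = "optrode_corrupt_error")
  }
  con <- file(p$payload, "rb")
  on.exit(close(con))
  uv <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  wave <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  fs <- header$sampling_rate_hz
  trace <- voltage_trace(uv, fs, start_time_s = header$start_time_s %||% 0,
                         channel_label = header$channels$label[1] %||% "ch1")
  list(trace = trace, ttl = ttl_from_wave(wave, fs))
}

#' Read a spike-timestamp table
#'
#' One timestamp (seconds) per line; blank lines and lines starting with
#' `#` are ignored. Output is sorted; exact duplicates are collapsed with a
#' warning.
#'
#' @param path File to read.
#' @param duration_s Recording duration to attach; defaults to the last
#'   timestamp.
#' @return A `spike_train` with `source = "imported"`.
#' @export
read_spike_table <- function(path, duration_s = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (any(is.na(vals))) {
    bad <- which(keep)[which(is.na(vals))[1]]
    abort(sprintf("non-numeric timestamp at line %d of '%s'", bad, path),
          class = "optrode_parse_error")
  }
  duration_s <- duration_s %||% if (length(vals)) max(vals) else 0
  spike_train(vals, duration_s, source = "imported")
}

#' Write a spike-timestamp table
#'
#' @param train A `spike_train`.
#' @param path Destination file; timestamps are written with microsecond
#'   precision, one per line, after a `#` comment header.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  writeLines(c(
    sprintf("# spike timestamps (s); duration_s=%s; source=%s",
            format(train_duration_s(train)), attr(train, "source")),
    sprintf("%.6f", train$time_s)
  ), path)
  invisible(path)
}

#' Read/write a light-interval table
#'
#' Two comma-separated columns `on_s, off_s`, one pulse per line, `#`
#' comments tolerated.
#'
#' @param path File to read or write.
#' @return `read_ttl_table()` returns a `ttl` interval table;
#'   `write_ttl_table()` returns `path` invisibly.
#' @export
read_ttl_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) return(ttl())
  parts <- strsplit(trimws(lines[keep]), "\\s*,\\s*")
  if (any(lengths(parts) != 2)) {
    bad <- which(keep)[which(lengths(parts) != 2)[1]]
    abort(sprintf("expected 'on_s,off_s' at line %d of '%s'", bad, path),
          class = "optrode_parse_error")
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE))
  if (any(is.na(m))) {
    abort(sprintf("non-numeric interval in '%s'", path), class = "optrode_parse_error")
  }
  ttl(m[, 1], m[, 2])
}

#' @rdname read_ttl_table
#' @param x A `ttl` interval table.
#' @export
write_ttl_table <- function(x, path) {
  stopifnot(inherits(x, "ttl"))
  writeLines(c("# on_s,off_s", sprintf("%.6f,%.6f", x$on_s, x$off_s)), path)
  invisible(path)
}

#' Write a generation manifest
#'
#' Saves the configuration, protocol and seed of a synthetic session as a
#' plain-text YAML file so every fixture can be regenerated exactly.
#'
#' @param session A `synth_session`.
#' @param path Destination `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(session, path) {
  stopifnot(inherits(session, "synth_session"))
  yaml::write_yaml(list(
    package = "optrode",
    version = as.character(utils::packageVersion("optrode")),
    seed = session$config$seed,
    duration_s = session$duration_s,
    config = unclass(session$config),
    protocol = unclass(session$protocol)
  ), path)
  invisible(path)
}

#' Rebuild a session from its manifest
#'
#' @param path Manifest written by [write_manifest()].
#' @param render Passed to the generator.
#' @return A `synth_session` identical to the one the manifest describes.
#' @export
read_manifest_session <- function(path, render = "trace") {
  m <- yaml::read_yaml(path)
  config <- do.call(synth_config, m$config[setdiff(names(m$config), NULL)])
  protocol <- do.call(stim_protocol, m$protocol)
  gen <- if (protocol$kind == "pulse_train") generate_chr2_session else generate_nphr_session
  gen(config, protocol, render = render)
}
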
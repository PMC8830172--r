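# Trace and event-table file formats.
#
# Text trace: a "# key: value" header block then two whitespace-separated
# columns (time_s, current_pA). Binary trace: magic "PBTR", format version,
# sampling rate, sample count, float64 samples, little-endian -- exact
# round trip. ABF files can be converted externally (e.g. pyabf) to the
# text form and ingested here.

TRACE_MAGIC <- "PBTR"
TRACE_VERSION <- 1L

#' Write a current trace to disk
#'
#' @param trace A `current_trace`.
#' @param path Output file path.
#' @param format `"binary"` (exact round trip) or `"text"` (two-column
#'   tabular, portable, ~1e-6 pA round-trip accuracy).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("binary", "text")) {
  stopifnot(inherits(trace, "current_trace"))
  format <- match.arg(format)
  md <- trace$metadata
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(TRACE_MAGIC, con, nchars = 4L, eos = NULL)
    writeBin(TRACE_VERSION, con, size = 4L, endian = "little")
    writeBin(as.numeric(trace$sampling_rate), con, size = 8L, endian = "little")
    writeBin(length(trace$samples), con, size = 4L, endian = "little")
    hdr <- sprintf("condition=%s;voltage=%s;baseline_current=%s;filter_bandwidth=%s;seed=%s",
                   md$condition, md$voltage %||% NA, md$baseline_current %||% NA,
                   md$filter_bandwidth %||% NA, md$seed %||% NA)
    writeBin(nchar(hdr, type = "bytes"), con, size = 4L, endian = "little")
    writeChar(hdr, con, nchars = nchar(hdr, type = "bytes"), eos = NULL)
    writeBin(trace$samples, con, size = 8L, endian = "little")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# poreblock_trace: v%d", TRACE_VERSION),
      sprintf("# condition: %s", md$condition),
      sprintf("# sampling_rate_Hz: %.10g", trace$sampling_rate),
      sprintf("# voltage_mV: %.10g", as.numeric(md$voltage %||% NA)),
      sprintf("# baseline_current_pA: %.10g", as.numeric(md$baseline_current %||% NA)),
      sprintf("# filter_bandwidth_Hz: %.10g", as.numeric(md$filter_bandwidth %||% NA)),
      sprintf("# seed: %d", as.integer(md$seed %||% NA)),
      sprintf("# n_samples: %d", length(trace$samples)),
      "# columns: time_s current_pA"), con)
    t_s <- (seq_along(trace$samples) - 1) / trace$sampling_rate
    utils::write.table(
      data.frame(t = sprintf("%.9f", t_s), i = sprintf("%.6f", trace$samples)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a current trace written by [write_trace()]
#'
#' The format (binary vs text) is sniffed from the file's first bytes.
#' Malformed headers or truncated sample blocks raise a parse error; no
#' partial trace is returned.
#'
#' @param path File path.
#' @return A `current_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("read_trace: no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  magic <- rawToChar(readBin(con, "raw", 4L))
  close(con)
  if (identical(magic, TRACE_MAGIC)) read_trace_binary(path) else read_trace_text(path)
}

read_trace_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 4L)  # magic, already checked
  ver <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(ver) || ver != TRACE_VERSION) {
    stop("read_trace: unsupported binary trace version (offset 4)", call. = FALSE)
  }
  fs <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(fs) || !length(n) || !length(hlen) || n < 0L || hlen < 0L) {
    stop("read_trace: malformed binary header (offset 8)", call. = FALSE)
  }
  hdr <- readChar(con, hlen, useBytes = TRUE)
  kv <- strsplit(strsplit(hdr, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  md <- stats::setNames(lapply(kv, function(p) p[2L]), vapply(kv, `[[`, "", 1L))
  x <- readBin(con, "numeric", n, size = 8L, endian = "little")
  if (length(x) != n) {
    stop("read_trace: truncated sample block: expected ", n, " samples, got ",
         length(x), " (offset ", 24L + hlen, ")", call. = FALSE)
  }
  num_or_na <- function(v) suppressWarnings(as.numeric(v %||% NA))
  structure(
    list(samples = x, sampling_rate = fs,
         metadata = list(condition = md$condition %||% NA_character_,
                         voltage = num_or_na(md$voltage),
                         baseline_current = num_or_na(md$baseline_current),
                         filter_bandwidth = num_or_na(md$filter_bandwidth),
                         duration = n / fs,
                         seed = suppressWarnings(as.integer(md$seed %||% NA)))),
    class = "current_trace")
}

read_trace_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#", lines)
  if (!length(hdr_idx) || !grepl("^# poreblock_trace:", lines[1L])) {
    stop("read_trace: line 1: not a poreblock trace file", call. = FALSE)
  }
  hdr <- lines[hdr_idx]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1L]))
  }
  fs <- as.numeric(get("sampling_rate_Hz"))
  n_declared <- as.integer(get("n_samples"))
  if (!is.finite(fs)) stop("read_trace: missing sampling_rate_Hz header", call. = FALSE)
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "[ \t]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("read_trace: line ", setdiff(seq_along(lines), hdr_idx)[bad[1L]],
         ": expected two columns", call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(x)) {
    stop("read_trace: non-numeric current value near line ",
         which(is.na(x))[1L], call. = FALSE)
  }
  if (is.finite(n_declared) && length(x) != n_declared) {
    stop("read_trace: truncated file: header declares ", n_declared,
         " samples, found ", length(x), call. = FALSE)
  }
  structure(
    list(samples = x, sampling_rate = fs,
         metadata = list(condition = get("condition"),
                         voltage = as.numeric(get("voltage_mV")),
                         baseline_current = as.numeric(get("baseline_current_pA")),
                         filter_bandwidth = as.numeric(get("filter_bandwidth_Hz")),
                         duration = length(x) / fs,
                         seed = suppressWarnings(as.integer(get("seed"))))),
    class = "current_trace")
}

#' Write / read ground-truth event streams as CSV
#'
#' Columns: `class,start_s,dwell_ms,amplitude_pA`.
#'
#' @param events A `ground_truth_events` data.frame.
#' @param path File path.
#' @return `path` / the events data.frame.
#' @export
write_truth_csv <- function(events, path) {
  utils::write.csv(events[, c("class", "start_s", "dwell_ms", "amplitude_pA")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "start_s", "dwell_ms", "amplitude_pA")
  if (!all(need %in% names(ev))) {
    stop("read_truth_csv: missing columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "), call. = FALSE)
  }
  class(ev) <- c("ground_truth_events", "data.frame")
  ev
}

#' Write / read detected event tables as CSV
#'
#' Columns: `replicate,start_s,dwell_ms,blockade_pA,class`.
#'
#' @param events An `event_table`.
#' @param path File path.
#' @return `path` / an `event_table`.
#' @export
write_events_csv <- function(events, path) {
  md <- attr(events, "meta") %||% list()
  out <- data.frame(replicate = md$replicate %||% 1L,
                    start_s = events$start_s,
                    dwell_ms = events$dwell_ms,
                    blockade_pA = events$blockade_pA,
                    class = events$class)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param condition Condition name to attach when reading.
#' @export
read_events_csv <- function(path, condition = NA_character_) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "dwell_ms", "blockade_pA", "class")
  if (!all(need %in% names(ev))) {
    stop("read_events_csv: missing columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "), call. = FALSE)
  }
  rep_id <- if ("replicate" %in% names(ev)) ev$replicate[1L] else 1L
  ev$low_confidence <- ev$low_confidence %||% FALSE
  new_event_table(ev[, c(need, "low_confidence")], condition = condition,
                  replicate = rep_id, source = path)
}
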
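#' Write an IQ recording as a two-channel WAV file
#'
#' Channel 0 carries I, channel 1 carries Q. `format = "pcm16"` writes 16-bit
#' integer samples (values clipped to \[-1, 1\]); `"float32"` writes IEEE
#' floats. No WAV package is assumed: the RIFF container is written directly.
#'
#' @param rec an [iq_recording]
#' @param path output file
#' @param format "pcm16" or "float32"
#' @return `path`, invisibly
#' @export
write_iq_wav <- function(rec, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(rec, "iq_recording"))
  format <- match.arg(format)
  fs <- as.integer(round(rec$sample_rate))
  n <- length(rec$i)
  inter <- as.numeric(rbind(rec$i, rec$q))  # interleave I,Q
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    bytes_ps <- 2L; fmt_code <- 1L
    data_len <- n * 2L * bytes_ps
  } else {
    bytes_ps <- 4L; fmt_code <- 3L
    data_len <- n * 2L * bytes_ps
  }
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                 # channels
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L * bytes_ps), con, size = 4,
           endian = "little")                                    # byte rate
  writeBin(2L * bytes_ps, con, size = 2, endian = "little")      # block align
  writeBin(8L * bytes_ps, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (format == "pcm16") {
    v <- as.integer(round(pmax(pmin(inter, 1), -1) * 32767))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(inter, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a two-channel IQ WAV file
#'
#' Accepts 16-bit PCM or 32-bit float WAV; channel 0 is taken as I and
#' channel 1 as Q, and integer amplitudes are normalised to \[-1, 1\].
#'
#' @param path WAV file
#' @return an [iq_recording]
#' @export
read_iq_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAV file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little",
                       signed = FALSE),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        block = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little"))
      if (len > 16) invisible(readBin(con, raw(), len - 16))
    } else if (id == "data") {
      data <- readBin(con, raw(), len)
      break
    } else {
      invisible(readBin(con, raw(), len))
    }
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV file: ", path)
  if (fmt$channels != 2)
    stop(sprintf(
      "expected a 2-channel IQ WAV (channel 0 = I, channel 1 = Q); got %d channel(s)",
      fmt$channels))
  if (fmt$code == 1 && fmt$bits == 16) {
    v <- readBin(data, integer(), n = length(data) / 2, size = 2,
                 endian = "little") / 32767
  } else if (fmt$code == 3 && fmt$bits == 32) {
    v <- readBin(data, numeric(), n = length(data) / 4, size = 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (need 16-bit PCM or 32-bit float)")
  }
  iq_recording(v[c(TRUE, FALSE)], v[c(FALSE, TRUE)], fmt$rate)
}

#' Read a ground-truth event timeline from CSV
#'
#' Expects header `label,start_s,end_s`; labels must be inward, outward or
#' hover (background is implied by the absence of events). Rows are validated
#' with their line numbers and sorted by start. Events are re-hydrated with
#' default kinematics so the result can be re-synthesized if needed.
#'
#' @param path CSV file
#' @param total_duration recording duration; defaults to the latest event end
#' @return an [event_timeline]
#' @export
read_timeline_csv <- function(path, total_duration = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("label", "start_s", "end_s")))
    stop("timeline CSV must have header 'label,start_s,end_s'")
  events <- lapply(seq_len(nrow(df)), function(r) {
    lab <- df$label[r]
    if (!(lab %in% EVENT_LEVELS))
      stop(sprintf("line %d: unknown label '%s'", r + 1L, lab))
    if (!is.finite(df$start_s[r]) || !is.finite(df$end_s[r]) ||
        df$end_s[r] <= df$start_s[r])
      stop(sprintf("line %d: end_s must exceed start_s", r + 1L))
    dur <- df$end_s[r] - df$start_s[r]
    bee_event(lab, df$start_s[r], df$end_s[r],
              motion = motion_profile(lab, function(t) rep(1, length(t)), dur))
  })
  if (is.null(total_duration))
    total_duration <- if (nrow(df)) max(df$end_s) else 1
  event_timeline(events, total_duration)
}

#' Write an event timeline to CSV (`label,start_s,end_s`)
#'
#' @param timeline an [event_timeline]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_timeline_csv <- function(timeline, path) {
  stopifnot(inherits(timeline, "event_timeline"))
  df <- data.frame(
    label = vapply(timeline$events, `[[`, character(1), "label"),
    start_s = vapply(timeline$events, `[[`, numeric(1), "start"),
    end_s = vapply(timeline$events, `[[`, numeric(1), "end"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature table to CSV (`window_id,label,f_1..f_N`)
#' @param x feature matrix
#' @param labels label per row
#' @param path output file
#' @param window_ids optional identifiers
#' @return `path`, invisibly
#' @export
write_features_csv <- function(x, labels, path, window_ids = NULL) {
  if (is.null(window_ids)) window_ids <- sprintf("w%04d", seq_len(nrow(x)))
  df <- data.frame(window_id = window_ids, label = labels, x)
  names(df) <- c("window_id", "label", sprintf("f_%d", seq_len(ncol(x))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features_csv]
#' @param path CSV file
#' @return list with `x`, `labels`, `window_ids`
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  list(x = as.matrix(df[, -(1:2), drop = FALSE]),
       labels = df$label, window_ids = df$window_id)
}

#' Write metrics (and confusion matrix) as JSON
#' @param metrics a `pathway_metrics` object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(list(
    accuracy = metrics$accuracy, precision = metrics$precision,
    recall = metrics$recall, f1_macro = metrics$f1_macro,
    confusion = unclass(metrics$confusion)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
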
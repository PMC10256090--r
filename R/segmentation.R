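#' Segmentation specification
#'
#' Fixed-length analysis windows with a nominal overlap between consecutive
#' windows; the final window is anchored to the end of the recording so that
#' no source data are discarded, which can enlarge the last overlap.
#'
#' @param window_len window length in seconds (default 0.4)
#' @param nominal_overlap overlap between consecutive windows in seconds
#' @return an object of class `segmentation_spec`
#' @export
segmentation_spec <- function(window_len = 0.4, nominal_overlap = 0.1) {
  stopifnot(window_len > 0, nominal_overlap >= 0,
            nominal_overlap < window_len)
  structure(list(window_len = window_len, nominal_overlap = nominal_overlap),
            class = "segmentation_spec")
}

#' Split a recording into fixed-length windows
#'
#' Windows start at multiples of `step = window_len - nominal_overlap`; the
#' final window is placed to end exactly at the recording end, so its overlap
#' with the previous window lies in `[nominal_overlap, window_len)`. A 0.6 s
#' recording with 0.4 s windows and 0.1 s nominal overlap therefore yields two
#' windows overlapping by 0.2 s. All placement arithmetic is done in sample
#' indices with half-open index spans.
#'
#' @param rec an [iq_recording]
#' @param spec a [segmentation_spec]
#' @param source_id identifier recorded on each window
#' @return list of `window_sample` objects, each with fields `recording`
#'   ([iq_recording] excerpt), `start`, `end` (seconds), `label` (NA until
#'   assigned) and `source_id`
#' @export
segment_recording <- function(rec, spec = segmentation_spec(),
                              source_id = "rec") {
  stopifnot(inherits(rec, "iq_recording"),
            inherits(spec, "segmentation_spec"))
  fs <- rec$sample_rate
  n <- length(rec$i)
  w <- round(spec$window_len * fs)
  s <- round((spec$window_len - spec$nominal_overlap) * fs)
  if (n < w)
    stop(sprintf(
      "recording (%.3f s) is shorter than the %g s minimum window",
      rec$duration, spec$window_len))
  starts <- seq(0L, n - w, by = s)
  if (starts[length(starts)] != n - w)
    starts <- c(starts, n - w)
  lapply(starts, function(i0) {
    idx <- (i0 + 1):(i0 + w)
    structure(list(
      recording = iq_recording(rec$i[idx], rec$q[idx], fs),
      start = i0 / fs, end = (i0 + w) / fs,
      label = NA_character_, source_id = source_id
    ), class = "window_sample")
  })
}

#' @export
print.window_sample <- function(x, ...) {
  cat(sprintf("<window_sample> [%.3f, %.3f) s  label=%s  source=%s\n",
              x$start, x$end, x$label, x$source_id))
  invisible(x)
}

#' Assign a single class label to a window from a ground-truth timeline
#'
#' A window overlapping no event is `background`. Otherwise the label of the
#' highest-priority overlapping event wins; by default inward and outward
#' share top priority and outrank hover. Ties among equal-priority events are
#' broken by the larger overlap duration with the window, then by the earlier
#' event start. Event spans are half-open `[start, end)`.
#'
#' @param window a `window_sample` (or list with `start`/`end` in seconds)
#' @param timeline an [event_timeline]
#' @param priority named numeric vector of label priorities (larger wins)
#' @return a single label string
#' @export
label_window <- function(window, timeline,
                         priority = c(inward = 2, outward = 2, hover = 1)) {
  stopifnot(inherits(timeline, "event_timeline"))
  ws <- window$start
  we <- window$end
  best <- NULL
  for (e in timeline$events) {
    ov <- min(we, e$end) - max(ws, e$start)
    if (ov <= 0) next
    cand <- list(label = e$label, pri = priority[[e$label]],
                 overlap = ov, start = e$start)
    if (is.null(best) ||
        cand$pri > best$pri ||
        (cand$pri == best$pri && cand$overlap > best$overlap) ||
        (cand$pri == best$pri && cand$overlap == best$overlap &&
         cand$start < best$start))
      best <- cand
  }
  if (is.null(best)) "background" else best$label
}

#' Segment a recording and label every window
#'
#' @param rec an [iq_recording]
#' @param timeline an [event_timeline] of ground truth
#' @param spec a [segmentation_spec]
#' @param source_id identifier for provenance
#' @return list of labelled `window_sample`s
#' @export
segment_and_label <- function(rec, timeline, spec = segmentation_spec(),
                              source_id = "rec") {
  ws <- segment_recording(rec, spec, source_id)
  lapply(ws, function(w) {
    w$label <- label_window(w, timeline)
    w
  })
}
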
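#' Radar and receiver configuration
#'
#' Physical constants of the continuous-wave radar front end: the 5.8 GHz
#' carrier (wavelength ~5.17 cm), the first-order low-pass that limits the IF
#' band to roughly DC-408 Hz, the audio-card sampling rate, and the additive
#' noise floor of the receiver chain.
#'
#' @param carrier_frequency carrier in Hz (default 5.8e9)
#' @param if_cutoff -3 dB corner of the first-order IF low-pass, Hz
#' @param sample_rate ADC sampling rate in Hz
#' @param noise_rms RMS amplitude of additive white Gaussian noise per channel.
#'   The default 0.07 gives roughly 20 dB SNR for a unit-amplitude body return.
#' @param tone_1khz_amplitude amplitude of a faint narrowband equipment tone
#'   near 1 kHz (0 disables it)
#' @return an object of class `radar_config`
#' @export
radar_config <- function(carrier_frequency = 5.8e9, if_cutoff = 408,
                         sample_rate = 44100, noise_rms = 0.07,
                         tone_1khz_amplitude = 0) {
  stopifnot(carrier_frequency > 0, if_cutoff > 0,
            sample_rate > 2 * if_cutoff,
            noise_rms >= 0, tone_1khz_amplitude >= 0)
  structure(list(
    carrier_frequency = carrier_frequency,
    wavelength = 299792458 / carrier_frequency,
    if_cutoff = if_cutoff,
    sample_rate = sample_rate,
    noise_rms = noise_rms,
    tone_1khz_amplitude = tone_1khz_amplitude
  ), class = "radar_config")
}

#' Wingbeat specification of a single scatterer
#'
#' Amplitude and angular frequency of the harmonic wing motion that phase
#' modulates the return. Honeybee wingbeat frequencies fall in 150-230 Hz with
#' an oscillation amplitude near 1 cm.
#'
#' @param amplitude wing oscillation amplitude A_H in metres
#' @param angular_frequency wingbeat angular frequency omega_H in rad/s
#' @return an object of class `wingbeat_spec`
#' @export
wingbeat_spec <- function(amplitude = 0.01,
                          angular_frequency = 2 * pi * 190) {
  stopifnot(amplitude >= 0, angular_frequency >= 0)
  structure(list(amplitude = amplitude, angular_frequency = angular_frequency),
            class = "wingbeat_spec")
}

#' Scatterer amplitudes
#'
#' Scalar radar-cross-section stand-ins: body translation amplitude A1 and
#' wing amplitude A2. The field calibration A2 = A1/5 = 0.2 fixes A1 = 1.
#'
#' @param body_amplitude A1, dimensionless
#' @param wing_amplitude A2, dimensionless
#' @return an object of class `scatterer_spec`
#' @export
scatterer_spec <- function(body_amplitude = 1, wing_amplitude = 0.2) {
  stopifnot(body_amplitude >= 0, wing_amplitude >= 0)
  structure(list(body_amplitude = body_amplitude,
                 wing_amplitude = wing_amplitude),
            class = "scatterer_spec")
}

#' Motion profile of one flight event
#'
#' Radar-target range as a function of time over the event. `range_fn` must be
#' vectorised over t in `[0, duration]` seconds and return metres.
#'
#' @param class_label one of "inward", "outward", "hover"
#' @param range_fn vectorised function t -> R(t) in metres
#' @param duration event duration in seconds
#' @return an object of class `motion_profile`
#' @export
motion_profile <- function(class_label, range_fn, duration) {
  class_label <- match.arg(class_label, EVENT_LEVELS)
  stopifnot(is.function(range_fn), duration > 0)
  # validate kinematic invariants on a coarse grid
  tt <- seq(0, duration, length.out = max(64L, ceiling(duration * 200)))
  rr <- range_fn(tt)
  if (any(!is.finite(rr)) || any(rr < 0.05) || any(rr > 3))
    stop("range_fn must stay within [0.05, 3] m over the event")
  v <- abs(diff(rr) / diff(tt))
  if (any(v > 3 + 1e-9))
    stop("|dR/dt| must not exceed 3 m/s")
  structure(list(class_label = class_label, range_fn = range_fn,
                 duration = duration),
            class = "motion_profile")
}

#' Clutter specification
#'
#' Non-target returns modelled by the same phase-modulation law with the body
#' term absent (A1 = 0): radar shake from wind (frequency at or below 5 Hz,
#' large excursion) or mechanical coupling with a vibration source (50 Hz).
#'
#' @param kind "wind" or "vibration"
#' @param amplitude harmonic range excursion A_H in metres
#' @param frequency modulation frequency in Hz (omega_H / 2 pi); wind must be
#'   <= 5 Hz, vibration is fixed at 50 Hz
#' @param a2 scattering amplitude of the clutter term
#' @return an object of class `clutter_spec`
#' @export
clutter_spec <- function(kind = c("wind", "vibration"), amplitude = 0.003,
                         frequency = if (kind[1] == "wind") 2 else 50,
                         a2 = 0.1) {
  kind <- match.arg(kind)
  stopifnot(amplitude >= 0, a2 >= 0)
  if (kind == "wind" && frequency > 5)
    stop("wind clutter frequency must be <= 5 Hz")
  if (kind == "vibration" && frequency != 50)
    stop("vibration clutter frequency is fixed at 50 Hz")
  structure(list(kind = kind, amplitude = amplitude,
                 frequency = frequency, a2 = a2),
            class = "clutter_spec")
}

#' A single labelled flight event on a timeline
#'
#' @param label "inward", "outward" or "hover"
#' @param start,end event span in seconds, 0-based at recording start,
#'   half-open `[start, end)`
#' @param motion a [motion_profile] with `duration == end - start`
#' @param scatterer a [scatterer_spec]
#' @param wingbeat a [wingbeat_spec]
#' @return an object of class `bee_event`
#' @export
bee_event <- function(label, start, end, motion,
                      scatterer = scatterer_spec(),
                      wingbeat = wingbeat_spec()) {
  label <- match.arg(label, EVENT_LEVELS)
  stopifnot(start >= 0, end > start,
            inherits(motion, "motion_profile"),
            inherits(scatterer, "scatterer_spec"),
            inherits(wingbeat, "wingbeat_spec"))
  if (abs(motion$duration - (end - start)) > 1e-9)
    stop("motion$duration must equal end - start")
  structure(list(label = label, start = start, end = end, motion = motion,
                 scatterer = scatterer, wingbeat = wingbeat),
            class = "bee_event")
}

#' Ground-truth event timeline for one recording
#'
#' @param events list of [bee_event], any order (sorted by start on creation)
#' @param total_duration recording duration in seconds
#' @param clutter list of [clutter_spec] active over the whole recording
#' @return an object of class `event_timeline`
#' @export
event_timeline <- function(events = list(), total_duration, clutter = list()) {
  stopifnot(total_duration > 0)
  lapply(events, function(e) stopifnot(inherits(e, "bee_event")))
  lapply(clutter, function(cl) stopifnot(inherits(cl, "clutter_spec")))
  for (e in events)
    if (e$end > total_duration + 1e-9)
      stop(sprintf("event [%g, %g) extends past total_duration %g",
                   e$start, e$end, total_duration))
  if (length(events) > 1) {
    ord <- order(vapply(events, `[[`, numeric(1), "start"))
    events <- events[ord]
  }
  structure(list(events = events, total_duration = total_duration,
                 clutter = clutter),
            class = "event_timeline")
}

#' Two-channel IQ baseband recording
#'
#' Channel i holds the in-phase mixer output, channel q the quadrature output;
#' `i + 1i*q` is the complex baseband whose spectrum separates approaching
#' (positive frequency) from receding (negative frequency) targets.
#'
#' @param i,q equal-length numeric vectors
#' @param sample_rate sampling rate in Hz
#' @return an object of class `iq_recording`
#' @export
iq_recording <- function(i, q, sample_rate) {
  stopifnot(length(i) == length(q), sample_rate > 0)
  structure(list(i = as.numeric(i), q = as.numeric(q),
                 sample_rate = sample_rate,
                 duration = length(i) / sample_rate),
            class = "iq_recording")
}

#' @export
print.iq_recording <- function(x, ...) {
  cat(sprintf("<iq_recording> %d samples @ %g Hz (%.3f s)\n",
              length(x$i), x$sample_rate, x$duration))
  invisible(x)
}

#' @export
print.event_timeline <- function(x, ...) {
  cat(sprintf("<event_timeline> %.2f s, %d events, %d clutter sources\n",
              x$total_duration, length(x$events), length(x$clutter)))
  for (e in x$events)
    cat(sprintf("  %-8s %7.3f - %7.3f s\n", e$label, e$start, e$end))
  invisible(x)
}

# complex baseband view of a recording
as_complex <- function(rec) rec$i + 1i * rec$q
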
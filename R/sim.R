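#' Draw a randomised flight motion profile for an activity class
#'
#' Builds R(t) kinematics matching the qualitative flight behaviour of each
#' class at the hive entrance, with the radar placed 1-2 m from the hive:
#'
#' * `outward`: the bee accelerates from rest up to a cruise speed in
#'   1.1-1.9 m/s and closes on the radar, passing it in proximity near the end
#'   of the event, so the radial speed ramps up and then rolls off only at the
#'   closest approach.
#' * `inward`: the bee arrives at 0.5-1.5 m/s moving away from the radar
#'   towards the entrance and decelerates to rest; radial speed in the final
#'   tenth of the event is essentially zero.
#' * `hover`: bounded low-frequency oscillatory radial motion around a fixed
#'   stand-off, with peak radial speed below 0.5 m/s.
#'
#' @param class_label "inward", "outward" or "hover"
#' @param seed integer seed for the draw (NULL uses the current RNG state)
#' @param duration event duration in seconds (default drawn in 0.8-1.4 s)
#' @param kinematic_ranges optional list overriding the speed ranges:
#'   `outward_vmax` (c(lo, hi) m/s), `inward_v0`, `hover_vmax`
#' @return a [motion_profile]
#' @export
make_flight_profile <- function(class_label, seed = NULL, duration = NULL,
                                kinematic_ranges = list()) {
  if (!is.character(class_label) || length(class_label) != 1 ||
      !(class_label %in% EVENT_LEVELS))
    stop("unknown class_label '", paste(class_label, collapse = ","),
         "'; expected one of ", paste(EVENT_LEVELS, collapse = ", "))
  kr <- modifyList(list(outward_vmax = c(1.1, 1.9),
                        inward_v0 = c(0.5, 1.5),
                        hover_vmax = c(0.15, 0.4)), kinematic_ranges)
  with_seed(seed, {
    if (is.null(duration)) duration <- runif(1, 0.8, 1.4)
    T <- duration
    fn <- switch(class_label,
      outward = {
        # speed ramp reaching vmax halfway; straight path passing the radar
        # at lateral offset rmin just before the event ends
        vmax <- runif(1, kr$outward_vmax[1], kr$outward_vmax[2])
        rmin <- runif(1, 0.10, 0.20)
        # distance travelled by time t under v(t) = vmax*min(1, 2t/T)
        dist <- function(t) {
          th <- pmin(t, T / 2)
          vmax * th^2 / T + vmax * pmax(0, t - T / 2)
        }
        p0 <- min(dist(0.92 * T), sqrt(9 - rmin^2) - 1e-3)  # crosses 0 late
        function(t) sqrt(rmin^2 + (p0 - dist(t))^2)
      },
      inward = {
        # linear deceleration to rest just before entry (the labelled event
        # ends when the bee enters the hive), range increasing towards the
        # hive stand-off
        v0 <- runif(1, kr$inward_v0[1], kr$inward_v0[2])
        rend <- runif(1, 1.0, 2.0)
        tstop <- 0.93 * T
        dtot <- v0 * tstop / 2
        if (rend - dtot < 0.1) {
          v0 <- 2 * (rend - 0.1) / tstop
          dtot <- v0 * tstop / 2
        }
        function(t) {
          th <- pmin(t, tstop)
          rend - dtot + (v0 * th - v0 * th^2 / (2 * tstop))
        }
      },
      hover = {
        # two incommensurate slow sinusoids around the stand-off range
        r0 <- runif(1, 0.5, 1.5)
        f1 <- runif(1, 0.5, 2.5)
        f2 <- runif(1, 2.5, 5)
        vpk <- runif(1, kr$hover_vmax[1], kr$hover_vmax[2])
        a1 <- 0.7 * vpk / (2 * pi * f1)
        a2 <- 0.3 * vpk / (2 * pi * f2)
        ph1 <- runif(1, 0, 2 * pi)
        ph2 <- runif(1, 0, 2 * pi)
        function(t) r0 + a1 * sin(2 * pi * f1 * t + ph1) +
          a2 * sin(2 * pi * f2 * t + ph2)
      })
    motion_profile(class_label, fn, duration)
  })
}

#' Synthesize the IQ return of a single flight event
#'
#' Generates the complex baseband return of a body scatterer plus a harmonic
#' wing scatterer,
#' \deqn{x(t) = A_1 e^{-j 4\pi R(t)/\lambda} +
#'       A_2 e^{-j 4\pi [R(t) + A_H\cos(\omega_H t)]/\lambda},}
#' sampled at the radar sampling rate. The in-phase channel is the real part
#' (the printed real-valued return model) and the quadrature channel the
#' imaginary part; with the negative phase sign an approaching target
#' (decreasing R) lands at positive frequencies of the complex spectrum.
#'
#' @param event a [bee_event]
#' @param config a [radar_config]
#' @return an [iq_recording] of length `duration * sample_rate`
#' @export
synthesize_event <- function(event, config) {
  stopifnot(inherits(event, "bee_event"), inherits(config, "radar_config"))
  dur <- event$end - event$start
  fs <- config$sample_rate
  fh <- event$wingbeat$angular_frequency / (2 * pi)
  if (fh > fs / 2)
    warning(sprintf(
      "wingbeat frequency %.0f Hz exceeds Nyquist %.0f Hz; line will alias",
      fh, fs / 2))
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  R <- event$motion$range_fn(t)
  lam <- config$wavelength
  k <- 4 * pi / lam
  wing <- event$wingbeat$amplitude *
    cos(event$wingbeat$angular_frequency * t)
  x <- event$scatterer$body_amplitude * exp(-1i * k * R) +
    event$scatterer$wing_amplitude * exp(-1i * k * (R + wing))
  iq_recording(Re(x), Im(x), fs)
}

#' Synthesize the IQ return of a clutter source
#'
#' The same phase-modulation law with the body term removed (A1 = 0) and the
#' range harmonically modulated: wind shake concentrates power near DC and its
#' low-order modulation harmonics; a 50 Hz vibration source puts lines at
#' multiples of 50 Hz.
#'
#' @param spec a [clutter_spec]
#' @param config a [radar_config]
#' @param duration seconds
#' @param r0 static stand-off range in metres
#' @return an [iq_recording]
#' @export
synthesize_clutter <- function(spec, config, duration, r0 = 1) {
  stopifnot(inherits(spec, "clutter_spec"), inherits(config, "radar_config"),
            duration > 0)
  fs <- config$sample_rate
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  k <- 4 * pi / config$wavelength
  R <- r0 + spec$amplitude * cos(2 * pi * spec$frequency * t)
  x <- spec$a2 * exp(-1i * k * R)
  iq_recording(Re(x), Im(x), fs)
}

#' Apply the modelled receiver chain to a recording
#'
#' First-order IF low-pass at `config$if_cutoff` (bilinear-transform IIR,
#' prewarped so the -3 dB point sits exactly at the cutoff) on both channels,
#' then additive white Gaussian noise of RMS `config$noise_rms` per channel,
#' then an optional faint equipment tone near 1 kHz with a random phase.
#' With noise and tone amplitudes at zero no randomness is consumed and the
#' output is exactly the filtered input.
#'
#' @param rec an [iq_recording]
#' @param config a [radar_config]
#' @param seed integer seed for the stochastic stages (NULL uses current RNG)
#' @return an [iq_recording] of identical length
#' @export
apply_receiver_chain <- function(rec, config, seed = NULL) {
  stopifnot(inherits(rec, "iq_recording"), inherits(config, "radar_config"))
  i <- first_order_lowpass(rec$i, config$if_cutoff, rec$sample_rate)
  q <- first_order_lowpass(rec$q, config$if_cutoff, rec$sample_rate)
  if (config$noise_rms > 0 || config$tone_1khz_amplitude > 0) {
    n <- length(i)
    with_seed(seed, {
      if (config$noise_rms > 0) {
        i <- i + rnorm(n, 0, config$noise_rms)
        q <- q + rnorm(n, 0, config$noise_rms)
      }
      if (config$tone_1khz_amplitude > 0) {
        t <- (seq_len(n) - 1) / rec$sample_rate
        ph <- runif(1, 0, 2 * pi)
        # narrowband equipment pickup enters both channels coherently
        tone <- config$tone_1khz_amplitude * cos(2 * pi * 1000 * t + ph)
        i <- i + tone
        q <- q + config$tone_1khz_amplitude * sin(2 * pi * 1000 * t + ph)
      }
    })
  }
  iq_recording(i, q, rec$sample_rate)
}

#' Compose a full hive-entrance scene from a ground-truth timeline
#'
#' Superposes the IQ returns of every event (each placed at its start time)
#' and every clutter source, then applies the receiver chain. Deterministic
#' given `seed`.
#'
#' @param timeline an [event_timeline]
#' @param config a [radar_config]
#' @param seed integer seed driving the receiver-chain randomness
#' @param receiver apply the receiver chain (set FALSE for the raw superposition)
#' @return list with elements `recording` ([iq_recording]) and `timeline`
#'   (the unchanged ground truth)
#' @export
compose_scene <- function(timeline, config, seed = 1L, receiver = TRUE) {
  stopifnot(inherits(timeline, "event_timeline"),
            inherits(config, "radar_config"))
  fs <- config$sample_rate
  n <- round(timeline$total_duration * fs)
  i <- numeric(n)
  q <- numeric(n)
  for (e in timeline$events) {
    er <- synthesize_event(e, config)
    i0 <- round(e$start * fs)
    idx <- i0 + seq_along(er$i)
    if (max(idx) > n)
      stop("event extends past total_duration")
    i[idx] <- i[idx] + er$i
    q[idx] <- q[idx] + er$q
  }
  for (cl in timeline$clutter) {
    cr <- synthesize_clutter(cl, config, timeline$total_duration)
    m <- min(n, length(cr$i))
    i[1:m] <- i[1:m] + cr$i[1:m]
    q[1:m] <- q[1:m] + cr$q[1:m]
  }
  rec <- iq_recording(i, q, fs)
  if (receiver)
    rec <- apply_receiver_chain(rec, config, seed = seed)
  list(recording = rec, timeline = timeline)
}
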
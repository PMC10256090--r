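# shared fixture builders; everything is generated in code at test time

# complex tone as an IQ recording
tone_iq <- function(freq, fs = 44100, dur = 1) {
  t <- (seq_len(round(fs * dur)) - 1) / fs
  iq_recording(cos(2 * pi * freq * t), sin(2 * pi * freq * t), fs)
}

# event moving at constant radial speed; v > 0 recedes, v < 0 approaches
const_speed_event <- function(v, dur = 1, r0 = if (v >= 0) 0.3 else 2.5,
                              a1 = 1, a2 = 0, wing = wingbeat_spec(0, 0)) {
  cls <- if (v >= 0) "inward" else "outward"
  mo <- motion_profile(cls, function(t) r0 + v * t, dur)
  bee_event(cls, 0, dur, mo, scatterer_spec(a1, a2), wing)
}

# static-range event with pure wingbeat modulation
wingbeat_event <- function(AH, fh, dur = 1, r0 = 1, a2 = 1) {
  mo <- motion_profile("hover", function(t) rep(r0, length(t)), dur)
  bee_event("hover", 0, dur, mo, scatterer_spec(0, a2),
            wingbeat_spec(AH, 2 * pi * fh))
}

# well-separated Gaussian blobs for classifier tests
blob_features <- function(n_per_class, classes, d = 4, sep = 6, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(classes), function(k) {
    mu <- numeric(d)
    mu[(k - 1) %% d + 1] <- sep * ((k + 1) %/% 2)
    matrix(rnorm(n_per_class * d, mean = rep(mu, each = n_per_class)),
           n_per_class, d)
  }))
  list(x = x, labels = rep(classes, each = n_per_class))
}

# white-noise IQ recording
noise_rec <- function(dur, fs = 44100, seed = 1) {
  set.seed(seed)
  n <- round(dur * fs)
  iq_recording(rnorm(n), rnorm(n), fs)
}

# amplitude of the spectral line closest to f in the complex spectrum
line_amp <- function(rec, f) {
  sp <- beedar:::complex_spectrum(beedar:::as_complex(rec), rec$sample_rate)
  sp$amp[which.min(abs(sp$freq - f))]
}

peak_freq <- function(rec) {
  sp <- beedar:::complex_spectrum(beedar:::as_complex(rec), rec$sample_rate)
  sp$freq[which.max(sp$amp)]
}
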
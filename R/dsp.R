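#' First-order low-pass IIR filter
#'
#' Bilinear-transform discretisation of the analog RC low-pass
#' `H(s) = 1 / (1 + s/wc)`, prewarped so the digital -3 dB point falls
#' exactly at `cutoff`.
#'
#' @param x numeric signal
#' @param cutoff -3 dB frequency in Hz
#' @param fs sampling rate in Hz
#' @return filtered signal of the same length
#' @export
first_order_lowpass <- function(x, cutoff, fs) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  wa <- tan(pi * cutoff / fs)  # prewarped analog corner (normalised)
  b0 <- wa / (1 + wa)
  a1 <- (1 - wa) / (1 + wa)
  v <- b0 * (x + c(0, x[-length(x)]))
  as.numeric(stats::filter(v, a1, method = "recursive"))
}

# windowed-sinc FIR low-pass taps (Hamming window), odd length
sinc_lowpass_taps <- function(cutoff_norm, half_len) {
  n <- seq(-half_len, half_len)
  h <- 2 * cutoff_norm * ifelse(n == 0, 1, sin(2 * pi * cutoff_norm * n) /
                                  (2 * pi * cutoff_norm * n))
  w <- 0.54 + 0.46 * cos(pi * n / half_len)
  h * w / sum(h * w)
}

#' Anti-aliased rational-ratio resampling of an IQ recording
#'
#' Resamples both channels by the reduced rational factor p/q (zero-stuff by
#' p, windowed-sinc low-pass at the smaller of the two Nyquist limits,
#' decimate by q). Duration is preserved to within one output sample.
#'
#' @param rec an [iq_recording]
#' @param target_rate new sampling rate in Hz (must not exceed the original)
#' @return an [iq_recording] at `target_rate`
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "iq_recording"))
  if (target_rate <= 0) stop("target_rate must be positive")
  if (target_rate > rec$sample_rate)
    stop("upsampling not supported: target_rate exceeds the source rate")
  if (target_rate == rec$sample_rate) return(rec)
  g <- gcd_int(round(target_rate), round(rec$sample_rate))
  p <- round(target_rate) / g
  q <- round(rec$sample_rate) / g
  iq_recording(resample_channel(rec$i, p, q),
               resample_channel(rec$q, p, q),
               target_rate)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# polyphase evaluation: convolves the (conceptually) zero-stuffed signal with
# the windowed-sinc taps, but only at the q-strided output points
resample_channel <- function(x, p, q) {
  n <- length(x)
  if (p == 1 && q == 1) return(x)
  m <- max(p, q)
  hl <- 10L * m
  h <- sinc_lowpass_taps(1 / (2 * m), half_len = hl)
  nout <- ceiling(n * p / q)
  .polyphase_resample(x, h, as.integer(p), as.integer(q),
                      as.integer(hl), as.integer(nout))
}

#' Short-time Fourier transform magnitude, cropped to a frequency band
#'
#' Complex STFT of `i + 1i*q` with a Hamming window; rows are frequency bins
#' in `[0, fmax]` (the complex spectrum is shifted so negative frequencies
#' fold in only when `two_sided = TRUE`). For figures and debugging.
#'
#' @param rec an [iq_recording] (or a window sample's recording)
#' @param fmax upper frequency bound in Hz
#' @param nfft FFT length per frame
#' @param hop hop size in samples
#' @param two_sided include negative frequencies of the complex spectrum
#' @return list with `magnitude` (freq x time matrix), `freq` (Hz), `time` (s)
#' @export
iq_spectrogram <- function(rec, fmax = 150, nfft = 1024L,
                           hop = nfft %/% 4L, two_sided = FALSE) {
  stopifnot(inherits(rec, "iq_recording"))
  fs <- rec$sample_rate
  if (fmax > fs / 2) stop("fmax exceeds Nyquist")
  x <- as_complex(rec)
  n <- length(x)
  nfft <- min(nfft, n)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nfft) / (nfft + 1))
  starts <- seq(1, max(1, n - nfft + 1), by = max(1L, hop))
  spec <- vapply(starts, function(s) {
    abs(fft(x[s:(s + nfft - 1)] * w))
  }, numeric(nfft))
  freq <- (seq_len(nfft) - 1) * fs / nfft
  freq[freq > fs / 2] <- freq[freq > fs / 2] - fs
  if (two_sided) {
    keep <- abs(freq) <= fmax
  } else {
    keep <- freq >= 0 & freq <= fmax
  }
  ord <- order(freq[keep])
  mag <- spec[keep, , drop = FALSE][ord, , drop = FALSE]
  list(magnitude = mag, freq = sort(freq[keep]),
       time = (starts - 1 + nfft / 2) / fs)
}

# single-sided amplitude spectrum of a complex vector; returns freq (signed)
# and amplitude per line, used throughout the tests and analyses
complex_spectrum <- function(x, fs) {
  n <- length(x)
  a <- abs(fft(x)) / n
  f <- (seq_len(n) - 1) * fs / n
  f[f >= fs / 2] <- f[f >= fs / 2] - fs
  list(freq = f, amp = a)
}
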
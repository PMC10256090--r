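test_that("resampling preserves in-band tones and rejects out-of-band ones", {
  rec <- tone_iq(100, 44100, 1)
  expect_identical(resample_recording(rec, 44100), rec)

  r2 <- resample_recording(rec, 3500)
  expect_equal(length(r2$i), 3500, tolerance = 1)  # duration preserved
  expect_equal(line_amp(r2, 100), 1, tolerance = 0.01)

  # 2 kHz is above the 1.5 kHz Nyquist of a 3 kHz rate: > 20 dB down
  r3 <- resample_recording(tone_iq(2000, 44100, 1), 3000)
  sp <- beedar:::complex_spectrum(beedar:::as_complex(r3), 3000)
  expect_lt(max(sp$amp), 0.1)

  expect_error(resample_recording(rec, 0), "positive")
  expect_error(resample_recording(rec, 48000), "exceeds the source")
})

test_that("LPC recovers an AR(1) reflection coefficient", {
  set.seed(1)
  e <- rnorm(1e5)
  x <- as.numeric(stats::filter(e, 0.5, method = "recursive"))
  # independent oracle: lag-1 sample autocorrelation ratio r1/r0
  n <- length(x)
  k1_oracle <- sum(x[-1] * x[-n]) / sum(x^2)
  m <- compute_lpc(x, 1, taper = FALSE)
  expect_equal(m$reflection_coefficients[1], 0.5, tolerance = 0.05)
  expect_equal(m$reflection_coefficients[1], k1_oracle, tolerance = 1e-3)
  expect_equal(m$prediction_coefficients[1], m$reflection_coefficients[1])
})

test_that("LPC handles degenerate input and stays stable", {
  z <- compute_lpc(numeric(500), 8)
  expect_equal(z$reflection_coefficients, numeric(8))
  expect_equal(z$gain, 0)

  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(400) + sin(2 * pi * 0.05 * (1:400) + runif(1))
    m <- compute_lpc(x, 20)
    expect_true(all(abs(m$reflection_coefficients) < 1))
    # whitening: residual power non-increasing in order
    gains <- vapply(c(1, 2, 5, 10, 20),
                    function(p) compute_lpc(x, p)$gain, numeric(1))
    expect_true(all(diff(gains) <= 1e-12))
  }

  expect_error(compute_lpc(rnorm(10), 10), "more samples")
  expect_error(compute_lpc(rnorm(10), 0))
})

test_that("log area ratios match their closed form and invert", {
  expect_equal(lar_transform(0), 0)
  expect_equal(lar_transform(0.5), log(1 / 3))
  expect_equal(lar_transform(-0.5), -log(1 / 3))
  k <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(lar_transform(-k), -lar_transform(k))  # odd symmetry
  expect_equal(lar_inverse(lar_transform(k)), k, tolerance = 1e-9)
  # clamping keeps the transform total at |k| = 1
  expect_true(is.finite(lar_transform(1)))
})

test_that("feature vectors have the configured layout and scale invariance", {
  w <- noise_rec(0.4, seed = 3)

  fv <- extract_features(w, feature_spec(44100, order = 110,
                                         sub_window_len = 0.2))
  expect_length(fv$values, 2 * 2 * 110)  # 220 per channel

  fv2 <- extract_features(w, feature_spec(44100, order = 240, channels = "i"))
  expect_length(fv2$values, 240)

  # amplitude scaling leaves reflection coefficients (hence LARs) unchanged
  w10 <- iq_recording(10 * w$i, 10 * w$q, 44100)
  expect_equal(extract_features(w10, feature_spec(44100, 60))$values,
               extract_features(w, feature_spec(44100, 60))$values,
               tolerance = 1e-9)

  expect_error(extract_features(noise_rec(0.6), feature_spec(44100, 60)),
               "does not match")
  expect_error(feature_spec(44100, order = 100, sub_window_len = 0.3),
               "divide")
  expect_error(feature_spec(3500, order = 2000))
})

test_that("spectral envelopes behave like the model spectra they compress", {
  # white model: flat positive envelope
  m0 <- compute_lpc(rnorm(1000), 1)
  m0$prediction_coefficients[1] <- 0
  m0$gain <- 1
  env0 <- spectral_envelope(m0, seq(0, 500, 50), 1000)
  expect_equal(env0, rep(1, 11))

  # AR(1), a = 0.9: monotone decreasing, matching the closed form
  m <- structure(list(order = 1, prediction_coefficients = 0.9,
                      reflection_coefficients = 0.9, gain = 1),
                 class = "lpc_model")
  f <- seq(0, 500, length.out = 64)
  env <- spectral_envelope(m, f, 1000)
  oracle <- 1 / Mod(1 - 0.9 * exp(-1i * 2 * pi * f / 1000))
  expect_equal(env, oracle, tolerance = 1e-12)
  expect_true(all(diff(env) < 0))
  expect_true(all(env >= 0))
  expect_error(spectral_envelope(m, c(-1, 10), 1000))
})

test_that("spectrograms localise tones and track outward acceleration", {
  sg <- iq_spectrogram(tone_iq(100, 44100, 1), fmax = 150)
  ridge <- sg$freq[apply(sg$magnitude, 2, which.max)]
  expect_true(all(abs(ridge - 100) < 44100 / 1024))

  expect_error(iq_spectrogram(tone_iq(100, 1000, 1), fmax = 600), "Nyquist")

  z <- iq_recording(numeric(4096), numeric(4096), 44100)
  expect_equal(max(iq_spectrogram(z, fmax = 150)$magnitude), 0)

  # outward flight: magnitude-weighted |f| rises from early to late frames
  rc <- radar_config(noise_rms = 0)
  mo <- make_flight_profile("outward", seed = 4)
  ev <- bee_event("outward", 0, mo$duration, mo,
                  scatterer_spec(1, 0), wingbeat_spec(0, 0))
  rec <- synthesize_event(ev, rc)
  sg <- iq_spectrogram(rec, fmax = 150, two_sided = TRUE)
  wmean <- function(j) sum(abs(sg$freq) * sg$magnitude[, j]) /
    sum(sg$magnitude[, j])
  nf <- ncol(sg$magnitude)
  early <- mean(vapply(1:ceiling(nf / 4), wmean, numeric(1)))
  late <- mean(vapply((nf - ceiling(nf / 4)):nf, wmean, numeric(1)))
  expect_gt(late, early)
})
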
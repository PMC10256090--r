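#' Linear predictive coding by the autocorrelation method
#'
#' Fits an order-`order` all-pole model to `samples` with a Hamming taper,
#' biased autocorrelation estimates and the Levinson-Durbin recursion.
#' Returns prediction coefficients `a` (signal model
#' `x_n = sum_k a_k x_{n-k} + e_n`), the per-order reflection (partial
#' correlation) coefficients `k`, and the residual gain. A zero-energy input
#' maps to the all-zero model (`k = 0`) rather than an error.
#'
#' @param samples numeric vector, length > order
#' @param order model order (>= 1)
#' @param taper apply a Hamming taper before autocorrelation (speech
#'   convention; set FALSE for raw autocorrelation)
#' @return an object of class `lpc_model` with fields `order`,
#'   `prediction_coefficients`, `reflection_coefficients`, `gain`
#' @export
compute_lpc <- function(samples, order, taper = TRUE) {
  stopifnot(order >= 1)
  n <- length(samples)
  if (n <= order) stop("need more samples than the model order")
  x <- as.numeric(samples)
  if (taper) {
    w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    x <- x * w
  }
  r <- autocorr_fft(x, order)
  if (r[1] <= 0) {
    return(structure(list(order = order,
                          prediction_coefficients = numeric(order),
                          reflection_coefficients = numeric(order),
                          gain = 0),
                     class = "lpc_model"))
  }
  ld <- levinson_durbin(r, order)
  structure(list(order = order,
                 prediction_coefficients = ld$a,
                 reflection_coefficients = ld$k,
                 gain = sqrt(max(ld$err, 0))),
            class = "lpc_model")
}

# biased autocorrelation r[0..order] via FFT
autocorr_fft <- function(x, order) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- fft(c(x, numeric(nfft - n)))
  r <- Re(fft(Mod(X)^2, inverse = TRUE)) / nfft / n
  r[1:(order + 1)]
}

# Levinson-Durbin recursion on autocorrelations r[1] = r0 .. r[p+1] = rp
levinson_durbin <- function(r, p) {
  a <- numeric(p)    # prediction coefficients (x_n ~ sum a_k x_{n-k})
  k <- numeric(p)
  err <- r[1]
  for (m in seq_len(p)) {
    if (err <= 0) break  # numerically exhausted; remaining k stay 0
    acc <- r[m + 1]
    if (m > 1) acc <- acc - sum(a[1:(m - 1)] * r[m:2])
    km <- acc / err
    k[m] <- km
    a_new <- a
    a_new[m] <- km
    if (m > 1) a_new[1:(m - 1)] <- a[1:(m - 1)] - km * a[(m - 1):1]
    a <- a_new
    err <- err * (1 - km^2)
  }
  list(a = a, k = k, err = err)
}

#' Log Area Ratios from reflection coefficients
#'
#' `LAR_i = log((1 - k_i) / (1 + k_i))`, elementwise. Reflection coefficients
#' are clamped to `|k| <= 1 - 1e-6` first so the transform is total.
#'
#' @param k numeric vector of reflection coefficients (or an `lpc_model`)
#' @return numeric vector of LARs, same length and order
#' @export
lar_transform <- function(k) {
  if (inherits(k, "lpc_model")) k <- k$reflection_coefficients
  k <- pmax(pmin(k, 1 - 1e-6), -1 + 1e-6)
  log((1 - k) / (1 + k))
}

#' Inverse of [lar_transform]
#' @param g numeric vector of LARs
#' @return reflection coefficients
#' @export
lar_inverse <- function(g) (1 - exp(g)) / (1 + exp(g))

#' Feature extraction specification
#'
#' @param sample_rate rate the windows are (re)sampled at, Hz
#' @param order LPC order per sub-window (240 is the full-window budget at
#'   44.1 kHz; 100 at 3.5 kHz)
#' @param sub_window_len sub-window length in seconds; must divide the window
#'   length into an integer number of non-overlapping sub-windows. NULL means
#'   the full window.
#' @param channels "iq" (both channels, concatenated channel-major) or "i"
#' @param window_len analysis window length in seconds
#' @return an object of class `feature_spec`
#' @export
feature_spec <- function(sample_rate = 44100, order = 240,
                         sub_window_len = NULL, channels = c("iq", "i"),
                         window_len = 0.4) {
  channels <- match.arg(channels)
  if (is.null(sub_window_len)) sub_window_len <- window_len
  ratio <- window_len / sub_window_len
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("sub_window_len must divide window_len exactly")
  if (order >= sub_window_len * sample_rate)
    stop("order must be below the per-sub-window sample count")
  structure(list(sample_rate = sample_rate, order = order,
                 sub_window_len = sub_window_len, channels = channels,
                 window_len = window_len,
                 n_sub_windows = as.integer(round(ratio)),
                 n_channels = if (channels == "iq") 2L else 1L),
            class = "feature_spec")
}

#' Extract the LAR feature vector of one window sample
#'
#' Per channel, the window is split into non-overlapping sub-windows; each
#' sub-window is LPC-encoded at `spec$order` and transformed to LARs. Values
#' are concatenated channel-major, then sub-window, then coefficient index,
#' for a total of `n_channels * n_sub_windows * order` features. Reflection
#' coefficients are ratios of autocorrelations, so features are invariant to
#' amplitude scaling of the input.
#'
#' @param window a `window_sample` (or an [iq_recording] of window length)
#' @param spec a [feature_spec]; the window is resampled to
#'   `spec$sample_rate` first when rates differ
#' @return list of class `feature_vector`: `values`, `spec`, `label`
#' @export
extract_features <- function(window, spec = feature_spec()) {
  rec <- if (inherits(window, "window_sample")) window$recording else window
  stopifnot(inherits(rec, "iq_recording"), inherits(spec, "feature_spec"))
  if (abs(rec$duration - spec$window_len) * rec$sample_rate > 1)
    stop(sprintf("window duration %.4f s does not match spec window_len %g s",
                 rec$duration, spec$window_len))
  if (rec$sample_rate != spec$sample_rate)
    rec <- resample_recording(rec, spec$sample_rate)
  chans <- if (spec$channels == "iq") list(rec$i, rec$q) else list(rec$i)
  nsw <- spec$n_sub_windows
  swn <- max(1L, floor(length(chans[[1]]) / nsw))
  vals <- unlist(lapply(chans, function(x) {
    unlist(lapply(seq_len(nsw), function(j) {
      seg <- x[((j - 1) * swn + 1):(j * swn)]
      lar_transform(compute_lpc(seg, spec$order))
    }))
  }))
  label <- if (inherits(window, "window_sample")) window$label else NA_character_
  structure(list(values = vals, spec = spec, label = label),
            class = "feature_vector")
}

#' Spectral envelope of an LPC model
#'
#' Evaluates `gain / |A(e^{j 2 pi f / fs})|` on a frequency grid, where
#' `A(z) = 1 - sum_k a_k z^-k` is the prediction-error polynomial.
#'
#' @param model an `lpc_model`
#' @param freq_grid frequencies in Hz, within `[0, sample_rate/2]`
#' @param sample_rate Hz
#' @return numeric vector of non-negative envelope magnitudes
#' @export
spectral_envelope <- function(model, freq_grid, sample_rate) {
  stopifnot(inherits(model, "lpc_model"),
            all(freq_grid >= 0), all(freq_grid <= sample_rate / 2))
  a <- model$prediction_coefficients
  z <- exp(-1i * 2 * pi * outer(freq_grid / sample_rate, seq_along(a)))
  A <- 1 - as.vector(z %*% a)
  g <- if (model$gain > 0) model$gain else 0
  g / pmax(Mod(A), 1e-12)
}
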
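#' Per-channel feature budget of a sub-windowing configuration
#'
#' `(window_len / sub_window_len) * order` LARs per channel, the budget
#' arithmetic behind the published sub-window table (e.g. 110 coefficients at
#' 200 ms sub-windows of a 400 ms window give 220 features per channel).
#'
#' @param window_len window length in seconds
#' @param sub_window_len sub-window length in seconds; must divide
#'   `window_len` exactly
#' @param order LPC order per sub-window
#' @return integer feature count per channel
#' @export
feature_budget <- function(window_len, sub_window_len, order) {
  stopifnot(window_len > 0, sub_window_len > 0, order >= 1)
  ratio <- window_len / sub_window_len
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("sub_window_len must divide window_len exactly")
  as.integer(round(ratio) * order)
}

#' Default order rule for sampling-rate sweeps
#'
#' Scales the LPC order proportionally to the sampling rate (100 coefficients
#' at 3.5 kHz) and caps it at the 240-coefficient full-rate budget.
#'
#' @param rate sampling rate in Hz
#' @return integer order
#' @export
default_order_rule <- function(rate) {
  as.integer(pmin(240, pmax(2, round(100 * rate / 3500))))
}

# shared sweep engine: evaluates cross-validated accuracy over a config grid
sweep_engine <- function(dataset, grid, spec_fn, pathway, seeds, folds,
                         hyperopt_budget, inner_folds) {
  if (is.character(pathway)) pathway <- pathway_spec(pathway)
  rows <- list()
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(grid))) {
    cfg <- grid[r, , drop = FALSE]
    spec <- tryCatch(spec_fn(cfg), error = function(e) NULL)
    feasible <- !is.null(spec)
    feats <- NULL
    if (feasible) {
      key <- paste(cfg, collapse = "|")
      if (!is.null(cache[[key]])) feats <- cache[[key]]
      else {
        feats <- dataset_features(dataset, spec)
        cache[[key]] <- feats
      }
    }
    for (sd in seeds) {
      acc <- NA_real_
      if (feasible) {
        m <- cross_validate(feats$x, feats$labels, pathway, folds = folds,
                            seed = sd, hyperopt_budget = hyperopt_budget,
                            inner_folds = inner_folds)
        acc <- m$accuracy
      }
      rows[[length(rows) + 1L]] <-
        cbind(cfg, data.frame(seed = sd, accuracy = acc, feasible = feasible))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", class(out))
  out
}

#' Accuracy versus sampling rate
#'
#' For each rate: resample-and-encode the dataset with the order given by
#' `order_rule`, then run stratified cross-validation of `pathway`; one row
#' per (rate, seed). Cells whose order is infeasible at the rate are marked
#' `feasible = FALSE`.
#'
#' @param dataset a window dataset from [simulate_window_dataset]
#' @param rates sampling rates in Hz (must not exceed the source rate)
#' @param pathway a [pathway_spec] or id
#' @param order_rule function rate -> LPC order
#' @param seeds training seeds averaged over
#' @param folds,hyperopt_budget,inner_folds cross-validation controls
#' @param channels "iq" or "i"
#' @return a `sweep_result` data frame: `rate, seed, accuracy, feasible`
#' @export
sweep_sampling_rate <- function(dataset, rates, pathway = "P1",
                                order_rule = default_order_rule,
                                seeds = 1:5, folds = 10L,
                                hyperopt_budget = 10, inner_folds = 3L,
                                channels = "iq") {
  grid <- data.frame(rate = rates)
  sweep_engine(dataset, grid, function(cfg) {
    feature_spec(sample_rate = cfg$rate, order = order_rule(cfg$rate),
                 channels = channels)
  }, pathway, seeds, folds, hyperopt_budget, inner_folds)
}

#' Accuracy versus LPC coefficient count across sampling rates
#'
#' @param orders LPC orders to test (full-window encoding)
#' @inheritParams sweep_sampling_rate
#' @return a `sweep_result` data frame: `order, rate, seed, accuracy, feasible`
#' @export
sweep_coefficients <- function(dataset, orders, rates = 44100,
                               pathway = "P1", seeds = 1:5, folds = 10L,
                               hyperopt_budget = 10, inner_folds = 3L,
                               channels = "iq") {
  stopifnot(all(orders >= 1))
  grid <- expand.grid(order = orders, rate = rates)
  sweep_engine(dataset, grid, function(cfg) {
    feature_spec(sample_rate = cfg$rate, order = cfg$order,
                 channels = channels)
  }, pathway, seeds, folds, hyperopt_budget, inner_folds)
}

#' Accuracy versus sub-window length
#'
#' @param sub_window_lens sub-window lengths in seconds; each must divide the
#'   0.4 s window
#' @inheritParams sweep_coefficients
#' @return a `sweep_result` data frame:
#'   `sub_window_len, order, rate, seed, accuracy, feasible`
#' @export
sweep_subwindow <- function(dataset, sub_window_lens, orders, rates = 44100,
                            pathway = "P1", seeds = 1:5, folds = 10L,
                            hyperopt_budget = 10, inner_folds = 3L,
                            channels = "iq") {
  for (sw in sub_window_lens)
    if (abs(0.4 / sw - round(0.4 / sw)) > 1e-9)
      stop(sprintf("sub-window %g s does not divide the 0.4 s window", sw))
  grid <- expand.grid(sub_window_len = sub_window_lens, order = orders,
                      rate = rates)
  sweep_engine(dataset, grid, function(cfg) {
    feature_spec(sample_rate = cfg$rate, order = cfg$order,
                 sub_window_len = cfg$sub_window_len, channels = channels)
  }, pathway, seeds, folds, hyperopt_budget, inner_folds)
}

#' Per-class standard deviation of spectral envelopes
#'
#' Encodes every window at a fixed LPC order, evaluates each spectral
#' envelope on a frequency grid up to `fmax`, and returns the pointwise
#' standard deviation across the samples of each class — peaks mark frequency
#' bands where a class varies most (bee body Doppler below 150 Hz, equipment
#' tone near 1 kHz in background).
#'
#' @param dataset a window dataset
#' @param fmax upper frequency bound in Hz (default 1500)
#' @param grid_size number of grid points
#' @param order LPC order used for every sample
#' @param channel "i" or "q" channel to analyse
#' @return list of `envelope_std_curve` objects (one per class), each with
#'   `class`, `freq`, `std`
#' @export
class_envelope_std <- function(dataset, fmax = 1500, grid_size = 256L,
                               order = 240, channel = "i") {
  windows <- if (!is.null(dataset$windows)) dataset$windows else dataset
  labels <- vapply(windows, `[[`, character(1), "label")
  fs <- windows[[1]]$recording$sample_rate
  stopifnot(fmax <= fs / 2)
  freq <- seq(0, fmax, length.out = grid_size)
  env <- t(vapply(windows, function(w) {
    x <- if (channel == "i") w$recording$i else w$recording$q
    spectral_envelope(compute_lpc(x, order), freq, fs)
  }, numeric(grid_size)))
  lapply(sort(unique(labels)), function(cls) {
    rows <- env[labels == cls, , drop = FALSE]
    if (nrow(rows) < 2) {
      warning(sprintf("class '%s' has fewer than 2 samples; zero curve", cls))
      s <- numeric(grid_size)
    } else {
      s <- apply(rows, 2, sd)
    }
    structure(list(class = cls, freq = freq, std = s),
              class = "envelope_std_curve")
  })
}
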
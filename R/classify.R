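#' Prediction pathway specifications
#'
#' Three ways of labelling a window as background / hover / inward / outward:
#' * `P1`: one four-way model.
#' * `P2`: background vs rest, then hover vs \{inward, outward\}, then
#'   inward vs outward — a cascade of binary stages.
#' * `P3`: background vs rest, then a three-way model.
#'
#' Each stage is a partition of the classes it may see into named groups; a
#' singleton group emits its class, a larger group is refined by the next
#' stage.
#'
#' @param id "P1", "P2" or "P3"
#' @return an object of class `pathway_spec`
#' @export
pathway_spec <- function(id = c("P1", "P2", "P3")) {
  id <- match.arg(id)
  stages <- switch(id,
    P1 = list(list(background = "background", hover = "hover",
                   inward = "inward", outward = "outward")),
    P2 = list(
      list(background = "background",
           rest = c("hover", "inward", "outward")),
      list(hover = "hover", inout = c("inward", "outward")),
      list(inward = "inward", outward = "outward")),
    P3 = list(
      list(background = "background",
           rest = c("hover", "inward", "outward")),
      list(hover = "hover", inward = "inward", outward = "outward")))
  structure(list(id = id, stages = stages), class = "pathway_spec")
}

# map labels to stage-group names; NA for labels outside the stage domain
stage_groups <- function(labels, stage) {
  out <- rep(NA_character_, length(labels))
  for (g in names(stage)) out[labels %in% stage[[g]]] <- g
  out
}

#' Train a classification pathway
#'
#' Each stage is an RBF-kernel SVM over standardized features; `C` and `gamma`
#' are chosen by Bayesian optimization (expected improvement over a Gaussian
#' process surrogate) of the stage's internal stratified cross-validation
#' accuracy, over `log10 C` in \[-3, 3\] and `log10 gamma` in \[-4, 1\].
#' Standardization statistics are fit on each stage's training subset only.
#' A stage whose training subset contains a single group degenerates to a
#' constant predictor with a warning.
#'
#' @param features numeric matrix (rows = samples) or list of
#'   `feature_vector`s
#' @param labels character vector of the four class labels
#' @param pathway a [pathway_spec] (or its id string)
#' @param hyperopt_budget objective evaluations for the Bayesian search
#' @param seed integer seed (drives the search and fold assignment)
#' @param inner_folds folds of the internal CV that scores hyperparameters
#' @return an object of class `trained_pathway`
#' @export
train_pathway <- function(features, labels, pathway = pathway_spec("P1"),
                          hyperopt_budget = 30, seed = 1L, inner_folds = 3L) {
  x <- features_matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (is.character(pathway)) pathway <- pathway_spec(pathway)
  fitted <- vector("list", length(pathway$stages))
  for (s in seq_along(pathway$stages)) {
    stage <- pathway$stages[[s]]
    grp <- stage_groups(labels, stage)
    sel <- !is.na(grp)
    xs <- x[sel, , drop = FALSE]
    ys <- grp[sel]
    if (length(unique(ys)) < 2) {
      warning(sprintf("pathway %s stage %d saw a single group ('%s'); using a constant predictor",
                      pathway$id, s, unique(ys)[1]))
      fitted[[s]] <- list(constant = unique(ys)[1], stage = stage)
      next
    }
    st <- standardizer_fit(xs)
    xz <- standardizer_apply(st, xs)
    sseed <- derive_seed(seed, s)
    obj <- function(par) {
      C <- 10^par[1]
      gamma <- 10^par[2]
      folds <- stratified_folds(ys, inner_folds, seed = sseed)
      accs <- vapply(seq_len(max(folds)), function(f) {
        tr <- folds != f
        fit <- svm_fit(xz[tr, , drop = FALSE], ys[tr], C = C, gamma = gamma)
        mean(predict(fit, xz[!tr, , drop = FALSE]) == ys[!tr])
      }, numeric(1))
      mean(accs)
    }
    opt <- bayes_optimize(obj, lower = c(-3, -4), upper = c(3, 1),
                          budget = hyperopt_budget, seed = sseed)
    fit <- svm_fit(xz, ys, C = 10^opt$par[1], gamma = 10^opt$par[2])
    fitted[[s]] <- list(model = fit, standardizer = st, stage = stage,
                        hyperparameters = c(C = 10^opt$par[1],
                                            gamma = 10^opt$par[2]),
                        cv_score = opt$value)
  }
  structure(list(pathway = pathway, stages = fitted, seed = seed),
            class = "trained_pathway")
}

#' @export
print.trained_pathway <- function(x, ...) {
  cat(sprintf("<trained_pathway> %s, %d stage(s)\n",
              x$pathway$id, length(x$stages)))
  invisible(x)
}

#' Predict labels with a trained pathway
#'
#' Applies the stage cascade: samples predicted into a singleton group stop
#' with that class; samples in a composite group are forwarded to the next
#' stage. Every sample receives exactly one of the four labels.
#'
#' @param object a `trained_pathway`
#' @param newdata feature matrix or list of `feature_vector`s
#' @param ... unused
#' @return character vector of labels
#' @export
predict.trained_pathway <- function(object, newdata, ...) {
  x <- features_matrix(newdata)
  n <- nrow(x)
  out <- rep(NA_character_, n)
  pending <- seq_len(n)
  for (fs in object$stages) {
    if (length(pending) == 0) break
    stage <- fs$stage
    if (!is.null(fs$constant)) {
      grp <- rep(fs$constant, length(pending))
    } else {
      xz <- standardizer_apply(fs$standardizer, x[pending, , drop = FALSE])
      grp <- predict(fs$model, xz)
    }
    nxt <- integer(0)
    for (g in unique(grp)) {
      members <- stage[[g]]
      idx <- pending[grp == g]
      if (length(members) == 1) out[idx] <- members
      else nxt <- c(nxt, idx)
    }
    pending <- sort(nxt)
  }
  if (any(is.na(out))) stop("pathway failed to label every sample")
  out
}

# deterministic stratified fold assignment: 1..k per sample
stratified_folds <- function(labels, k, seed = 1L) {
  with_seed(seed, {
    folds <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    folds
  })
}

#' Stratified k-fold cross-validation of a pathway
#'
#' Standardization and the Bayesian hyperparameter search are re-run inside
#' every training fold (no leakage into held-out folds). Scalar metrics are
#' averaged over folds; confusion matrices are summed.
#'
#' @inheritParams train_pathway
#' @param folds number of folds (default 10); reduced with a warning if the
#'   smallest class has fewer members
#' @return a `pathway_metrics` object (averaged), with per-fold metrics in
#'   `$per_fold`
#' @export
cross_validate <- function(features, labels, pathway = pathway_spec("P1"),
                           folds = 10L, seed = 1L, hyperopt_budget = 30,
                           inner_folds = 3L) {
  x <- features_matrix(features)
  labels <- as.character(labels)
  if (folds < 2) stop("folds must be >= 2")
  smallest <- min(table(labels))
  if (smallest < folds) {
    warning(sprintf("smallest class has %d members; reducing folds from %d",
                    smallest, folds))
    folds <- max(2L, smallest)
  }
  fa <- stratified_folds(labels, folds, seed = seed)
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fa != f
    tp <- train_pathway(x[tr, , drop = FALSE], labels[tr], pathway,
                        hyperopt_budget = hyperopt_budget,
                        seed = derive_seed(seed, 100 + f),
                        inner_folds = inner_folds)
    compute_metrics(labels[!tr], predict(tp, x[!tr, , drop = FALSE]))
  })
  avg <- list(
    accuracy = mean(vapply(per_fold, `[[`, numeric(1), "accuracy")),
    precision = mean(vapply(per_fold, `[[`, numeric(1), "precision")),
    recall = mean(vapply(per_fold, `[[`, numeric(1), "recall")),
    f1_macro = mean(vapply(per_fold, `[[`, numeric(1), "f1_macro")),
    confusion = Reduce(`+`, lapply(per_fold, `[[`, "confusion")),
    per_fold = per_fold, folds = folds
  )
  structure(avg, class = "pathway_metrics")
}

#' Classification metrics
#'
#' Accuracy, support-weighted precision and recall, macro-averaged F1 and the
#' confusion matrix (true labels in rows). Per-class ratios with an empty
#' denominator count as zero, the usual convention for absent classes.
#'
#' @param true,predicted equal-length label vectors
#' @param levels label set fixing the confusion-matrix order
#' @return a `pathway_metrics` object
#' @export
compute_metrics <- function(true, predicted,
                            levels = if (all(c(true, predicted) %in% CLASS_LEVELS))
                              CLASS_LEVELS else sort(unique(c(true, predicted)))) {
  if (length(true) == 0) stop("empty input")
  if (length(true) != length(predicted)) stop("length mismatch")
  tf <- factor(true, levels = levels)
  pf <- factor(predicted, levels = levels)
  cm <- table(true = tf, predicted = pf)
  tp <- diag(cm)
  support <- rowSums(cm)
  predn <- colSums(cm)
  prec <- ifelse(predn > 0, tp / predn, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- support > 0
  structure(list(
    accuracy = sum(tp) / length(true),
    precision = sum(prec * support) / sum(support),
    recall = sum(rec * support) / sum(support),
    f1_macro = mean(f1[present]),
    confusion = unclass(cm)
  ), class = "pathway_metrics")
}

#' @export
print.pathway_metrics <- function(x, ...) {
  cat(sprintf(
    "<pathway_metrics> accuracy %.4f  precision %.4f  recall %.4f  F1-macro %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1_macro))
  print(x$confusion)
  invisible(x)
}

# accept a matrix, data.frame, or list of feature_vector objects
features_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  if (is.data.frame(features)) return(as.matrix(features))
  if (is.list(features) && length(features) &&
      inherits(features[[1]], "feature_vector"))
    return(do.call(rbind, lapply(features, `[[`, "values")))
  as.matrix(features)
}

# labels carried by a list of feature_vectors
features_labels <- function(features)
  vapply(features, `[[`, character(1), "label")
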
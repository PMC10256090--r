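four_blobs <- function(n = 25, seed = 1, sep = 8)
  blob_features(n, c("background", "hover", "inward", "outward"),
                sep = sep, seed = seed)

test_that("every pathway labels every sample with one of the four classes", {
  b <- four_blobs(20)
  for (id in c("P1", "P2", "P3")) {
    tp <- train_pathway(b$x, b$labels, pathway_spec(id),
                        hyperopt_budget = 4, seed = 1, inner_folds = 2)
    pred <- predict(tp, b$x)
    expect_length(pred, nrow(b$x))
    expect_true(all(pred %in% c("background", "hover", "inward", "outward")))
    # separable training set: training predictions match the labels
    expect_gt(mean(pred == b$labels), 0.97)
  }
})

test_that("training is deterministic given the seed", {
  b <- four_blobs(15)
  t1 <- train_pathway(b$x, b$labels, "P2", hyperopt_budget = 5, seed = 9,
                      inner_folds = 2)
  t2 <- train_pathway(b$x, b$labels, "P2", hyperopt_budget = 5, seed = 9,
                      inner_folds = 2)
  for (s in seq_along(t1$stages))
    expect_identical(t1$stages[[s]]$hyperparameters,
                     t2$stages[[s]]$hyperparameters)
})

test_that("cascade short-circuits on a constant first stage", {
  b <- four_blobs(15)
  sel <- b$labels == "background"
  w <- capture_warnings(
    tp <- train_pathway(b$x[sel, ], b$labels[sel], "P2",
                        hyperopt_budget = 4, seed = 1, inner_folds = 2))
  expect_true(any(grepl("single group", w)))  # every stage degenerates
  expect_true(all(predict(tp, b$x) == "background"))
})

test_that("P2 and P3 agree on samples routed identically through stage 1", {
  b <- four_blobs(20, seed = 4)
  p2 <- train_pathway(b$x, b$labels, "P2", hyperopt_budget = 4, seed = 3,
                      inner_folds = 2)
  p3 <- train_pathway(b$x, b$labels, "P3", hyperopt_budget = 4, seed = 3,
                      inner_folds = 2)
  pr2 <- predict(p2, b$x)
  pr3 <- predict(p3, b$x)
  # identical stage-1 configuration and seed: background sets coincide
  expect_identical(pr2 == "background", pr3 == "background")
})

test_that("shuffled labels score at chance under cross-validation", {
  set.seed(11)
  x <- matrix(rnorm(120 * 6), 120, 6)
  labels <- sample(rep(c("background", "hover", "inward", "outward"), 30))
  m <- cross_validate(x, labels, "P1", folds = 10, seed = 2,
                      hyperopt_budget = 3, inner_folds = 2)
  # binomial null: accuracy ~ 0.25 +- 3 * sqrt(p(1-p)/n)
  expect_lt(abs(m$accuracy - 0.25), 3 * sqrt(0.25 * 0.75 / 120))
})

test_that("cross-validation is stratified, leak-free and averages correctly", {
  b <- four_blobs(20, seed = 6)
  m <- cross_validate(b$x, b$labels, "P1", folds = 4, seed = 1,
                      hyperopt_budget = 3, inner_folds = 2)
  expect_gt(m$accuracy, 0.95)  # separable world
  expect_equal(m$accuracy,
               mean(vapply(m$per_fold, `[[`, numeric(1), "accuracy")),
               tolerance = 1e-12)
  expect_equal(sum(m$confusion), nrow(b$x))

  expect_error(cross_validate(b$x, b$labels, "P1", folds = 1), "folds")
  expect_warning(
    cross_validate(b$x[1:25, ], b$labels[1:25], "P1", folds = 10, seed = 1,
                   hyperopt_budget = 3, inner_folds = 2),
    "reducing folds")

  # standardization is fit per training subset: different folds, different
  # statistics on heterogeneous data
  f1 <- train_pathway(b$x[1:40, ], b$labels[1:40], "P1",
                      hyperopt_budget = 3, seed = 1, inner_folds = 2)
  f2 <- train_pathway(b$x[41:80, ], b$labels[41:80], "P1",
                      hyperopt_budget = 3, seed = 1, inner_folds = 2)
  expect_false(identical(f1$stages[[1]]$standardizer$mean,
                         f2$stages[[1]]$standardizer$mean))
})

test_that("metrics match their definitions", {
  # perfect predictions
  y <- c("background", "hover", "inward", "outward", "hover")
  m <- compute_metrics(y, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1_macro, 1)
  expect_equal(sum(m$confusion) - sum(diag(m$confusion)), 0)

  # hand-computed imbalanced 2-class example: 8 of class a, 2 of class b,
  # everything predicted a -> accuracy 0.8; per-class F1 = (8/9*... ) vs 0
  truth <- c(rep("a", 8), rep("b", 2))
  pred <- rep("a", 10)
  m2 <- compute_metrics(truth, pred)
  expect_equal(m2$accuracy, 0.8)
  expect_equal(m2$recall, 0.8)
  expect_equal(m2$precision, 0.8 * 0.8)      # weighted: 0.8*0.8 + 0.2*0
  expect_equal(m2$f1_macro, (2 * 0.8 / 1.8) / 2)  # mean(8/9, 0)
  expect_lt(m2$f1_macro, m2$accuracy)

  # order invariance
  set.seed(5)
  perm <- sample(10)
  m3 <- compute_metrics(truth[perm], pred[perm])
  expect_equal(m3$accuracy, m2$accuracy)
  expect_equal(m3$f1_macro, m2$f1_macro)

  expect_error(compute_metrics(character(0), character(0)), "empty")
  expect_error(compute_metrics(c("a", "b"), "a"), "length")
})
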
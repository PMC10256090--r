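#' Train a support vector machine with an RBF kernel
#'
#' C-SVC solved by sequential minimal optimization with maximal-violating-pair
#' working-set selection. Multiclass problems are handled by one-vs-one
#' voting, ties broken by the summed decision margins.
#'
#' @param x numeric feature matrix (rows = samples)
#' @param y factor or character vector of labels
#' @param C soft-margin cost
#' @param gamma RBF kernel width, `k(u,v) = exp(-gamma * ||u - v||^2)`
#' @param tol SMO stopping tolerance on the duality gap
#' @return an object of class `beedar_svm`
#' @export
svm_fit <- function(x, y, C = 1, gamma = 1 / ncol(x), tol = 1e-3) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), C > 0, gamma > 0)
  lev <- sort(unique(y))
  if (length(lev) < 2) {
    return(structure(list(levels = lev, constant = lev[1], gamma = gamma),
                     class = "beedar_svm"))
  }
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    yy <- ifelse(y[sel] == pr[1], 1, -1)
    fit <- .smo_train(x[sel, , drop = FALSE], yy, C, gamma, tol)
    fit$pair <- pr
    fit
  })
  structure(list(levels = lev, models = models, gamma = gamma, C = C),
            class = "beedar_svm")
}

#' @export
predict.beedar_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(newdata)))
  lev <- object$levels
  votes <- matrix(0, nrow(newdata), length(lev),
                  dimnames = list(NULL, lev))
  margin <- votes
  for (m in object$models) {
    d <- .smo_decision(m$sv, m$coef, m$b, object$gamma, newdata)
    win <- ifelse(d >= 0, m$pair[1], m$pair[2])
    for (lv in m$pair) {
      sel <- win == lv
      votes[sel, lv] <- votes[sel, lv] + 1
      margin[, lv] <- margin[, lv] + ifelse(lv == m$pair[1], d, -d)
    }
  }
  apply(votes + 1e-6 * tanh(margin), 1, function(v) lev[which.max(v)])
}

# feature standardization helpers; statistics are fit on training data only
standardizer_fit <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[!is.finite(sg) | sg < 1e-12] <- 1
  list(mean = mu, sd = sg)
}
standardizer_apply <- function(st, x)
  sweep(sweep(as.matrix(x), 2, st$mean, "-"), 2, st$sd, "/")

#' Bayesian optimization of a black-box objective over a box
#'
#' Gaussian-process surrogate (squared-exponential kernel with a nugget) with
#' the expected-improvement acquisition maximised over random candidates.
#' Used to tune `log10(C)` and `log10(gamma)` of the SVM stages. Deterministic
#' given `seed`.
#'
#' @param objective function taking a numeric vector (one point) and returning
#'   a scalar score to maximise
#' @param lower,upper bounds of the search box
#' @param budget total number of objective evaluations (>= 2)
#' @param n_init size of the initial space-filling design
#' @param seed integer seed
#' @return list with `par` (best point), `value`, and the evaluation history
#' @export
bayes_optimize <- function(objective, lower, upper, budget = 30,
                           n_init = min(8, budget), seed = 1L) {
  d <- length(lower)
  stopifnot(length(upper) == d, budget >= 2, n_init >= 2, n_init <= budget)
  with_seed(seed, {
    # latin-hypercube-ish initial design
    pts <- sapply(seq_len(d), function(j) {
      u <- (sample(n_init) - runif(n_init)) / n_init
      lower[j] + u * (upper[j] - lower[j])
    })
    pts <- matrix(pts, ncol = d)
    vals <- apply(pts, 1, objective)
    ls <- (upper - lower) / 3  # fixed GP lengthscales per dimension
    while (nrow(pts) < budget) {
      y <- (vals - mean(vals)) / max(sd(vals), 1e-9)
      Kf <- gp_kern(pts, pts, ls) + diag(1e-6 + 1e-4, nrow(pts))
      L <- chol(Kf)
      ai <- backsolve(L, forwardsolve(t(L), y))
      cand <- matrix(runif(256 * d, lower, upper), ncol = d, byrow = TRUE)
      Ks <- gp_kern(cand, pts, ls)
      mu <- as.vector(Ks %*% ai)
      v <- forwardsolve(t(L), t(Ks))
      s2 <- pmax(1 + 1e-4 - colSums(v^2), 1e-12)
      s <- sqrt(s2)
      best <- max(y)
      z <- (mu - best) / s
      ei <- s * (z * pnorm(z) + dnorm(z))
      nxt <- cand[which.max(ei), , drop = FALSE]
      pts <- rbind(pts, nxt)
      vals <- c(vals, objective(as.numeric(nxt)))
    }
    ibest <- which.max(vals)
    list(par = as.numeric(pts[ibest, ]), value = vals[ibest],
         points = pts, values = vals)
  })
}

gp_kern <- function(A, B, ls) {
  z <- 0
  for (j in seq_along(ls)) z <- z + outer(A[, j], B[, j], "-")^2 / ls[j]^2
  exp(-0.5 * z)
}

#' @importFrom stats pnorm dnorm
NULL
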
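## Classifiers used by the validation phase.
##
## The SVM (polynomial kernel, degree 3) comes from e1071.  The multilayer
## perceptron is a single-hidden-layer softmax network trained by
## gradient descent with momentum (learning rate 0.2, momentum 0.8, hidden
## units = rounded mean of feature and class counts), and AdaBoost.M1
## (10 iterations, weighted resampling) can wrap either base learner.

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit a multilayer perceptron
#'
#' Single hidden sigmoid layer, softmax output, cross-entropy loss,
#' full-batch gradient descent with momentum.
#'
#' @param x Numeric feature matrix (standardized).
#' @param y Class factor.
#' @param hidden Hidden units; default `round((ncol(x) + nlevels(y)) / 2)`.
#' @param learning_rate Learning rate (default 0.2).
#' @param momentum Momentum coefficient (default 0.8).
#' @param epochs Training epochs (default 500).
#' @param seed Seed for weight initialization.
#' @return An `hotex_mlp` model object.
#' @export
fit_mlp <- function(x, y, hidden = NULL, learning_rate = 0.2,
                    momentum = 0.8, epochs = 500L, seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  k <- nlevels(y)
  p <- ncol(x)
  if (is.null(hidden)) hidden <- max(1L, as.integer(round((p + k) / 2)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  target <- matrix(0, n, k)
  target[cbind(seq_len(n), as.integer(y))] <- 1
  W1 <- matrix(stats::runif(p * hidden, -0.5, 0.5), p, hidden)
  b1 <- stats::runif(hidden, -0.5, 0.5)
  W2 <- matrix(stats::runif(hidden * k, -0.5, 0.5), hidden, k)
  b2 <- stats::runif(k, -0.5, 0.5)
  vW1 <- matrix(0, p, hidden); vb1 <- numeric(hidden)
  vW2 <- matrix(0, hidden, k); vb2 <- numeric(k)
  for (e in seq_len(epochs)) {
    H <- sigmoid(sweep(x %*% W1, 2L, b1, "+"))
    O <- softmax_rows(sweep(H %*% W2, 2L, b2, "+"))
    dO <- (O - target) / n
    gW2 <- crossprod(H, dO); gb2 <- colSums(dO)
    dH <- (dO %*% t(W2)) * H * (1 - H)
    gW1 <- crossprod(x, dH); gb1 <- colSums(dH)
    vW2 <- momentum * vW2 - learning_rate * gW2
    vb2 <- momentum * vb2 - learning_rate * gb2
    vW1 <- momentum * vW1 - learning_rate * gW1
    vb1 <- momentum * vb1 - learning_rate * gb1
    W2 <- W2 + vW2; b2 <- b2 + vb2
    W1 <- W1 + vW1; b1 <- b1 + vb1
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, levels = levels(y)),
            class = "hotex_mlp")
}

#' @export
predict.hotex_mlp <- function(object, newdata,
                              type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  H <- sigmoid(sweep(x %*% object$W1, 2L, object$b1, "+"))
  O <- softmax_rows(sweep(H %*% object$W2, 2L, object$b2, "+"))
  colnames(O) <- object$levels
  if (type == "prob") return(O)
  factor(object$levels[max.col(O, ties.method = "first")],
         levels = object$levels)
}

## base-learner plumbing ------------------------------------------------------

# A learner is a list(fit(x, y, seed), prob(model, x) -> matrix with class
# columns).
base_learner <- function(spec, mlp_epochs = 500L) {
  switch(spec,
    svm_poly3 = list(
      fit = function(x, y, seed) {
        e1071::svm(x = x, y = y, kernel = "polynomial", degree = 3,
                   probability = TRUE)
      },
      prob = function(model, x) {
        pr <- attr(stats::predict(model, x, probability = TRUE),
                   "probabilities")
        pr[, model$levels, drop = FALSE]
      }),
    mlp = list(
      fit = function(x, y, seed) {
        fit_mlp(x, y, epochs = mlp_epochs, seed = seed)
      },
      prob = function(model, x) stats::predict(model, x, type = "prob")),
    stop_validation("unknown base learner '%s'", spec))
}

#' Fit an AdaBoost.M1 ensemble
#'
#' Boosts a base learner for a fixed number of iterations using weighted
#' resampling: each round trains the base learner on a weighted bootstrap
#' sample, weights the learner by `log((1 - err) / err)` on the weighted
#' training error, and re-weights the instances.  Rounds with error 0 or
#' `>= 0.5` terminate boosting (a zero-error round is kept).
#'
#' @param x Numeric feature matrix.
#' @param y Class factor.
#' @param base `"svm_poly3"` or `"mlp"`.
#' @param iterations Boosting rounds (default 10).
#' @param seed RNG seed (resampling and learner initialization).
#' @param mlp_epochs Epochs for an MLP base learner.
#' @return An `hotex_adaboost` model object.
#' @export
fit_adaboost <- function(x, y, base = c("svm_poly3", "mlp"),
                         iterations = 10L, seed = 1L, mlp_epochs = 500L) {
  base <- match.arg(base)
  learner <- base_learner(base, mlp_epochs)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  n <- nrow(x)
  if (!is.null(seed)) set.seed(seed)
  w <- rep(1 / n, n)
  models <- list(); alphas <- numeric(0)
  for (m in seq_len(iterations)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    model <- learner$fit(x[idx, , drop = FALSE], y[idx],
                         seed = sample.int(.Machine$integer.max, 1L))
    prob <- learner$prob(model, x)
    pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                   levels = levels(y))
    err <- sum(w[pred != y])
    if (err >= 0.5) {
      if (!length(models)) { models <- list(model); alphas <- 1 }
      break
    }
    if (err <= 0) {
      models <- c(models, list(model))
      alphas <- c(alphas, log((1 - 1e-10) / 1e-10))
      break
    }
    alpha <- log((1 - err) / err)
    models <- c(models, list(model))
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  structure(list(models = models, alphas = alphas, base = base,
                 levels = levels(y), learner = learner),
            class = "hotex_adaboost")
}

#' @export
predict.hotex_adaboost <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  votes <- matrix(0, nrow(x), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (m in seq_along(object$models)) {
    prob <- object$learner$prob(object$models[[m]], x)
    pred <- colnames(prob)[max.col(prob, ties.method = "first")]
    votes[cbind(seq_len(nrow(x)), match(pred, object$levels))] <-
      votes[cbind(seq_len(nrow(x)), match(pred, object$levels))] +
      object$alphas[m]
  }
  votes <- votes / sum(object$alphas)
  if (type == "prob") return(votes)
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}
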
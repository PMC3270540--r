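## Stratified cross-validated evaluation and the per-class textural model.

#' Stratified fold assignment
#'
#' Shuffles each class separately (seeded) and deals its rows round-robin
#' over the folds, so every fold's class proportions match the table's
#' within one instance per class.
#'
#' @param table Feature table with a `class` column.
#' @param k Number of folds (default 5: 80% train / 20% test per
#'   iteration).
#' @param seed Shuffle seed.
#' @return Integer vector of fold ids in `1:k`, one per row.
#' @export
stratified_folds <- function(table, k = 5L, seed = 1L) {
  check_feature_table(table)
  k <- as.integer(k)
  if (k < 2L) stop_validation("k must be at least 2")
  cls <- as.character(table$class)
  tab <- table(cls)
  if (min(tab) < k)
    stop_validation("every class needs at least k = %d rows (smallest has %d)",
                    k, min(tab))
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(cls))
  for (cl in names(tab)) {
    idx <- sample(which(cls == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Area under the ROC curve by rank statistic
#'
#' Mann–Whitney form: ties in the scores receive average ranks, so the
#' value is invariant under monotone transforms of the score.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param positive Logical vector marking positive instances.
#' @return AUC in `[0, 1]`, or `NA` when a group is empty.
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Train-fold standardization with mean imputation of missing values.
standardize_train_test <- function(train, test) {
  mu <- colMeans(train, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  sdv <- apply(train, 2L, stats::sd, na.rm = TRUE)
  sdv[is.na(sdv) | sdv == 0] <- 1
  fix <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
    sweep(sweep(m, 2L, mu), 2L, sdv, "/")
  }
  list(train = fix(train), test = fix(test))
}

fit_predict_fold <- function(classifier, xtr, ytr, xte, seed,
                             mlp_epochs) {
  model <- switch(classifier,
    svm_poly3 = e1071::svm(x = xtr, y = ytr, kernel = "polynomial",
                           degree = 3, probability = TRUE),
    mlp = fit_mlp(xtr, ytr, epochs = mlp_epochs, seed = seed),
    adaboost_svm = fit_adaboost(xtr, ytr, base = "svm_poly3", seed = seed),
    adaboost_mlp = fit_adaboost(xtr, ytr, base = "mlp", seed = seed,
                                mlp_epochs = mlp_epochs),
    stop_validation(
      "unknown classifier '%s' (valid: svm_poly3, mlp, adaboost_svm, adaboost_mlp)",
      classifier))
  prob <- switch(classifier,
    svm_poly3 = {
      pr <- attr(stats::predict(model, xte, probability = TRUE),
                 "probabilities")
      pr[, levels(ytr), drop = FALSE]
    },
    stats::predict(model, xte, type = "prob")[, levels(ytr), drop = FALSE])
  list(pred = factor(levels(ytr)[max.col(prob, ties.method = "first")],
                     levels = levels(ytr)),
       prob = prob)
}

#' Cross-validated classifier evaluation
#'
#' Runs stratified k-fold cross-validation for one classifier: per fold,
#' features are standardized on the training split (missing values
#' mean-imputed), the classifier is fitted and the held-out split is
#' predicted.  Metrics come from the pooled confusion matrix: recognition
#' rate (correctly classified %), TP rate (sensitivity of the positive
#' class; macro-averaged recall beyond two classes), TN rate
#' (specificity; macro-averaged), and AUC from the held-out scores by
#' rank statistic (macro one-vs-rest beyond two classes).
#'
#' @param table Feature table.
#' @param selection Optional `selection_result` (or character vector of
#'   feature names); `NULL` uses every feature column.
#' @param classifier One of `"svm_poly3"`, `"mlp"`, `"adaboost_svm"`,
#'   `"adaboost_mlp"`.
#' @param folds Fold assignment from [stratified_folds()]; built from
#'   `k` and `seed` when `NULL`.
#' @param k Folds when `folds` is `NULL` (default 5).
#' @param seed Seed for folds and classifier initialization.
#' @param positive Positive class label for TP/TN rates (default: first
#'   class level).
#' @param mlp_epochs Training epochs for MLP-based classifiers.
#' @return A `texture_eval` object.
#' @export
evaluate <- function(table, selection = NULL, classifier = "svm_poly3",
                     folds = NULL, k = 5L, seed = 1L, positive = NULL,
                     mlp_epochs = 500L) {
  check_feature_table(table)
  feats <- if (is.null(selection)) feature_columns(table)
           else if (inherits(selection, "selection_result"))
             selection$final_set
           else as.character(selection)
  missing <- setdiff(feats, feature_columns(table))
  if (length(missing))
    stop_validation("selected features not in table: %s",
                    paste(missing, collapse = ", "))
  if (is.null(folds)) folds <- stratified_folds(table, k, seed)
  y <- droplevels(as.factor(table$class))
  if (!is.null(positive)) {
    if (!positive %in% levels(y))
      stop_validation("positive class '%s' not among class labels", positive)
    y <- stats::relevel(y, positive)
  }
  x <- as.matrix(table[feats])
  t0 <- proc.time()["elapsed"]
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(y))
  prob <- matrix(NA_real_, nrow(x), nlevels(y),
                 dimnames = list(NULL, levels(y)))
  fold_confusions <- list()
  for (f in sort(unique(folds))) {
    te <- folds == f
    if (length(unique(y[!te])) < 2L)
      stop_validation("fold %d leaves a single-class training set", f)
    z <- standardize_train_test(x[!te, , drop = FALSE],
                                x[te, , drop = FALSE])
    res <- fit_predict_fold(classifier, z$train, y[!te], z$test,
                            seed = seed + f, mlp_epochs = mlp_epochs)
    pred[te] <- res$pred
    prob[te, ] <- res$prob
    fold_confusions[[as.character(f)]] <- table(truth = y[te],
                                                predicted = res$pred)
  }
  wall <- unname(proc.time()["elapsed"] - t0)
  confusion <- table(truth = y, predicted = pred)
  recognition <- 100 * sum(diag(confusion)) / sum(confusion)
  recalls <- diag(confusion) / rowSums(confusion)
  specifics <- vapply(seq_len(nrow(confusion)), function(i) {
    tn <- sum(confusion[-i, -i]); fp <- sum(confusion[-i, i])
    tn / (tn + fp)
  }, numeric(1L))
  if (nlevels(y) == 2L) {
    tp_rate <- 100 * recalls[1L]
    tn_rate <- 100 * specifics[1L]
    auc <- 100 * auc_rank(prob[, 1L], y == levels(y)[1L])
  } else {
    tp_rate <- 100 * mean(recalls)
    tn_rate <- 100 * mean(specifics)
    auc <- 100 * mean(vapply(levels(y), function(cl)
      auc_rank(prob[, cl], y == cl), numeric(1L)))
  }
  structure(list(classifier = classifier, features = feats,
                 recognition_rate = recognition,
                 tp_rate = unname(tp_rate), tn_rate = unname(tn_rate),
                 auc = unname(auc), confusion = confusion,
                 fold_confusions = fold_confusions,
                 positive = levels(y)[1L], wall_time = wall,
                 predictions = pred, scores = prob, folds = folds),
            class = "texture_eval")
}

#' @export
print.texture_eval <- function(x, ...) {
  cat(sprintf("%s: recognition %.2f%%, TP rate %.2f%%, TN rate %.2f%%, AUC %.2f%% (%.1fs)\n",
              x$classifier, x$recognition_rate, x$tp_rate, x$tn_rate,
              x$auc, x$wall_time))
  invisible(x)
}

#' @export
summary.texture_eval <- function(object, ...) {
  print(object)
  cat(sprintf("Positive class: %s; %d features; pooled confusion:\n",
              object$positive, length(object$features)))
  print(object$confusion)
  invisible(object)
}

#' Evaluation summary table
#'
#' Collates `texture_eval` reports into a summary data.frame with one row
#' per classifier: recognition rate, TP rate, TN rate, AUC and model
#' building time.
#'
#' @param reports List of `texture_eval` objects.
#' @return A data.frame.
#' @export
eval_summary <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(classifier = r$classifier,
               recognition_rate = r$recognition_rate,
               tp_rate = r$tp_rate, tn_rate = r$tn_rate, auc = r$auc,
               time_s = r$wall_time, stringsAsFactors = FALSE)
  }))
}

## textural model -------------------------------------------------------------

#' Build the per-class textural model
#'
#' For every selected feature and every class the model stores the
#' feature's relevance (how many selectors — CFS and the IG top-k —
#' retained it), its class-conditional mean and standard deviation, and a
#' normalized fixed-bin histogram over the pooled feature range.
#'
#' @param table Feature table.
#' @param selection A `selection_result`.
#' @param bins Histogram bins (default 16).
#' @return A `textural_model` object.
#' @export
build_textural_model <- function(table, selection, bins = 16L) {
  check_feature_table(table)
  stopifnot(inherits(selection, "selection_result"))
  feats <- selection$final_set
  if (!length(feats))
    stop_validation("selection has an empty final set")
  missing <- setdiff(feats, feature_columns(table))
  if (length(missing))
    stop_validation("selected features not in table: %s",
                    paste(missing, collapse = ", "))
  bins <- as.integer(bins)
  classes <- sort(unique(as.character(table$class)))
  model <- list()
  for (f in feats) {
    v_all <- table[[f]]
    rng <- range(v_all, na.rm = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
    per_class <- lapply(classes, function(cl) {
      v <- v_all[table$class == cl]
      v <- v[!is.na(v)]
      h <- if (length(v)) {
        cnt <- tabulate(pmin(pmax(findInterval(v, breaks,
                                               rightmost.closed = TRUE),
                                  1L), bins), bins)
        cnt / sum(cnt)
      } else rep(NA_real_, bins)
      list(mean = if (length(v)) mean(v) else NA_real_,
           standard_deviation = if (length(v) > 1L) stats::sd(v) else 0,
           probability_distribution = h)
    })
    names(per_class) <- classes
    model[[f]] <- list(
      relevance = as.integer(f %in% selection$cfs_subset) +
        as.integer(f %in% selection$ig_top),
      breaks = breaks,
      classes = per_class)
  }
  structure(list(features = model, classes = classes, bins = bins),
            class = "textural_model")
}

#' @export
print.textural_model <- function(x, ...) {
  cat(sprintf("Textural model: %d relevant features, %d classes, %d-bin histograms\n",
              length(x$features), length(x$classes), x$bins))
  for (f in utils::head(names(x$features), 10L)) {
    e <- x$features[[f]]
    means <- vapply(e$classes, `[[`, numeric(1L), "mean")
    cat(sprintf("  %s (relevance %d): %s\n", f, e$relevance,
                paste(sprintf("%s %.3g", names(means), means),
                      collapse = ", ")))
  }
  if (length(x$features) > 10L)
    cat(sprintf("  ... and %d more\n", length(x$features) - 10L))
  invisible(x)
}

#' @export
summary.textural_model <- function(object, ...) {
  df <- do.call(rbind, lapply(names(object$features), function(f) {
    e <- object$features[[f]]
    do.call(rbind, lapply(names(e$classes), function(cl) {
      data.frame(feature = f, class = cl, relevance = e$relevance,
                 mean = e$classes[[cl]]$mean,
                 standard_deviation = e$classes[[cl]]$standard_deviation,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(df) <- NULL
  df
}

#' Plot class-conditional feature distributions
#'
#' Draws the stored histograms of up to `max_features` model features,
#' one panel per feature, classes overlaid.
#'
#' @param x A `textural_model`.
#' @param max_features Panels to draw (default 4).
#' @param ... Ignored.
#' @export
plot.textural_model <- function(x, max_features = 4L, ...) {
  feats <- utils::head(names(x$features), max_features)
  old <- graphics::par(mfrow = c(ceiling(length(feats) / 2),
                                 min(2L, length(feats))))
  on.exit(graphics::par(old))
  cols <- seq_along(x$classes) + 1L
  for (f in feats) {
    e <- x$features[[f]]
    mids <- (utils::head(e$breaks, -1L) + utils::tail(e$breaks, -1L)) / 2
    ylim <- c(0, max(vapply(e$classes, function(c1)
      max(c1$probability_distribution, na.rm = TRUE), numeric(1L))))
    graphics::plot(NA, xlim = range(e$breaks), ylim = ylim, xlab = f,
                   ylab = "probability", main = f)
    for (i in seq_along(x$classes)) {
      graphics::lines(mids,
                      e$classes[[x$classes[i]]]$probability_distribution,
                      type = "b", col = cols[i], pch = 16)
    }
    graphics::legend("topright", legend = x$classes, col = cols, lty = 1,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Write a textural model as JSON
#'
#' @param model A `textural_model`.
#' @param path Output path.
#' @export
write_textural_model <- function(model, path) {
  stopifnot(inherits(model, "textural_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
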
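# Stratified folds, metrics, classifiers and the textural model.

test_that("stratified folds preserve class proportions within one instance", {
  tab <- make_feature_table(n_per_class = 100, seed = 81)
  f <- stratified_folds(tab, k = 5, seed = 1)
  expect_setequal(unique(f), 1:5)
  for (k in 1:5) {
    counts <- table(tab$class[f == k])
    expect_true(all(counts == 20))  # 100+100 split exactly
  }
  # 80/20 train/test split per iteration
  expect_equal(sum(f != 1) / length(f), 0.8)
  expect_identical(stratified_folds(tab, 5, seed = 9),
                   stratified_folds(tab, 5, seed = 9))
  # uneven classes stay within +/- 1
  tab2 <- make_feature_table(n_per_class = 13, seed = 82)
  f2 <- stratified_folds(tab2, k = 5, seed = 2)
  for (k in 1:5) {
    counts <- table(factor(tab2$class[f2 == k], levels = c("a", "b")))
    expect_true(all(abs(counts - 13 / 5) <= 1))
  }
  small <- make_feature_table(n_per_class = 3, seed = 83)
  expect_error(stratified_folds(small, k = 5), "at least k")
})

test_that("rank AUC is 1 for separating scores and invariant to monotone maps", {
  pos <- c(rep(TRUE, 10), rep(FALSE, 15))
  scores <- c(stats::runif(10, 10, 20), stats::runif(15, 0, 5))
  expect_equal(auc_rank(scores, pos), 1)
  expect_equal(auc_rank(exp(scores / 3), pos), 1)
  set.seed(85)
  s2 <- stats::rnorm(25)
  expect_equal(auc_rank(s2, pos), auc_rank(tanh(s2) * 100 + 3, pos))
  expect_equal(auc_rank(rep(1, 25), pos), 0.5)  # all-tied scores
  skip_if_not_installed("pROC")
  a <- auc_rank(s2, pos)
  b <- as.numeric(pROC::auc(pROC::roc(pos, s2, quiet = TRUE,
                                      direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("every classifier separates a separable two-class table", {
  tab <- make_feature_table(n_per_class = 20, informative = 2, noise = 3,
                            delta = 8, seed = 87)
  for (cl in c("svm_poly3", "mlp", "adaboost_svm", "adaboost_mlp")) {
    r <- evaluate(tab, classifier = cl, k = 5, seed = 1, mlp_epochs = 300)
    expect_equal(r$recognition_rate, 100, info = cl)
    expect_equal(r$auc, 100, info = cl)
    expect_equal(r$tp_rate, 100, info = cl)
    expect_equal(r$tn_rate, 100, info = cl)
  }
  expect_error(evaluate(tab, classifier = "forest"), "unknown classifier")
})

test_that("recognition rate equals pooled-confusion arithmetic exactly", {
  tab <- make_feature_table(n_per_class = 25, informative = 1, noise = 4,
                            delta = 1.5, seed = 89)
  r <- evaluate(tab, classifier = "svm_poly3", k = 5, seed = 1)
  cm <- r$confusion
  expect_equal(r$recognition_rate, 100 * sum(diag(cm)) / sum(cm))
  expect_equal(r$tp_rate, 100 * cm[1, 1] / sum(cm[1, ]))
  expect_equal(r$tn_rate, 100 * cm[2, 2] / sum(cm[2, ]))
  expect_equal(sum(cm), nrow(tab))
  # fold confusions pool to the overall one
  pooled <- Reduce(`+`, r$fold_confusions)
  expect_equal(as.numeric(pooled), as.numeric(cm))
})

test_that("MLP training is seeded and benefits from its hidden layer", {
  set.seed(91)
  x <- matrix(stats::rnorm(200), 100, 2)
  y <- factor(ifelse(x[, 1] * x[, 2] > 0, "p", "q"))  # XOR-like, nonlinear
  m1 <- fit_mlp(x, y, hidden = 8, epochs = 400, seed = 3)
  m2 <- fit_mlp(x, y, hidden = 8, epochs = 400, seed = 3)
  expect_identical(m1$W1, m2$W1)
  acc <- mean(predict(m1, x) == y)
  expect_gt(acc, 0.9)
  pr <- predict(m1, x, type = "prob")
  expect_equal(rowSums(pr), rep(1, 100), tolerance = 1e-9)
})

test_that("AdaBoost weights rounds by their weighted error", {
  tab <- make_feature_table(n_per_class = 25, informative = 1, noise = 2,
                            delta = 2, seed = 93)
  x <- as.matrix(tab[setdiff(names(tab), "class")])
  y <- factor(tab$class)
  m <- fit_adaboost(x, y, base = "svm_poly3", iterations = 5, seed = 1)
  expect_lte(length(m$models), 5L)
  expect_true(all(m$alphas > 0))
  pr <- predict(m, x, type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(x)), tolerance = 1e-9)
})

test_that("evaluate restricted to a selection uses only those features", {
  tab <- make_feature_table(n_per_class = 20, informative = 2, noise = 5,
                            delta = 6, seed = 95)
  r <- evaluate(tab, selection = c("inf1", "inf2"), classifier = "svm_poly3",
                k = 4, seed = 1)
  expect_setequal(r$features, c("inf1", "inf2"))
  expect_error(evaluate(tab, selection = "ghost"), "not in table")
})

test_that("the textural model stores per-class relevance, moments and histograms", {
  set.seed(97)
  n <- 200
  tab <- data.frame(
    f_gauss = c(stats::rnorm(n / 2, 0), stats::rnorm(n / 2, 5)),
    f_const = rep(c(1, 1), n / 2),
    class = rep(c("a", "b"), each = n / 2),
    stringsAsFactors = FALSE)
  sel <- structure(list(cfs_subset = c("f_gauss", "f_const"),
                        cfs_merit = 0.5,
                        ig_ranking = data.frame(feature = c("f_gauss", "f_const"),
                                                info_gain = c(0.6, 0)),
                        ig_top = "f_gauss",
                        final_set = c("f_gauss", "f_const"), ig_top_k = 1L),
                   class = "selection_result")
  tm <- build_textural_model(tab, sel, bins = 16)
  expect_s3_class(tm, "textural_model")
  expect_identical(tm$features$f_gauss$relevance, 2L)  # CFS and IG
  expect_identical(tm$features$f_const$relevance, 1L)  # CFS only
  # parameter recovery within 3 se of the truth
  se <- 1 / sqrt(n / 2)
  expect_lt(abs(tm$features$f_gauss$classes$a$mean - 0), 3 * se)
  expect_lt(abs(tm$features$f_gauss$classes$b$mean - 5), 3 * se)
  # constant-in-class feature: zero sd, single-spike histogram
  expect_equal(tm$features$f_const$classes$a$standard_deviation, 0)
  h <- tm$features$f_const$classes$a$probability_distribution
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(max(h), 1)
  for (f in names(tm$features)) {
    for (cl in c("a", "b")) {
      expect_equal(sum(tm$features[[f]]$classes[[cl]]$probability_distribution),
                   1, tolerance = 1e-9)
    }
  }
  s <- summary(tm)
  expect_identical(nrow(s), 4L)
  f <- tempfile(fileext = ".json")
  write_textural_model(tm, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})

test_that("permuted labels drive recognition to chance", {
  tab <- make_feature_table(n_per_class = 30, informative = 2, noise = 4,
                            delta = 5, seed = 99)
  set.seed(11)
  accs <- replicate(5, {
    tab$class <- sample(tab$class)
    evaluate(tab, classifier = "svm_poly3", k = 5, seed = 1)$recognition_rate
  })
  expect_lt(abs(mean(accs) - 50), 12)
})
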
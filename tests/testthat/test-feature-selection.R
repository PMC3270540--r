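# MDL discretization, SU/IG, CFS merit and the genetic search.

test_that("MDL discretization cuts separable columns and rejects noise", {
  set.seed(51)
  cls <- rep(c("A", "B"), each = 40)
  sep <- c(stats::runif(40, -2, -0.1), stats::runif(40, 0.1, 2))
  cuts <- mdl_discretize(sep, cls)
  expect_length(cuts, 1L)
  expect_lt(abs(cuts), 0.2)

  noise <- stats::runif(80)
  expect_length(mdl_discretize(noise, cls), 0L)

  # two value clusters aligned to a 3-class problem
  cls3 <- rep(c("A", "B", "C"), each = 30)
  v3 <- c(stats::rnorm(30, 0, 0.1), stats::rnorm(30, 5, 0.1),
          stats::rnorm(30, 5, 0.1))
  expect_gte(length(mdl_discretize(v3, cls3)), 1L)
  expect_length(mdl_discretize(rep(1, 80), cls), 0L)  # constant column
})

test_that("symmetrical uncertainty has its boundary values", {
  a <- rep(c(1L, 2L), 20)
  expect_equal(symmetrical_uncertainty(a, a), 1)
  expect_equal(symmetrical_uncertainty(rep(1L, 40), a), 0)
  expect_equal(symmetrical_uncertainty(rep(1L, 40), rep(2L, 40)), 0)
  set.seed(53)
  x <- sample(0:1, 1e4, TRUE); y <- sample(0:1, 1e4, TRUE)
  expect_lt(symmetrical_uncertainty(x, y), 0.01)  # independence limit
  expect_error(symmetrical_uncertainty(1:3, 1:4), "length")
})

test_that("information gain equals hand-computed plug-in entropies", {
  cls <- rep(c("A", "B"), each = 10)
  expect_equal(info_gain(as.integer(factor(cls)), cls),
               discrete_entropy_oracle(cls))
  expect_equal(info_gain(rep(1L, 20), cls), 0)
  # printed 2x2 contingency: attr value 1 -> classes (8, 2); value 2 -> (2, 8)
  attr_col <- rep(c(1L, 2L), each = 10)
  cls2 <- c(rep("A", 8), rep("B", 2), rep("A", 2), rep("B", 8))
  hC <- -(0.5 * log(0.5)) * 2
  hC_given <- -(0.8 * log(0.8) + 0.2 * log(0.2))  # both branches identical
  expect_equal(info_gain(attr_col, cls2), hC - hC_given, tolerance = 1e-12)
})

test_that("SU and IG vanish together on a shared discretization", {
  set.seed(59)
  for (i in 1:10) {
    a <- sample(0:2, 60, TRUE)
    b <- if (i %% 2 == 0) a else sample(0:2, 60, TRUE)
    su <- symmetrical_uncertainty(a, b)
    ig <- info_gain(a, b)
    expect_equal(su == 0, ig < 1e-12)
  }
})

test_that("CFS merit reduces to SU at k = 1 and sqrt(k) r_cf at zero redundancy", {
  # f1 determines the class; f2 is exactly independent of f1 and the class
  tab <- data.frame(f1 = rep(c(0, 0, 1, 1), 25),
                    f2 = rep(c(0, 1, 0, 1), 25),
                    class = rep(c("A", "A", "B", "B"), 25),
                    stringsAsFactors = FALSE)
  m1 <- cfs_merit("f1", tab)
  cuts1 <- mdl_discretize(tab$f1, tab$class)
  su1 <- symmetrical_uncertainty(bin_by_cuts(tab$f1, cuts1), tab$class)
  expect_equal(m1, su1)
  expect_equal(m1, 1)  # perfect predictor
  # pairwise SU between f1 and f2 is 0, so merit = k rcf / sqrt(k)
  m12 <- cfs_merit(c("f1", "f2"), tab)
  expect_equal(m12, 2 * (1 + 0) / 2 / sqrt(2), tolerance = 1e-12)
  expect_error(cfs_merit(character(0), tab), "at least one")
  expect_error(cfs_merit("ghost", tab), "not in table")
})

test_that("CFS merit matches direct substitution of the formula", {
  tab <- make_feature_table(n_per_class = 30, informative = 2, noise = 1,
                            seed = 61)
  feats <- setdiff(names(tab), "class")
  disc <- lapply(tab[feats], function(v)
    bin_by_cuts(v, mdl_discretize(v, tab$class)))
  su_fc <- vapply(disc, symmetrical_uncertainty, numeric(1), b = tab$class)
  su_ff <- outer(seq_along(feats), seq_along(feats),
                 Vectorize(function(i, j)
                   if (i == j) 0 else
                     symmetrical_uncertainty(disc[[i]], disc[[j]])))
  k <- 3
  rcf <- mean(su_fc); rff <- mean(su_ff[upper.tri(su_ff)])
  expected <- k * rcf / sqrt(k + k * (k - 1) * rff)
  expect_equal(cfs_merit(feats, tab), expected, tolerance = 1e-12)
})

test_that("genetic search is deterministic and finds planted predictors", {
  tab <- make_feature_table(n_per_class = 25, informative = 1, noise = 9,
                            delta = 6, seed = 67)
  g1 <- genetic_search(tab, seed = 1)
  g2 <- genetic_search(tab, seed = 1)
  expect_identical(g1$subset, g2$subset)
  expect_equal(g1$merit, g2$merit)
  expect_true("inf1" %in% g1$subset)
  # merit dominates every singleton
  singles <- vapply(setdiff(names(tab), "class"),
                    function(f) cfs_merit(f, tab), numeric(1))
  expect_gte(g1$merit, max(singles) - 1e-12)
})

test_that("the union rule combines CFS and IG selections with a floor", {
  tab <- make_feature_table(n_per_class = 30, informative = 2, noise = 6,
                            delta = 4, seed = 71)
  sel <- select_union(tab, ig_top_k = 3, seed = 1)
  expect_s3_class(sel, "selection_result")
  expect_setequal(sel$final_set, union(sel$cfs_subset, sel$ig_top))
  expect_true(all(c("inf1", "inf2") %in% sel$final_set))
  expect_identical(sel$ig_ranking$feature[1:2] %in% c("inf1", "inf2"),
                   c(TRUE, TRUE))
  # ig_top_k = 0 keeps the CFS subset alone
  sel0 <- select_union(tab, ig_top_k = 0, seed = 1)
  expect_setequal(sel0$final_set, sel0$cfs_subset)
  # capped at the feature count
  selA <- select_union(tab, ig_top_k = 999, ig_positive_only = FALSE,
                       seed = 1)
  expect_lte(length(selA$ig_top), length(setdiff(names(tab), "class")))
})

test_that("selection results round-trip through JSON", {
  tab <- make_feature_table(seed = 73)
  sel <- select_union(tab, seed = 1)
  f <- tempfile(fileext = ".json")
  write_selection(sel, f)
  sel2 <- read_selection(f)
  expect_setequal(sel2$final_set, sel$final_set)
  expect_equal(sel2$cfs_merit, sel$cfs_merit)
})
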
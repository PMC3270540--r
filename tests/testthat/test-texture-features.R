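# Extended Haralick statistics, classic features and the feature vector.

test_that("degenerate and uniform distributions give the textbook identities", {
  delta <- cooc_tensor(matrix(c(3L, 3L), 1), 1, L = 8, normalized = TRUE)
  h <- extended_haralick(delta)
  expect_equal(unname(h["energy"]), 1)
  expect_equal(unname(h["entropy"]), 0)
  expect_equal(unname(h["contrast"]), 0)
  expect_equal(unname(h["homogeneity"]), 1)
  expect_equal(unname(h["max_probability"]), 1)

  K <- 7L
  tuples <- cbind(0:6, 0:6, 0:6)
  unif <- cooc_tensor(tuples, rep(1 / K, K), L = 8, normalized = TRUE)
  hu <- extended_haralick(unif)
  expect_equal(unname(hu["entropy"]), log(K), tolerance = 1e-12)
  expect_equal(unname(hu["energy"]), 1 / K, tolerance = 1e-12)
  expect_equal(unname(hu["contrast"]), 0)  # equal-component tuples

  expect_error(extended_haralick(cooc_tensor(matrix(1L, 1, 2), 2, L = 4)),
               "normalized")
})

test_that("order-2 features reduce to the classical Haralick definitions", {
  # fixed two-level 6x6 image plus random 8x8 images, all four directions
  img0 <- matrix(c(0L, 1L), 6, 6)
  imgs <- c(list(img0 * 200L),
            lapply(1:10, function(i) {
              set.seed(i)
              matrix(sample(0:255, 64, TRUE), 8, 8)
            }))
  dirs <- list(c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  for (img in imgs) {
    q <- quantize(img, 256)
    for (d in dirs) {
      p <- to_probability(count_cooccurrence(q, displacement_set(matrix(d, 1))))
      got <- extended_haralick(p)
      want <- classical_haralick(img, d[1], d[2], L = 256L)
      expect_equal(unname(got[names(want)]), unname(want),
                   tolerance = 1e-9)
    }
  }
})

test_that("entropy is bounded by log of the support size", {
  map <- random_map(10, 10, L = 4, seed = 17)
  for (ds in standard_direction_sets(3, "glcm")[1:3]) {
    p <- to_probability(count_cooccurrence(map, ds))
    h <- extended_haralick(p)
    expect_lte(unname(h["entropy"]), log(length(p$values)) + 1e-12)
  }
})

test_that("mean grey level is the plain average", {
  expect_equal(mean_grey(matrix(42L, 5, 5)), 42)
  expect_equal(mean_grey(cbind(matrix(0L, 4, 2), matrix(100L, 4, 2))), 50)
  expect_equal(mean_grey(matrix(c(0L, 50L, 100L, 150L), 2, 2)), 75)
})

test_that("laws features detect microstructure and ignore constants", {
  l0 <- laws_features(matrix(77L, 20, 20))
  expect_true(all(l0 == 0))
  expect_named(l0, c(t(outer(paste0("laws_", names(hotex:::laws_vectors)),
                             c("_frequency", "_density"), paste0))),
               ignore.order = TRUE)

  # bright kernel-scale spot (Gaussian blob, sigma 1.2 px)
  d2 <- outer((1:30) - 15.5, (1:30) - 15.5, function(a, b) a^2 + b^2)
  spotty <- round(100 + 155 * exp(-d2 / (2 * 1.2^2)))
  storage.mode(spotty) <- "integer"
  ls <- laws_features(spotty, threshold_k = 1)
  expect_gt(ls[["laws_spot_density"]], ls[["laws_wave_density"]])

  set.seed(23)
  wn <- matrix(sample(0:255, 2500, TRUE), 50, 50)
  lw <- laws_features(wn, threshold_k = 0)
  expect_gt(lw[["laws_edge_density"]], 0.25)
  expect_lt(lw[["laws_edge_density"]], 0.75)
  expect_error(laws_features(matrix(1L, 3, 3)), "5x5")
})

test_that("wavelet entropies have the 20-subband contract", {
  w <- wavelet_entropies(matrix(123L, 50, 50))
  expect_length(w, 20L)
  detail <- grep("(LH|HL|HH)", names(w))
  expect_true(all(w[detail] == 0))
  expect_true(all(c("wl1_LL", "wl2_LL_HH", "wl2_HH_HH") %in% names(w)))
  # single dominant detail coefficient -> zero entropy in that subband
  img <- matrix(0L, 8, 8)
  img[1, 1] <- 255L
  w2 <- wavelet_entropies(img)
  expect_equal(w2[["wl1_HH"]], 0)
  expect_error(wavelet_entropies(matrix(1L, 3, 3)), "4x4")
})

test_that("wavelet entropy follows the squared-coefficient distribution", {
  set.seed(31)
  img <- matrix(sample(0:255, 400, TRUE), 20, 20)
  # independent oracle: direct Haar transform via matrix products
  H <- function(n) {
    m <- matrix(0, n, n)
    for (i in seq_len(n / 2)) {
      m[i, 2 * i - 1] <- 1 / sqrt(2); m[i, 2 * i] <- 1 / sqrt(2)
      m[n / 2 + i, 2 * i - 1] <- 1 / sqrt(2); m[n / 2 + i, 2 * i] <- -1 / sqrt(2)
    }
    m
  }
  t1 <- H(20) %*% img %*% t(H(20))
  ll <- t1[1:10, 1:10]; hh <- t1[11:20, 11:20]
  ent <- function(c) {
    e <- c^2; p <- e[e > 0] / sum(e); -sum(p * log(p))
  }
  w <- wavelet_entropies(img)
  expect_equal(w[["wl1_LL"]], ent(ll), tolerance = 1e-9)
  expect_equal(w[["wl1_HH"]], ent(hh), tolerance = 1e-9)
})

test_that("the feature vector has a stable schema and honest constants", {
  cfg <- default_config()
  roi <- matrix(99L, 50, 50)
  fv <- compute_feature_vector(roi, cfg)
  expect_equal(unname(fv["mean_grey"]), 99)
  expect_equal(unname(fv["glcm2_avg_entropy"]), 0)
  # constant image has no edges: EOCM features missing, not fatal
  expect_true(is.na(fv["eocm2_avg_entropy"]))

  set.seed(37)
  roi2 <- matrix(sample(0:255, 2500, TRUE), 50, 50)
  fv2 <- compute_feature_vector(roi2, cfg)
  expect_identical(names(fv2), names(fv))

  cfg3 <- default_config(glcm3_mode = "0_270")
  fv3 <- compute_feature_vector(roi2, cfg3)
  expect_true("glcm3_0_270_entropy" %in% names(fv3))
  expect_false("glcm3_avg_entropy" %in% names(fv3))
  expect_error(compute_feature_vector(roi2, default_config(glcm3_mode = "0_99")),
               "unknown order-3")
})

test_that("direction averaging happens at the feature level", {
  set.seed(41)
  img <- matrix(sample(0:255, 2500, TRUE), 50, 50)
  q <- quantize(img, 256)
  sets <- standard_direction_sets(2, "glcm")
  per_dir <- vapply(sets, function(ds)
    extended_haralick(to_probability(count_cooccurrence(q, ds)))["entropy"],
    numeric(1))
  fv <- compute_feature_vector(img, default_config())
  expect_equal(unname(fv["glcm2_avg_entropy"]), mean(per_dir),
               tolerance = 1e-12)
})
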
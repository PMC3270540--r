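# Independent oracles used across the suite.

# Brute-force order-n cooccurrence enumerator.  For every mask-valid
# anchor pixel it scans ALL pixels for every neighbor slot and tests the
# matching predicate directly:
#   |x_{i+1} - x1| == |dx_i|, |y_{i+1} - y1| == |dy_i|,
#   sgn((x_{i+1} - x1)(y_{i+1} - y1)) == sgn(dx_i * dy_i),
# then enumerates every combination of valid slot assignments.  Counts are
# returned as a named vector keyed by "g1,g2,...".
brute_cooc <- function(map, dset) {
  labs <- map$labels
  mask <- map$valid_mask
  h <- nrow(labs); w <- ncol(labs)
  vecs <- dset$vectors
  n1 <- nrow(vecs)
  # pixel list (x = col, y = row), 0-based like nothing in particular --
  # only differences matter
  px <- as.vector(col(labs)); py <- as.vector(row(labs))
  pl <- as.vector(labs); pm <- as.vector(mask)
  counts <- new.env(parent = emptyenv())
  for (a in which(pm)) {
    x1 <- px[a]; y1 <- py[a]
    slot_labels <- vector("list", n1)
    ok_all <- TRUE
    for (i in seq_len(n1)) {
      dx <- vecs[i, "dx"]; dy <- vecs[i, "dy"]
      cand <- pm &
        abs(px - x1) == abs(dx) &
        abs(py - y1) == abs(dy) &
        sign((px - x1) * (py - y1)) == sign(dx * dy)
      if (!any(cand)) { ok_all <- FALSE; break }
      slot_labels[[i]] <- pl[cand]
    }
    if (!ok_all) next
    tuples <- expand.grid(slot_labels, KEEP.OUT.ATTRS = FALSE)
    keys <- do.call(paste, c(list(pl[a]), tuples, sep = ","))
    for (k in keys) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
    }
  }
  unlist(as.list(counts))
}

tensor_as_named <- function(tensor) {
  if (!length(tensor$values)) return(stats::setNames(numeric(0), character(0)))
  keys <- apply(tensor$tuples, 1L, paste, collapse = ",")
  stats::setNames(tensor$values, keys)
}

expect_same_counts <- function(tensor, brute) {
  got <- tensor_as_named(tensor)
  expect_equal(sort(names(got)), sort(names(brute)))
  if (length(brute)) {
    expect_identical(unname(got[names(brute)]), unname(brute))
  }
}

# Classical order-2 Haralick oracle: builds the dense symmetric GLCM for a
# single displacement by explicit double loops, then evaluates the
# textbook formulas.
classical_haralick <- function(image, dx, dy, L = 256L) {
  g <- floor(image * L / 256)
  h <- nrow(g); w <- ncol(g)
  P <- matrix(0, L, L)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      for (s in c(1L, -1L)) {
        r2 <- r + s * dy; c2 <- c + s * dx
        if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w) {
          P[g[r, c] + 1L, g[r2, c2] + 1L] <-
            P[g[r, c] + 1L, g[r2, c2] + 1L] + 1
        }
      }
    }
  }
  P <- P / sum(P)
  lev <- 0:(L - 1L)
  I <- matrix(lev, L, L); J <- t(I)
  mu_x <- sum(I * P); mu_y <- sum(J * P)
  sd_x <- sqrt(sum((I - mu_x)^2 * P)); sd_y <- sqrt(sum((J - mu_y)^2 * P))
  nz <- P > 0
  mu <- sum(P * (I + J) / 2)
  c(energy = sum(P^2),
    entropy = -sum(P[nz] * log(P[nz])),
    contrast = sum(P * (I - J)^2),
    homogeneity = sum(P / (1 + (I - J)^2)),
    correlation = if (sd_x > 0 && sd_y > 0)
      sum((I - mu_x) * (J - mu_y) * P) / (sd_x * sd_y) else 0,
    variance = sum(P * ((I - mu)^2 + (J - mu)^2) / 2),
    max_probability = max(P))
}

# Random quantized map, optionally with a random mask.
random_map <- function(h, w, L, seed, masked = FALSE) {
  set.seed(seed)
  labels <- matrix(sample.int(L, h * w, replace = TRUE) - 1L, h, w)
  mask <- if (masked) matrix(stats::runif(h * w) > 0.25, h, w)
          else matrix(TRUE, h, w)
  quantized_map(labels, L, mask)
}

# Build an orientation map directly from a vector of angles (degrees).
fake_orientation_map <- function(angles_deg) {
  n <- length(angles_deg)
  structure(list(orientation = matrix(as.integer(angles_deg), 1L, n),
                 edge_mask = matrix(TRUE, 1L, n),
                 gx = matrix(1, 1L, n), gy = matrix(0, 1L, n),
                 bin_width = 1L),
            class = "orientation_map")
}

# Small seeded feature table: `informative` features shift with the class,
# the rest are pure noise.
make_feature_table <- function(n_per_class = 25L, informative = 2L,
                               noise = 8L, delta = 3, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  cls <- rep(c("a", "b"), each = n_per_class)
  cols <- list()
  for (i in seq_len(informative)) {
    cols[[paste0("inf", i)]] <-
      stats::rnorm(n) + ifelse(cls == "a", 0, delta)
  }
  for (i in seq_len(noise)) {
    cols[[paste0("noise", i)]] <- stats::rnorm(n)
  }
  data.frame(cols, class = cls, stringsAsFactors = FALSE)
}

# Discretize a numeric column the way the selection module does, for
# independent recomputation of SU/IG/merit in tests.
bin_by_cuts <- function(values, cuts) {
  out <- rep.int(0L, length(values))
  ok <- !is.na(values)
  out[ok] <- findInterval(values[ok], cuts) + 1L
  out
}

# Plug-in Shannon entropy (nats) of a label vector.
discrete_entropy_oracle <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

# Exhaustive CFS merit maximum over all nonempty subsets of <= 15 features,
# from precomputed SU values (hand implementation of the merit formula).
exhaustive_best_merit <- function(su_fc, su_ff) {
  p <- length(su_fc)
  best <- -Inf; best_set <- integer(0)
  for (mask in seq_len(2^p - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    k <- length(idx)
    rcf <- mean(su_fc[idx])
    m <- if (k == 1L) rcf else {
      rff <- mean(su_ff[idx, idx][upper.tri(diag(k))])
      k * rcf / sqrt(k + k * (k - 1) * rff)
    }
    if (m > best) { best <- m; best_set <- idx }
  }
  list(merit = best, idx = best_set)
}
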
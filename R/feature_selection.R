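## Relevant-feature selection: supervised MDL discretization, symmetrical
## uncertainty, information-gain ranking, CFS merit and genetic search.
##
## A feature table is a data.frame of numeric feature columns plus a
## `class` column (character or factor) with at least two labels.

check_feature_table <- function(table) {
  if (!is.data.frame(table) || !"class" %in% names(table))
    stop_validation("feature table must be a data.frame with a 'class' column")
  cls <- table$class
  if (anyNA(cls))
    stop_validation("feature table has missing class labels")
  tab <- table(cls)
  if (length(tab) < 2L)
    stop_validation("feature table needs at least 2 class labels")
  if (min(tab) < 2L)
    stop_validation("every class needs at least 2 rows")
  invisible(table)
}

feature_columns <- function(table) setdiff(names(table), "class")

## entropies -----------------------------------------------------------------

# Shannon entropy of a discrete label vector, in the units of `log`.
discrete_entropy <- function(x, log_base = exp(1)) {
  p <- tabulate(as.integer(factor(x)))
  p <- p[p > 0] / length(x)
  -sum(p * log(p, base = log_base))
}

joint_entropy <- function(a, b, log_base = exp(1)) {
  discrete_entropy(paste(a, b, sep = "\r"), log_base)
}

## MDL discretization --------------------------------------------------------

# Entropy in bits of a class label subset, from a count table.
ent_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

mdl_cuts_recurse <- function(values, cls_int, n_classes) {
  n <- length(values)
  if (n < 4L) return(numeric(0))
  ord <- order(values)
  v <- values[ord]; y <- cls_int[ord]
  counts_all <- tabulate(y, n_classes)
  E <- ent_bits(counts_all)
  k <- sum(counts_all > 0)
  if (k < 2L) return(numeric(0))
  # candidate boundaries: between adjacent distinct values
  distinct_last <- which(diff(v) > 0)
  if (!length(distinct_last)) return(numeric(0))
  best <- NULL
  best_gain <- -Inf
  left <- matrix(0, n_classes, 1L)
  cum <- apply(outer(y, seq_len(n_classes), "=="), 2L, cumsum)
  for (i in distinct_last) {
    c1 <- cum[i, ]; c2 <- counts_all - c1
    E1 <- ent_bits(c1); E2 <- ent_bits(c2)
    gain <- E - (i / n) * E1 - ((n - i) / n) * E2
    if (gain > best_gain) {
      best_gain <- gain
      best <- list(i = i, E1 = E1, E2 = E2,
                   k1 = sum(c1 > 0), k2 = sum(c2 > 0))
    }
  }
  delta <- log2(3^k - 2) - (k * E - best$k1 * best$E1 - best$k2 * best$E2)
  threshold <- (log2(n - 1) + delta) / n
  if (best_gain <= threshold) return(numeric(0))
  cut <- (v[best$i] + v[best$i + 1L]) / 2
  lo <- values <= cut
  c(mdl_cuts_recurse(values[lo], cls_int[lo], n_classes),
    cut,
    mdl_cuts_recurse(values[!lo], cls_int[!lo], n_classes))
}

#' Supervised MDL discretization
#'
#' Fayyad–Irani entropy-based binary splitting with the minimum
#' description length stopping criterion.  Features where no cut is
#' accepted collapse to a single bin (zero information about the class).
#'
#' @param values Numeric column (`NA` allowed; ignored when placing cuts).
#' @param classes Class label vector, same length.
#' @return Sorted numeric cut points (possibly empty).
#' @export
mdl_discretize <- function(values, classes) {
  if (length(values) != length(classes))
    stop_validation("values and classes must have the same length")
  ok <- !is.na(values)
  if (sum(ok) < 4L) return(numeric(0))
  cls_int <- as.integer(factor(classes[ok]))
  sort(mdl_cuts_recurse(values[ok], cls_int, max(cls_int)))
}

# Apply cut points; NA values get their own bin (0).
apply_cuts <- function(values, cuts) {
  out <- rep.int(0L, length(values))
  ok <- !is.na(values)
  out[ok] <- findInterval(values[ok], cuts) + 1L
  out
}

# Discretize every feature column against the class.
discretize_table <- function(table) {
  check_feature_table(table)
  feats <- feature_columns(table)
  disc <- lapply(table[feats], function(v)
    apply_cuts(v, mdl_discretize(v, table$class)))
  list(features = as.data.frame(disc, optional = TRUE),
       class = as.character(table$class))
}

#' Symmetrical uncertainty between two discrete columns
#'
#' `SU = 2 (H(a) + H(b) - H(a,b)) / (H(a) + H(b))`, in `[0, 1]`; defined
#' as 0 when both entropies are 0.
#'
#' @param a,b Discrete label vectors of equal length.
#' @return Symmetrical uncertainty in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(a, b) {
  if (length(a) != length(b))
    stop_validation("columns must have the same length")
  ha <- discrete_entropy(a); hb <- discrete_entropy(b)
  if (ha + hb <= 0) return(0)
  su <- 2 * (ha + hb - joint_entropy(a, b)) / (ha + hb)
  min(max(su, 0), 1)
}

#' Information gain of an attribute about the class
#'
#' `IG = H(C) - H(C | A)` with plug-in entropies (natural log).
#'
#' @param attr Discrete attribute vector.
#' @param cls Class label vector, same length.
#' @return Information gain in nats, in `[0, H(C)]`.
#' @export
info_gain <- function(attr, cls) {
  if (length(attr) != length(cls))
    stop_validation("columns must have the same length")
  hc <- discrete_entropy(cls)
  hca <- joint_entropy(attr, cls) - discrete_entropy(attr)
  max(hc - hca, 0)
}

## CFS ------------------------------------------------------------------------

# Precompute the feature-class and feature-feature SU tables once.
cfs_precompute <- function(disc) {
  feats <- names(disc$features)
  p <- length(feats)
  su_fc <- vapply(disc$features, symmetrical_uncertainty,
                  numeric(1L), b = disc$class)
  su_ff <- matrix(0, p, p, dimnames = list(feats, feats))
  if (p >= 2L) {
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        su <- symmetrical_uncertainty(disc$features[[i]],
                                      disc$features[[j]])
        su_ff[i, j] <- su_ff[j, i] <- su
      }
    }
  }
  list(features = feats, su_fc = su_fc, su_ff = su_ff)
}

merit_from_su <- function(idx, su_fc, su_ff) {
  k <- length(idx)
  if (k == 0L) return(0)
  rcf <- mean(su_fc[idx])
  if (k == 1L) return(rcf)
  rff <- mean(su_ff[idx, idx][upper.tri(diag(k))])
  denom <- sqrt(k + k * (k - 1) * rff)
  if (denom <= 0) return(0)
  k * rcf / denom
}

#' CFS merit of a feature subset
#'
#' Heuristic merit `k * r_cf / sqrt(k + k (k - 1) * r_ff)`, where `r_cf`
#' is the mean symmetrical uncertainty between subset features and the
#' class and `r_ff` the mean pairwise symmetrical uncertainty between
#' subset features (the redundancy term vanishes at `k = 1`).  Features
#' are discretized with [mdl_discretize()] first.
#'
#' @param subset Character vector of feature names.
#' @param table Feature table (data.frame with `class` column).
#' @return The merit (finite, `>= 0`).
#' @export
cfs_merit <- function(subset, table) {
  check_feature_table(table)
  if (!length(subset))
    stop_validation("subset must contain at least one feature")
  missing <- setdiff(subset, feature_columns(table))
  if (length(missing))
    stop_validation("features not in table: %s",
                    paste(missing, collapse = ", "))
  disc <- discretize_table(table[c(subset, "class")])
  pre <- cfs_precompute(disc)
  merit_from_su(seq_along(subset), pre$su_fc, pre$su_ff)
}

#' Genetic search for the best CFS subset
#'
#' Bitstring chromosomes over the features, fitness = CFS merit, roulette
#' selection, single-point crossover, per-bit mutation, elitism of one,
#' best-ever subset retained.  Defaults are the method's standard
#' settings: population 20, 20 generations, crossover probability 0.6,
#' mutation probability 0.033, seed 1.
#'
#' @param table Feature table.
#' @param population Population size.
#' @param generations Number of generations.
#' @param crossover Single-point crossover probability.
#' @param mutation Per-bit mutation probability.
#' @param seed RNG seed.
#' @return List with `subset` (feature names) and `merit`.
#' @export
genetic_search <- function(table, population = 20L, generations = 20L,
                           crossover = 0.6, mutation = 0.033, seed = 1L) {
  check_feature_table(table)
  disc <- discretize_table(table)
  pre <- cfs_precompute(disc)
  p <- length(pre$features)
  if (p < 2L)
    stop_validation("genetic search needs at least 2 features")
  if (!is.null(seed)) set.seed(seed)
  fitness <- function(bits) {
    merit_from_su(which(bits), pre$su_fc, pre$su_ff)
  }
  pop <- matrix(stats::runif(population * p) < 0.5, population, p)
  fits <- apply(pop, 1L, fitness)
  best_bits <- pop[which.max(fits), ]
  best_fit <- max(fits)
  for (g in seq_len(generations)) {
    probs <- if (sum(fits) > 0) fits / sum(fits)
             else rep(1 / population, population)
    new_pop <- matrix(FALSE, population, p)
    new_pop[1L, ] <- best_bits  # elitism
    i <- 2L
    while (i <= population) {
      parents <- sample.int(population, 2L, replace = TRUE, prob = probs)
      c1 <- pop[parents[1L], ]; c2 <- pop[parents[2L], ]
      if (stats::runif(1L) < crossover && p >= 2L) {
        cp <- sample.int(p - 1L, 1L)
        tmp <- c1
        c1 <- c(c1[seq_len(cp)], c2[(cp + 1L):p])
        c2 <- c(c2[seq_len(cp)], tmp[(cp + 1L):p])
      }
      flip1 <- stats::runif(p) < mutation
      flip2 <- stats::runif(p) < mutation
      c1 <- xor(c1, flip1); c2 <- xor(c2, flip2)
      new_pop[i, ] <- c1
      if (i + 1L <= population) new_pop[i + 1L, ] <- c2
      i <- i + 2L
    }
    pop <- new_pop
    fits <- apply(pop, 1L, fitness)
    gen_best <- which.max(fits)
    if (fits[gen_best] > best_fit) {
      best_fit <- fits[gen_best]
      best_bits <- pop[gen_best, ]
    }
  }
  list(subset = pre$features[best_bits], merit = best_fit)
}

#' Select the final relevant feature set
#'
#' Runs CFS with genetic search and information-gain ranking, and returns
#' their union: the final relevant set is the CFS subset together with the
#' `ig_top_k` features of highest information gain.
#'
#' @param table Feature table.
#' @param ig_top_k How many top-ranked IG features enter the union
#'   (default 10; capped at the feature count; 0 keeps the CFS subset
#'   alone).
#' @param ig_positive_only Drop zero-gain features from the IG cut
#'   (default `TRUE`).
#' @param population,generations,crossover,mutation,seed Genetic-search
#'   settings, see [genetic_search()].
#' @return A `selection_result`: list with `cfs_subset`, `cfs_merit`,
#'   `ig_ranking` (data.frame `feature`, `info_gain`), `ig_top` and
#'   `final_set`.
#' @export
select_union <- function(table, ig_top_k = 10L, ig_positive_only = TRUE,
                         population = 20L, generations = 20L,
                         crossover = 0.6, mutation = 0.033, seed = 1L) {
  check_feature_table(table)
  feats <- feature_columns(table)
  disc <- discretize_table(table)
  ig <- vapply(disc$features, info_gain, numeric(1L), cls = disc$class)
  ranking <- data.frame(feature = feats, info_gain = unname(ig),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$info_gain, ranking$feature), ]
  rownames(ranking) <- NULL
  if (length(feats) >= 2L) {
    ga <- genetic_search(table, population, generations, crossover,
                         mutation, seed)
  } else {
    ga <- list(subset = character(0), merit = 0)
  }
  k <- min(as.integer(ig_top_k), length(feats))
  ig_top <- ranking$feature[seq_len(max(k, 0L))]
  if (ig_positive_only) ig_top <- ig_top[ranking$info_gain[seq_len(max(k, 0L))] > 0]
  final <- union(ga$subset, ig_top)
  if (!length(final)) final <- ranking$feature[1L]
  structure(list(cfs_subset = ga$subset, cfs_merit = ga$merit,
                 ig_ranking = ranking, ig_top = ig_top,
                 final_set = final, ig_top_k = k),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Relevant-feature selection\n")
  cat(sprintf("  CFS (genetic search): %d features, merit %.4f\n",
              length(x$cfs_subset), x$cfs_merit))
  cat(sprintf("  IG top-%d: %s\n", x$ig_top_k,
              paste(utils::head(x$ig_top, 10L), collapse = ", ")))
  cat(sprintf("  Final set (union): %d features\n", length(x$final_set)))
  invisible(x)
}

#' Write a selection result as JSON
#'
#' @param selection A `selection_result`.
#' @param path Output path.
#' @export
write_selection <- function(selection, path) {
  stopifnot(inherits(selection, "selection_result"))
  jsonlite::write_json(
    list(cfs_subset = selection$cfs_subset,
         cfs_merit = selection$cfs_merit,
         ig_ranking = selection$ig_ranking,
         ig_top = selection$ig_top,
         final_set = selection$final_set,
         ig_top_k = selection$ig_top_k),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a selection result from JSON
#'
#' @param path Path written by [write_selection()].
#' @return A `selection_result`.
#' @export
read_selection <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(cfs_subset = as.character(x$cfs_subset),
                 cfs_merit = x$cfs_merit,
                 ig_ranking = as.data.frame(x$ig_ranking),
                 ig_top = as.character(x$ig_top),
                 final_set = as.character(x$final_set),
                 ig_top_k = x$ig_top_k),
            class = "selection_result")
}
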
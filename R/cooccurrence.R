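## Sparse order-n cooccurrence counting.
##
## An order-n cooccurrence matrix C_D(g1, ..., gn) counts pixel n-tuples
## whose first element (the anchor) is related to the other n-1 pixels by a
## set of displacement vectors d_i = (dx_i, dy_i).  Matching is by absolute
## coordinate difference with a sign constraint on the product of the
## differences, so each displacement vector contributes both its +d and -d
## placements.  The same engine serves grey-level maps (GLCM) and
## edge-orientation maps (EOCM, with valid_mask marking edge pixels).

#' Construct a displacement set
#'
#' @param vectors Integer matrix with `order - 1` rows and columns
#'   `dx`, `dy`; `dx` is the column offset (x increasing rightwards), `dy`
#'   the row offset (y increasing downward).
#' @param name Optional tag (e.g. `"0_270"`).
#' @return A `displacement_set` object.
#' @export
displacement_set <- function(vectors, name = NULL) {
  vectors <- matrix(as.integer(vectors), ncol = 2L,
                    dimnames = list(NULL, c("dx", "dy")))
  if (nrow(vectors) < 1L)
    stop_validation("a displacement set needs at least one vector")
  if (any(rowSums(abs(vectors)) == 0L))
    stop_validation("every displacement vector needs a nonzero component")
  structure(list(order = nrow(vectors) + 1L, vectors = vectors,
                 name = name),
            class = "displacement_set")
}

# Map an angle (degrees, image y axis pointing down) to an integer offset
# with component magnitude m: the unit direction is rounded first, then
# scaled, so 45-degree multiples give components in {0, +/-m}.
angle_to_offset <- function(theta, m) {
  rad <- theta * pi / 180
  c(dx = as.integer(round(cos(rad)) * m),
    dy = as.integer(round(-sin(rad)) * m))
}

#' Standard displacement-vector direction sets
#'
#' The direction geometries used by the method:
#' order 2 uses the four classical directions 0, 45, 90, 135 degrees
#' (magnitude `d2`, default 1); order 3 uses the four collinear pairs
#' (0,180), (90,270), (45,225), (135,315) and the eight right-angle pairs
#' (0,90), (90,180), (180,270), (0,270), (45,135), (135,225), (225,315),
#' (45,315), all with component magnitude `d_high` (default 2); order 5
#' uses the two groups (0,180,90,270) and (45,225,135,315), also at
#' magnitude `d_high`.  The EOCM family uses the order-2 and order-3
#' geometries only.
#'
#' @param order 2, 3 or 5.
#' @param family `"glcm"` or `"eocm"`.
#' @param d2 Displacement magnitude for order 2 (default 1).
#' @param d_high Component magnitude for orders 3 and 5 (default 2).
#' @return A list of [displacement_set()] objects, named by their angle
#'   combination (e.g. `"0_270"`).
#' @export
standard_direction_sets <- function(order, family = c("glcm", "eocm"),
                                    d2 = 1L, d_high = 2L) {
  family <- match.arg(family)
  if (!order %in% c(2L, 3L, 5L))
    stop_validation("order must be 2, 3 or 5, got %s", deparse(order))
  if (family == "eocm" && order == 5L)
    stop_validation("EOCM direction sets are defined for orders 2 and 3 only")
  angle_groups <- switch(as.character(order),
    "2" = list(0, 45, 90, 135),
    "3" = list(c(0, 180), c(90, 270), c(45, 225), c(135, 315),
               c(0, 90), c(90, 180), c(180, 270), c(0, 270),
               c(45, 135), c(135, 225), c(225, 315), c(45, 315)),
    "5" = list(c(0, 180, 90, 270), c(45, 225, 135, 315)))
  m <- if (order == 2L) d2 else d_high
  sets <- lapply(angle_groups, function(angles) {
    vecs <- t(vapply(angles, angle_to_offset, integer(2L), m = m))
    displacement_set(vecs, name = paste(angles, collapse = "_"))
  })
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  sets
}

# Neighbor label matrix for a single signed offset: entry [r, c] is the
# label at (r + dy, c + dx) where that position is in bounds and
# mask-valid, NA otherwise.
shifted_labels <- function(map, dx, dy) {
  h <- nrow(map$labels); w <- ncol(map$labels)
  out <- matrix(NA_integer_, h, w)
  rs <- seq_len(h) + dy
  cs <- seq_len(w) + dx
  rok <- rs >= 1L & rs <= h
  cok <- cs >= 1L & cs <= w
  if (!any(rok) || !any(cok)) return(out)
  src <- map$labels
  src[!map$valid_mask] <- NA_integer_
  out[rok, cok] <- src[rs[rok], cs[cok], drop = FALSE]
  out
}

#' Count order-n cooccurrences
#'
#' For every mask-valid anchor pixel and every placement of the `n - 1`
#' neighbors consistent with the displacement set (each vector matches both
#' its `+d` and `-d` placement; neighbors must be in bounds and
#' mask-valid), the label n-tuple count is incremented.
#'
#' @param map A `quantized_map`.
#' @param dset A [displacement_set()].
#' @return A `cooc_tensor`: sparse tuple counts with fields `order`, `L`,
#'   `tuples` (integer matrix, one row per distinct tuple), `values`,
#'   `normalized` and `total`.
#' @export
count_cooccurrence <- function(map, dset) {
  stopifnot(inherits(map, "quantized_map"),
            inherits(dset, "displacement_set"))
  n1 <- nrow(dset$vectors)
  L <- map$L
  # all sign combinations: each vector contributes placements +v and -v
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n1)))
  anchor_ok <- map$valid_mask
  anchor_lab <- map$labels
  codes_all <- vector("list", nrow(signs))
  Lp <- as.numeric(L)
  for (s in seq_len(nrow(signs))) {
    ok <- anchor_ok
    code <- as.numeric(anchor_lab)
    mult <- Lp
    for (i in seq_len(n1)) {
      nb <- shifted_labels(map, signs[s, i] * dset$vectors[i, "dx"],
                           signs[s, i] * dset$vectors[i, "dy"])
      ok <- ok & !is.na(nb)
      nb[is.na(nb)] <- 0L
      code <- code + as.numeric(nb) * mult
      mult <- mult * Lp
    }
    codes_all[[s]] <- code[ok]
  }
  codes <- unlist(codes_all, use.names = FALSE)
  if (length(codes) == 0L) {
    return(cooc_tensor(matrix(integer(0L), 0L, n1 + 1L), numeric(0L), L))
  }
  r <- rle(sort(codes, method = "radix"))
  tuples <- decode_tuples(r$values, n1 + 1L, L)
  cooc_tensor(tuples, as.numeric(r$lengths), L)
}

decode_tuples <- function(codes, order, L) {
  out <- matrix(0L, length(codes), order)
  rest <- codes
  for (i in seq_len(order)) {
    out[, i] <- as.integer(rest %% L)
    rest <- (rest - out[, i]) / L
  }
  out
}

#' Construct a cooccurrence tensor
#'
#' @param tuples Integer matrix, one row per distinct label tuple.
#' @param values Nonnegative counts (or probabilities), one per row.
#' @param L Level count.
#' @param normalized Whether `values` are probabilities.
#' @param total Sum of the raw counts (defaults to `sum(values)` for raw
#'   tensors).
#' @return A `cooc_tensor` object.
#' @export
cooc_tensor <- function(tuples, values, L, normalized = FALSE,
                        total = NULL) {
  stopifnot(is.matrix(tuples), nrow(tuples) == length(values))
  if (length(values) && min(values) < 0)
    stop_validation("cooccurrence values must be nonnegative")
  if (is.null(total)) total <- if (normalized) NA_real_ else sum(values)
  structure(list(order = ncol(tuples), L = as.integer(L),
                 tuples = tuples, values = as.numeric(values),
                 normalized = isTRUE(normalized), total = total),
            class = "cooc_tensor")
}

#' Normalize a cooccurrence tensor to probabilities
#'
#' Divides every entry by the total count so that entries sum to 1.
#'
#' @param tensor A raw `cooc_tensor` with positive total.
#' @return The normalized `cooc_tensor`.
#' @export
to_probability <- function(tensor) {
  stopifnot(inherits(tensor, "cooc_tensor"))
  if (tensor$normalized) return(tensor)
  if (!length(tensor$values) || tensor$total <= 0)
    stop("degenerate cooccurrence tensor: total count is zero",
         call. = FALSE)
  cooc_tensor(tensor$tuples, tensor$values / tensor$total, tensor$L,
              normalized = TRUE, total = tensor$total)
}

#' @export
print.cooc_tensor <- function(x, ...) {
  cat(sprintf("Order-%d cooccurrence tensor: %d distinct tuples, L = %d, %s\n",
              x$order, nrow(x$tuples), x$L,
              if (x$normalized) "normalized"
              else sprintf("total count %g", x$total)))
  invisible(x)
}

#' Write a cooccurrence tensor as JSON lines
#'
#' One header record (`order`, `L`, `normalized`, `total`) followed by one
#' record `{"tuple": [...], "value": v}` per entry.
#'
#' @param tensor A `cooc_tensor`.
#' @param path Output path.
#' @export
write_cooc_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "cooc_tensor"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(order = tensor$order, L = tensor$L,
                               normalized = tensor$normalized,
                               total = tensor$total),
                          auto_unbox = TRUE, digits = NA)
  writeLines(hdr, con)
  for (i in seq_along(tensor$values)) {
    writeLines(jsonlite::toJSON(list(tuple = tensor$tuples[i, ],
                                     value = tensor$values[i]),
                                auto_unbox = FALSE, digits = NA), con)
  }
  invisible(path)
}

#' Read a cooccurrence tensor from JSON lines
#'
#' @param path Path written by [write_cooc_tensor()].
#' @return A `cooc_tensor`.
#' @export
read_cooc_tensor <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1L])
  if (length(lines) == 1L) {
    return(cooc_tensor(matrix(integer(0), 0L, hdr$order), numeric(0),
                       hdr$L, hdr$normalized, hdr$total))
  }
  recs <- lapply(lines[-1L], jsonlite::fromJSON)
  tuples <- do.call(rbind, lapply(recs, `[[`, "tuple"))
  values <- vapply(recs, function(r) as.numeric(r$value), numeric(1L))
  cooc_tensor(tuples, values, hdr$L, hdr$normalized, hdr$total)
}
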
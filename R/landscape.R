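# Exact piecewise-linear persistence landscapes.
#
# Each diagram pair (b, d) contributes a tent of height (d - b)/2 supported
# on [b, d]; lambda_k(t) is the k-th largest tent value at t. All layers are
# stored as exact PL functions (knot lists), never on a fixed grid: the only
# scales at which the pointwise ranking of tents can change are tent
# endpoints and pairwise side intersections (b_i + d_j)/2, so evaluating on
# that candidate set and pruning collinear knots is exact.

#' Construct a persistence landscape object
#'
#' @param layers list of two-column matrices `(t, value)`: the critical
#'   points of lambda_1, lambda_2, ... Each layer must be non-negative with
#'   zero boundary values.
#' @param max_layers number of layers that were requested/kept.
#' @param source_id label.
#' @return object of class `persistence_landscape`.
#' @export
persistence_landscape <- function(layers, max_layers = length(layers),
                                  source_id = "landscape") {
  layers <- lapply(layers, function(L) {
    L <- as.matrix(L)
    colnames(L) <- c("t", "value")
    assert_that(all(L[, 2L] >= -1e-12), "landscape layers must be non-negative")
    L
  })
  structure(list(layers = layers, max_layers = as.integer(max_layers),
                 source_id = source_id),
            class = "persistence_landscape")
}

#' @export
print.persistence_landscape <- function(x, ...) {
  cat(sprintf("<persistence_landscape %s: %d layer(s)>\n",
              x$source_id, length(x$layers)))
  for (k in seq_along(x$layers)) {
    L <- x$layers[[k]]
    if (k > 3L) { cat("  ...\n"); break }
    cat(sprintf("  lambda_%d: sup %.3f on [%.2f, %.2f]\n", k,
                max(L[, 2L]), min(L[, 1L]), max(L[, 1L])))
  }
  invisible(x)
}

#' Build the persistence landscape of a diagram
#'
#' @param diagram a [persistence_diagram()].
#' @param max_layers keep at most this many layers (default 10).
#' @return a [persistence_landscape()] with exact critical points; an empty
#'   diagram gives the zero landscape (no layers).
#' @export
diagram_to_landscape <- function(diagram, max_layers = 10L) {
  assert_that(max_layers >= 1L, "`max_layers` must be >= 1")
  bd <- diagram$pairs
  keep <- bd[, 2L] > bd[, 1L]
  bd <- bd[keep, , drop = FALSE]
  if (nrow(bd) == 0L)
    return(persistence_landscape(list(), max_layers, diagram$source_id))

  cand <- sort(unique(c(bd[, 1L], bd[, 2L],
                        as.vector(outer(bd[, 1L], bd[, 2L], "+")) / 2)))
  vals <- landscape_eval_cpp(bd, cand, as.integer(min(max_layers, nrow(bd))))
  layers <- list()
  for (k in seq_len(nrow(vals))) {
    if (all(vals[k, ] <= 0)) break
    layers[[k]] <- prune_collinear(cand, vals[k, ])
  }
  persistence_landscape(layers, max_layers, diagram$source_id)
}

#' Evaluate one landscape layer at arbitrary scales
#'
#' Linear interpolation of the stored critical points; zero outside the
#' support and for absent layers.
#'
#' @param landscape a [persistence_landscape()].
#' @param k layer index (1-based).
#' @param t numeric vector of scales.
#' @return numeric vector of lambda_k(t).
#' @export
eval_landscape <- function(landscape, k, t) {
  if (k > length(landscape$layers)) return(rep(0, length(t)))
  L <- landscape$layers[[k]]
  if (nrow(L) == 1L) return(rep(0, length(t)))
  approx(L[, 1L], L[, 2L], xout = t, yleft = 0, yright = 0)$y
}

# union of critical abscissae over a set of landscapes (and optional layers)
landscape_knots <- function(landscapes, layers = NULL) {
  sort(unique(unlist(lapply(landscapes, function(l) {
    ks <- layers %||% seq_along(l$layers)
    unlist(lapply(ks[ks <= length(l$layers)],
                  function(k) l$layers[[k]][, 1L]))
  }))))
}

#' Average a list of persistence landscapes
#'
#' Pointwise arithmetic mean per layer, computed exactly on the union of all
#' members' critical abscissae; landscapes lacking a layer contribute the
#' zero function to it. Averages are PL but their slopes are generally not in
#' \{-1, 0, 1\}.
#'
#' @param landscapes non-empty list of [persistence_landscape()]s.
#' @return a [persistence_landscape()].
#' @export
average_landscape <- function(landscapes) {
  assert_that(length(landscapes) > 0L, "cannot average an empty list")
  n_layers <- max(vapply(landscapes, function(l) length(l$layers), 1L))
  if (n_layers == 0L)
    return(persistence_landscape(list(), source_id = "average"))
  knots <- landscape_knots(landscapes)
  layers <- list()
  for (k in seq_len(n_layers)) {
    m <- rowMeans(vapply(landscapes, eval_landscape, numeric(length(knots)),
                         k = k, t = knots))
    if (all(m <= 0)) break
    layers[[k]] <- prune_collinear(knots, m)
  }
  persistence_landscape(layers,
                        max_layers = max(vapply(landscapes, `[[`, 1L, "max_layers")),
                        source_id = "average")
}

#' Distance between two persistence landscapes
#'
#' `L1` is the sum over layers of the exact integral of |lambda_k^a -
#' lambda_k^b| (PL segments are integrated in closed form, splitting at sign
#' changes); `sup` is the maximum absolute difference, attained at a knot of
#' the union partition.
#'
#' @param a,b [persistence_landscape()]s.
#' @param norm `"L1"` or `"sup"`.
#' @param layers optional integer vector restricting the comparison to
#'   specific layers (e.g. `2` for a lambda_2-only distance).
#' @return non-negative number.
#' @export
landscape_distance <- function(a, b, norm = c("L1", "sup"), layers = NULL) {
  norm <- match.arg(norm)
  ks <- layers %||% seq_len(max(length(a$layers), length(b$layers)))
  if (length(ks) == 0L) return(0)
  knots <- landscape_knots(list(a, b), layers = ks)
  if (length(knots) < 2L) return(0)
  total <- 0
  for (k in ks) {
    diffk <- eval_landscape(a, k, knots) - eval_landscape(b, k, knots)
    total <- if (norm == "L1") total + pl_abs_integral(knots, diffk)
             else max(total, max(abs(diffk)))
  }
  total
}

#' Map a landscape peak back to its diagram point
#'
#' Finds the highest strict local maximum `(t*, h)` of layer `k` inside the
#' window and inverts the tent formula: the matching diagram pair is
#' `(t* - h, t* + h)`. Plateau maxima (possible in averages) are located at
#' the plateau midpoint.
#'
#' @param landscape a [persistence_landscape()].
#' @param k layer index.
#' @param t_window length-2 scale interval to search.
#' @return named numeric `(birth, death)`, with attributes `t` and `height`.
#' @export
peak_to_pair <- function(landscape, k, t_window = c(-Inf, Inf)) {
  assert_that(k >= 1L && k <= length(landscape$layers),
              sprintf("layer %d not present", k))
  L <- landscape$layers[[k]]
  t <- L[, 1L]; v <- L[, 2L]
  best <- NULL
  i <- 2L
  n <- length(t)
  while (i <= n - 1L) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L  # plateau [i..j]
    if (v[i] > v[i - 1L] && j < n && v[i] > v[j + 1L]) {
      tstar <- (t[i] + t[j]) / 2
      if (tstar >= t_window[1L] && tstar <= t_window[2L] &&
          (is.null(best) || v[i] > best["height"]))
        best <- c(t = tstar, height = v[i])
    }
    i <- j + 1L
  }
  assert_that(!is.null(best), "no strict local maximum of the layer in the window")
  out <- c(birth = unname(best["t"] - best["height"]),
           death = unname(best["t"] + best["height"]))
  attr(out, "t") <- unname(best["t"])
  attr(out, "height") <- unname(best["height"])
  out
}

#' Write / read a landscape as JSON
#'
#' Layers are lists of `[t, value]` critical points, with `max_layers` and
#' the source id as metadata.
#'
#' @param landscape a [persistence_landscape()].
#' @param path output file.
#' @export
write_landscape_json <- function(landscape, path) {
  obj <- list(source_id = landscape$source_id,
              max_layers = landscape$max_layers,
              layers = lapply(landscape$layers, function(L) unname(as.matrix(L))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landscape_json
#' @export
read_landscape_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- obj$layers
  if (is.matrix(layers)) layers <- list(layers)  # single layer collapse
  persistence_landscape(lapply(layers, function(L) matrix(unlist(L), ncol = 2)),
                        max_layers = obj$max_layers, source_id = obj$source_id)
}
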
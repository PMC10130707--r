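# Degree-1 Vietoris-Rips persistent homology over Z/2.
#
# The filtration is the standard one (vertices at scale 0, an edge at its
# length, a triangle at its longest edge); ties are broken by (diameter,
# dimension, lexicographic vertex tuple), so pairings are deterministic.
# Zero-persistence pairs (birth == death) are discarded. With the default
# threshold -- the enclosing radius -- the Rips complex is a cone, so every
# degree-1 class has a finite death; smaller thresholds yield right-censored
# pairs flagged as such.

#' Enclosing radius of a point cloud
#'
#' `min_p max_q dist(p, q)`. At this scale every point is joined to some
#' point seeing the whole cloud, the Rips complex is a cone, and all degree-1
#' homology is dead — the natural finite-death threshold.
#'
#' @param points a [point_cloud()] or an n x 3 coordinate matrix.
#' @return scale in Angstrom.
#' @export
enclosing_radius <- function(points) {
  P <- if (inherits(points, "point_cloud")) points$points else as.matrix(points)
  assert_that(nrow(P) >= 1L, "empty point cloud")
  if (nrow(P) == 1L) return(0)
  D <- as.matrix(dist(P))
  min(apply(D, 1L, max))
}

#' Construct a persistence diagram object
#'
#' @param birth,death numeric vectors of birth/death scales (Angstrom).
#' @param censored logical vector: `TRUE` for pairs right-censored at
#'   `max_scale`.
#' @param max_scale filtration threshold used.
#' @param degree homology degree (1 throughout this package).
#' @param source_id label of the originating cloud.
#' @return object of class `persistence_diagram`.
#' @export
persistence_diagram <- function(birth, death, censored = NULL, max_scale = Inf,
                                degree = 1L, source_id = "diagram") {
  assert_that(length(birth) == length(death), "birth/death length mismatch")
  if (is.null(censored)) censored <- rep(FALSE, length(birth))
  assert_that(all(birth >= 0) && all(death >= birth),
              "need 0 <= birth <= death for every pair")
  structure(list(pairs = cbind(birth = as.numeric(birth),
                               death = as.numeric(death)),
                 censored = as.logical(censored),
                 max_scale = max_scale, degree = as.integer(degree),
                 source_id = source_id),
            class = "persistence_diagram")
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram %s: degree %d, %d pair(s)%s>\n",
              x$source_id, x$degree, nrow(x$pairs),
              if (any(x$censored)) sprintf(", %d censored", sum(x$censored)) else ""))
  if (nrow(x$pairs) > 0L) {
    show <- head(order(x$pairs[, 2L] - x$pairs[, 1L], decreasing = TRUE), 5L)
    for (i in show)
      cat(sprintf("  (%.3f, %.3f)%s\n", x$pairs[i, 1L], x$pairs[i, 2L],
                  if (x$censored[i]) " [censored]" else ""))
  }
  invisible(x)
}

#' Degree-1 Rips persistence diagram of a point cloud
#'
#' @param points a [point_cloud()] or n x 3 matrix.
#' @param max_scale filtration threshold; default [enclosing_radius()], which
#'   guarantees finite deaths. With a smaller threshold, still-alive classes
#'   are reported with `death = max_scale` and `censored = TRUE`.
#' @return a [persistence_diagram()]. Fewer than 3 points give an empty
#'   diagram. The result also carries the representative cycle of every
#'   finite pair (see [representative_cycle()]).
#' @export
rips_diagram_h1 <- function(points, max_scale = NULL) {
  P <- if (inherits(points, "point_cloud")) points$points else as.matrix(points)
  src <- if (inherits(points, "point_cloud")) points$source_id else "cloud"
  assert_that(all(is.finite(P)), "coordinates must be finite")
  if (is.null(max_scale)) max_scale <- if (nrow(P) > 0L) enclosing_radius(P) else 0
  res <- rips_h1_cpp(P, max_scale)
  d <- persistence_diagram(res$birth, res$death,
                           censored = res$censored == 1L,
                           max_scale = max_scale, source_id = src)
  d$cycles <- res$cycles
  d
}

#' Representative cycle of a diagram pair
#'
#' Returns the mod-2 cycle carried by the reduced boundary column of the
#' death triangle paired with the birth edge: an edge set in which every
#' vertex has even degree, all edge lengths are at most the birth scale, and
#' which becomes a boundary at the death scale. No post-hoc shortening is
#' applied.
#'
#' @param points the [point_cloud()] the diagram came from (or a diagram
#'   produced by [rips_diagram_h1()], which caches its cycles).
#' @param pair numeric `(birth, death)` identifying one diagram point
#'   (matched to 1e-9).
#' @return object of class `cycle_representative`: the pair, an edge matrix
#'   (point indices), and the sorted unique vertex indices.
#' @export
representative_cycle <- function(points, pair) {
  diagram <- if (inherits(points, "persistence_diagram")) points
             else rips_diagram_h1(points)
  hit <- which(abs(diagram$pairs[, 1L] - pair[1L]) < 1e-9 &
                 abs(diagram$pairs[, 2L] - pair[2L]) < 1e-9)
  assert_that(length(hit) > 0L,
              sprintf("pair (%g, %g) not found in diagram", pair[1L], pair[2L]))
  hit <- hit[1L]
  assert_that(!diagram$censored[hit],
              "no representative for censored pairs; recompute with max_scale = enclosing_radius")
  edges <- diagram$cycles[[hit]]
  structure(list(pair = c(birth = diagram$pairs[hit, 1L],
                          death = diagram$pairs[hit, 2L]),
                 edges = edges,
                 vertices = sort(unique(as.vector(edges))),
                 source_id = diagram$source_id),
            class = "cycle_representative")
}

#' @export
print.cycle_representative <- function(x, ...) {
  cat(sprintf("<cycle_representative of (%.3f, %.3f): %d edges, %d vertices>\n",
              x$pair[1L], x$pair[2L], nrow(x$edges), length(x$vertices)))
  invisible(x)
}

#' Write a persistence diagram as CSV
#'
#' Columns `birth`, `death`, `censored`.
#'
#' @param diagram a [persistence_diagram()].
#' @param path output file.
#' @export
write_diagram_csv <- function(diagram, path) {
  df <- data.frame(birth = diagram$pairs[, 1L], death = diagram$pairs[, 2L],
                   censored = diagram$censored)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagram_csv
#' @param source_id label for the diagram read back.
#' @export
read_diagram_csv <- function(path, source_id = NULL) {
  df <- read.csv(path)
  persistence_diagram(df$birth, df$death, censored = df$censored,
                      max_scale = if (nrow(df)) max(df$death) else Inf,
                      source_id = source_id %||% sub("\\.csv$", "", basename(path)))
}
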
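# Two-dimensional Isomap from a precomputed dissimilarity matrix:
# symmetric k-nearest-neighbour graph, geodesics by all-pairs shortest
# paths, classical MDS of the geodesic matrix.

# mutual/union k-NN adjacency with ties broken by id (row) order
knn_adjacency <- function(D, k) {
  n <- nrow(D)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    A[i, nb] <- TRUE
  }
  A | t(A)
}

# the smallest k whose union k-NN graph is connected
smallest_connecting_k <- function(D, start_k = 2L) {
  n <- nrow(D)
  for (k in start_k:(n - 1L)) {
    g <- igraph::graph_from_adjacency_matrix(knn_adjacency(D, k),
                                             mode = "undirected")
    if (igraph::components(g)$no == 1L) return(k)
  }
  n - 1L
}

#' 2-D Isomap embedding of a distance matrix
#'
#' The k-NN graph keeps an edge (i, j) when j is among the k nearest
#' neighbours of i or vice versa (ties broken by id order), weighted by the
#' input dissimilarity. Geodesic distances are shortest paths on this graph;
#' the top two classical-MDS coordinates of the geodesic matrix are
#' returned. Sign ambiguity is canonicalized: the first axis has
#' non-negative skewness, and the first item has a non-negative second
#' coordinate.
#'
#' @param distances a [distance_matrix()] (>= 3 items).
#' @param n_neighbors neighbourhood size k (>= 2, default 5).
#' @return object of class `embedding_2d`: `ids`, an n x 2 `coordinates`
#'   matrix, `n_neighbors` and `residual_variance`
#'   (`1 - cor(geodesic, embedded)^2`).
#' @export
isomap_2d <- function(distances, n_neighbors = 5L) {
  assert_that(inherits(distances, "distance_matrix"),
              "`distances` must be a distance_matrix")
  D <- distances$values
  n <- nrow(D)
  assert_that(n >= 3L, "need at least 3 items")
  assert_that(n_neighbors >= 2L && n_neighbors <= n - 1L,
              "`n_neighbors` must be in [2, n-1]")

  A <- knn_adjacency(D, n_neighbors)
  W <- ifelse(A, D, 0)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    kmin <- smallest_connecting_k(D, n_neighbors)
    stop(sprintf(
      "k-NN graph disconnected at k = %d (%d components: %s); smallest connecting k is %d",
      n_neighbors, comp$no,
      paste(tapply(distances$ids, comp$membership, paste, collapse = "+"),
            collapse = " | "),
      kmin), call. = FALSE)
  }

  G <- igraph::distances(g, algorithm = "dijkstra")
  mds <- cmdscale(G, k = 2L, eig = TRUE)
  Y <- mds$points
  if (ncol(Y) < 2L) Y <- cbind(Y, 0)  # degenerate geometry

  for (ax in 1:2) {
    skew <- sum((Y[, ax] - mean(Y[, ax]))^3)
    if (skew < -1e-12 || (abs(skew) <= 1e-12 && Y[1L, ax] < 0))
      Y[, ax] <- -Y[, ax]
  }

  gvec <- G[lower.tri(G)]
  evec <- as.matrix(dist(Y))[lower.tri(G)]
  rv <- if (sd(gvec) == 0 || sd(evec) == 0) 0
        else 1 - stats::cor(gvec, evec)^2

  structure(list(ids = distances$ids,
                 coordinates = structure(Y, dimnames = list(distances$ids,
                                                            c("x", "y"))),
                 n_neighbors = as.integer(n_neighbors),
                 residual_variance = rv),
            class = "embedding_2d")
}

#' @export
print.embedding_2d <- function(x, ...) {
  cat(sprintf("<embedding_2d: %d items, k = %d, residual variance %.4f>\n",
              length(x$ids), x$n_neighbors, x$residual_variance))
  invisible(x)
}

#' Write an embedding as CSV
#'
#' Columns `id`, `x`, `y`, plus any metadata columns joined by
#' `structure_id`.
#'
#' @param embedding an `embedding_2d`.
#' @param path output file.
#' @param metadata optional data.frame with a `structure_id` column to join.
#' @export
write_embedding_csv <- function(embedding, path, metadata = NULL) {
  df <- data.frame(id = embedding$ids,
                   x = embedding$coordinates[, 1L],
                   y = embedding$coordinates[, 2L])
  if (!is.null(metadata) && "structure_id" %in% names(metadata))
    df <- merge(df, metadata, by.x = "id", by.y = "structure_id",
                all.x = TRUE, sort = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
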
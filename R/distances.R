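# Exact 1-Wasserstein distance between persistence diagrams (L-infinity
# ground metric, diagonal matching allowed) and pairwise distance matrices.

#' W1[L-infinity] Wasserstein distance between two diagrams
#'
#' Minimum over partial matchings of the summed costs, where matching point
#' x to point y costs `max(|b_x - b_y|, |d_x - d_y|)` and matching a point to
#' the diagonal costs half its persistence. Solved exactly as an assignment
#' problem on the (n + m)-augmented square cost matrix.
#'
#' @param d1,d2 [persistence_diagram()]s with finite (uncensored) deaths.
#' @return non-negative number.
#' @export
wasserstein_w1_linf <- function(d1, d2) {
  for (d in list(d1, d2))
    assert_that(!any(d$censored),
                "censored pairs present; recompute the diagram with max_scale = enclosing_radius")
  A <- d1$pairs; B <- d2$pairs
  n <- nrow(A); m <- nrow(B)
  if (n == 0L && m == 0L) return(0)

  diagA <- (A[, 2L] - A[, 1L]) / 2
  diagB <- (B[, 2L] - B[, 1L]) / 2
  N <- n + m
  big <- 2 * (sum(diagA) + sum(diagB) + 1)
  if (n > 0L && m > 0L)
    big <- max(big, 2 * N * max(abs(outer(A[, 1L], B[, 1L], "-")),
                                abs(outer(A[, 2L], B[, 2L], "-"))))

  C <- matrix(0, N, N)
  if (n > 0L && m > 0L)
    C[1:n, 1:m] <- pmax(abs(outer(A[, 1L], B[, 1L], "-")),
                        abs(outer(A[, 2L], B[, 2L], "-")))
  if (n > 0L) {
    C[1:n, (m + 1):N] <- big
    C[cbind(1:n, m + 1:n)] <- diagA
  }
  if (m > 0L) {
    C[(n + 1):N, 1:m] <- big
    C[cbind(n + 1:m, 1:m)] <- diagB
  }
  # bottom-right block (diagonal to diagonal) stays 0
  assignment_cost_cpp(C)
}

#' Construct a distance matrix object
#'
#' @param values symmetric numeric matrix, zero diagonal.
#' @param ids labels for rows/columns.
#' @param metric_name one of `"wasserstein_w1_linf"`, `"landscape_L1"`,
#'   `"landscape_L1_layer2"` (or any descriptive label).
#' @return object of class `distance_matrix`.
#' @export
distance_matrix <- function(values, ids, metric_name) {
  values <- as.matrix(values)
  assert_that(nrow(values) == ncol(values) && nrow(values) == length(ids),
              "`values` must be square with one id per row")
  assert_that(max(abs(values - t(values))) < 1e-9, "matrix must be symmetric")
  assert_that(all(diag(values) == 0), "diagonal must be zero")
  assert_that(all(values >= 0), "distances must be non-negative")
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, metric_name = metric_name),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix: %d items, metric %s>\n",
              length(x$ids), x$metric_name))
  invisible(x)
}

#' Pairwise distance matrix over diagrams or landscapes
#'
#' @param items homogeneous list of [persistence_diagram()]s (for
#'   `wasserstein_w1_linf`) or [persistence_landscape()]s (for the landscape
#'   metrics); names (or source ids) become the matrix labels.
#' @param metric_name `"wasserstein_w1_linf"`, `"landscape_L1"` (all layers)
#'   or `"landscape_L1_layer2"` (lambda_2 only).
#' @return a [distance_matrix()].
#' @export
pairwise_distances <- function(items,
                               metric_name = c("wasserstein_w1_linf",
                                               "landscape_L1",
                                               "landscape_L1_layer2")) {
  metric_name <- match.arg(metric_name)
  assert_that(length(items) >= 2L, "need at least 2 items")
  want <- if (metric_name == "wasserstein_w1_linf") "persistence_diagram"
          else "persistence_landscape"
  ok <- vapply(items, inherits, logical(1L), what = want)
  assert_that(all(ok), sprintf("all items must be of class %s for metric %s",
                               want, metric_name))
  ids <- names(items) %||% vapply(items, `[[`, "", "source_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)

  fun <- switch(metric_name,
                wasserstein_w1_linf = wasserstein_w1_linf,
                landscape_L1 = function(a, b) landscape_distance(a, b, "L1"),
                landscape_L1_layer2 = function(a, b)
                  landscape_distance(a, b, "L1", layers = 2L))
  n <- length(items)
  V <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      V[i, j] <- V[j, i] <- fun(items[[i]], items[[j]])
  distance_matrix(V, ids, metric_name)
}

#' Write / read a distance matrix as CSV (ids in header row and first
#' column), with the metric name in a JSON sidecar.
#'
#' @param dm a [distance_matrix()].
#' @param path output CSV path; the sidecar is `<path>.meta.json`.
#' @export
write_distance_csv <- function(dm, path) {
  df <- data.frame(id = dm$ids, dm$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(metric_name = dm$metric_name, ids = dm$ids),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  metric <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path)$metric_name else "unknown"
  distance_matrix(as.matrix(df[, -1L, drop = FALSE]), df$id, metric)
}
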
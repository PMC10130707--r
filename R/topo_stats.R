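# Label-randomization test comparing the average persistence landscapes of
# two groups of curves.
#
# The test statistic is the landscape distance (L1 by default, optionally
# restricted to chosen layers) between the two group averages. Because every
# landscape involved is piecewise linear with knots inside the union of all
# members' critical abscissae, evaluating all landscapes once on that union
# grid makes each permutation a cheap exact matrix computation: group
# averages are column means and the L1 statistic is a closed-form segment
# integral (split at sign changes).

#' Randomization test on average landscapes
#'
#' Pools the two groups, repeatedly reshuffles the group labels (Monte-Carlo,
#' preserving group sizes), and recomputes the between-average distance. The
#' p-value uses the add-one convention
#' `p = (1 + #\{perm >= observed\}) / (1 + n_permutations)`, so it is bounded
#' below by `1/(n_permutations + 1)` and never zero.
#'
#' @param group_a,group_b non-empty lists of [persistence_landscape()]s.
#' @param n_permutations Monte-Carlo permutations (default 1000, as in a
#'   1000-sample randomization test).
#' @param seed integer seed for the label shuffles.
#' @param norm `"L1"` or `"sup"` distance between the group averages.
#' @param layer_filter optional integer vector of layers entering the
#'   statistic (e.g. `2` to compare lambda_2 alone); default all layers.
#' @return object of class `randomization_result` with fields
#'   `observed_statistic`, `permutation_statistics`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
randomization_test <- function(group_a, group_b, n_permutations = 1000L,
                               seed = 1L, norm = c("L1", "sup"),
                               layer_filter = NULL) {
  norm <- match.arg(norm)
  assert_that(length(group_a) > 0L && length(group_b) > 0L,
              "both groups must be non-empty")
  assert_that(n_permutations >= 1L, "`n_permutations` must be >= 1")
  pool <- c(group_a, group_b)
  na <- length(group_a); n <- length(pool)
  # canonical pool order (by landscape content), so that the Monte-Carlo
  # draws -- and hence the p-value -- are invariant under swapping the two
  # group arguments
  key <- vapply(pool, function(l)
    paste(signif(unlist(l$layers), 12), collapse = ","), "")
  ord <- order(key)
  in_a <- c(rep(TRUE, na), rep(FALSE, n - na))[ord]
  pool <- pool[ord]

  n_layers <- max(vapply(pool, function(l) length(l$layers), 1L))
  ks <- layer_filter %||% seq_len(n_layers)
  ks <- ks[ks <= n_layers]
  knots <- landscape_knots(pool, layers = ks)
  if (length(knots) < 2L) {  # all relevant layers identically zero
    obs <- 0
    perms <- rep(0, n_permutations)
    p <- 1
    return(structure(list(observed_statistic = obs,
                          permutation_statistics = perms, p_value = p,
                          n_permutations = as.integer(n_permutations),
                          seed = as.integer(seed), norm = norm,
                          layer_filter = ks),
                     class = "randomization_result"))
  }

  # n x (|knots| * |ks|) evaluation matrix; exact since all functions are PL
  # with knots inside `knots`
  E <- do.call(cbind, lapply(ks, function(k)
    t(vapply(pool, eval_landscape, numeric(length(knots)), k = k, t = knots))))

  m <- length(knots)
  dt <- diff(knots)
  seg_stat <- function(y) {  # y: matrix, rows = statistics to compute
    total <- numeric(nrow(y))
    for (blk in seq_along(ks)) {
      Y <- y[, (blk - 1L) * m + seq_len(m), drop = FALSE]
      Y1 <- Y[, -m, drop = FALSE]; Y2 <- Y[, -1L, drop = FALSE]
      if (norm == "L1") {
        opp <- Y1 * Y2 < 0
        contrib <- (abs(Y1) + abs(Y2)) / 2
        if (any(opp))
          contrib[opp] <- (Y1[opp]^2 + Y2[opp]^2) /
            (2 * (abs(Y1[opp]) + abs(Y2[opp])))
        total <- total + as.vector(contrib %*% dt)
      } else {
        total <- pmax(total, apply(abs(Y), 1L, max))
      }
    }
    total
  }

  # smaller group size drawn, so draws match under argument swap
  ndraw <- min(na, n - na)
  labels <- with_seed(seed, {
    matrix(vapply(seq_len(n_permutations), function(i) sample.int(n, ndraw),
                  integer(ndraw)),
           nrow = n_permutations, byrow = TRUE)
  })

  stat_for <- function(idx_mat) {  # rows: index sets for one group
    d <- t(apply(idx_mat, 1L, function(ia) {
      colMeans(E[ia, , drop = FALSE]) -
        colMeans(E[-ia, , drop = FALSE])
    }))
    if (nrow(idx_mat) == 1L) d <- matrix(d, nrow = 1L)
    seg_stat(d)
  }

  observed <- stat_for(matrix(which(in_a), nrow = 1L))
  perms <- stat_for(labels)
  p <- (1 + sum(perms >= observed)) / (1 + n_permutations)

  structure(list(observed_statistic = observed,
                 permutation_statistics = perms,
                 p_value = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), norm = norm, layer_filter = ks),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization_test: observed %.4f, p = %.4g (%d permutations)>\n",
              x$observed_statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Write a randomization result as JSON
#'
#' @param result a `randomization_result`.
#' @param path output file.
#' @param group_ids optional labels of the two groups.
#' @export
write_randomization_json <- function(result, path, group_ids = NULL) {
  jsonlite::write_json(
    list(observed_statistic = result$observed_statistic,
         p_value = result$p_value,
         n_permutations = result$n_permutations,
         seed = result$seed, norm = result$norm,
         layer_filter = result$layer_filter,
         group_ids = group_ids),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
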
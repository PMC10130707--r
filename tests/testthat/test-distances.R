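# W1[L-inf] Wasserstein distance and pairwise distance matrices.

dgm <- function(b, d) persistence_diagram(b, d)

test_that("hand-checked Wasserstein values", {
  empty <- dgm(numeric(0), numeric(0))
  expect_equal(wasserstein_w1_linf(dgm(0, 2), empty), 1)  # diagonal cost (2-0)/2
  expect_equal(wasserstein_w1_linf(empty, empty), 0)
  d <- dgm(c(0, 3), c(2, 7))
  expect_equal(wasserstein_w1_linf(d, d), 0)
  # direct match (cost 2) beats both-to-diagonal (1 + 2)
  expect_equal(wasserstein_w1_linf(dgm(0, 2), dgm(0, 4)), 2)
})

test_that("assignment solution equals exhaustive enumeration", {
  for (s in 1:60) {
    set.seed(s)
    A <- random_diagram(sample(0:4, 1), s)
    B <- random_diagram(sample(0:4, 1), s + 1000)
    expect_equal(wasserstein_w1_linf(A, B), oracle_w1_enum(A$pairs, B$pairs),
                 tolerance = 1e-9)
  }
})

test_that("W1 ignores the order of diagram points", {
  set.seed(5)
  A <- random_diagram(6, 5)
  perm <- sample(6)
  Ap <- persistence_diagram(A$pairs[perm, 1L], A$pairs[perm, 2L])
  expect_equal(wasserstein_w1_linf(A, Ap), 0)
})

test_that("censored diagrams are rejected with guidance", {
  circ <- cbind(cos(2 * pi * (0:11) / 12), sin(2 * pi * (0:11) / 12), 0)
  d <- rips_diagram_h1(circ, max_scale = 1)
  expect_error(wasserstein_w1_linf(d, d), "enclosing_radius")
})

test_that("pairwise matrices are metric-consistent and self-consistent", {
  set.seed(9)
  items <- lapply(1:5, function(s) random_diagram(sample(3:8, 1), s + 70))
  names(items) <- sprintf("d%d", 1:5)
  dm <- pairwise_distances(items, "wasserstein_w1_linf")
  expect_s3_class(dm, "distance_matrix")
  expect_equal(dm$ids, names(items))
  expect_equal(diag(dm$values), rep(0, 5), ignore_attr = TRUE)
  expect_equal(dm$values, t(dm$values))
  # element-wise recomputation via the single-pair operation
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(dm$values[i, j],
                 wasserstein_w1_linf(items[[i]], items[[j]]))
  # triangle inequality
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(dm$values[i, k], dm$values[i, j] + dm$values[j, k] + 1e-9)

  # two items: equal off-diagonals
  dm2 <- pairwise_distances(items[1:2], "wasserstein_w1_linf")
  expect_equal(dm2$values[1, 2], dm2$values[2, 1])

  expect_error(pairwise_distances(items[1], "wasserstein_w1_linf"), "at least 2")
  ls <- lapply(items, diagram_to_landscape)
  expect_error(pairwise_distances(c(items[1], ls[2]), "wasserstein_w1_linf"),
               "persistence_diagram")
})

test_that("landscape metrics accept the layer-2 restriction", {
  set.seed(11)
  ls <- lapply(1:4, function(s) diagram_to_landscape(random_diagram(6, s + 40)))
  names(ls) <- sprintf("l%d", 1:4)
  full <- pairwise_distances(ls, "landscape_L1")
  l2 <- pairwise_distances(ls, "landscape_L1_layer2")
  expect_equal(l2$values[1, 2],
               landscape_distance(ls[[1]], ls[[2]], "L1", layers = 2L))
  expect_true(all(l2$values <= full$values + 1e-9))
})

test_that("distance matrices round-trip as CSV with their metric sidecar", {
  set.seed(13)
  items <- lapply(1:3, function(s) random_diagram(4, s))
  names(items) <- c("a", "b", "c")
  dm <- pairwise_distances(items, "wasserstein_w1_linf")
  path <- tempfile(fileext = ".csv")
  write_distance_csv(dm, path)
  back <- read_distance_csv(path)
  expect_equal(back$values, dm$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$metric_name, "wasserstein_w1_linf")
  expect_equal(back$ids, dm$ids)
})
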
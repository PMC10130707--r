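# Persistence landscapes: exact construction, averaging, distances, and the
# peak <-> diagram-point correspondence.

tent_diagram <- function(...) {
  bd <- rbind(...)
  persistence_diagram(bd[, 1L], bd[, 2L])
}

test_that("a single pair gives the tent of height (d - b)/2 on [b, d]", {
  l <- diagram_to_landscape(tent_diagram(c(2, 6)))
  expect_length(l$layers, 1L)
  expect_equal(eval_landscape(l, 1, c(2, 4, 6)), c(0, 2, 0))
  expect_equal(eval_landscape(l, 1, c(1.9, 3, 5, 6.1)), c(0, 1, 1, 0))
  expect_equal(eval_landscape(l, 2, c(3, 4)), c(0, 0))
})

test_that("the empty diagram gives the zero landscape", {
  l <- diagram_to_landscape(persistence_diagram(numeric(0), numeric(0)))
  expect_length(l$layers, 0L)
  expect_equal(eval_landscape(l, 1, 0:10), rep(0, 11))
})

test_that("overlapping tents produce the documented second layer", {
  l <- diagram_to_landscape(tent_diagram(c(0, 6), c(1, 3)))
  expect_equal(eval_landscape(l, 2, 2), 1)
})

test_that("construction agrees with the pointwise k-th-largest oracle", {
  for (s in 1:10) {
    set.seed(s)
    d <- random_diagram(sample(1:30, 1), s)
    l <- diagram_to_landscape(d, max_layers = 10)
    ts <- runif(200, min(d$pairs) - 1, max(d$pairs) + 1)
    for (k in c(1:3, 7)) {
      expect_lt(max(abs(eval_landscape(l, k, ts) -
                          oracle_landscape_eval(d$pairs, k, ts))), 1e-9)
    }
    # slopes of diagram landscapes lie in {-1, 0, 1}
    for (L in l$layers) {
      sl <- diff(L[, 2L]) / diff(L[, 1L])
      expect_true(all(abs(sl) <= 1 + 1e-9))
    }
    # layers are pointwise ordered
    for (k in seq_len(length(l$layers) - 1L))
      expect_true(all(eval_landscape(l, k, ts) >=
                        eval_landscape(l, k + 1L, ts) - 1e-12))
  }
})

test_that("averages are exact pointwise means", {
  set.seed(100)
  ls <- lapply(1:5, function(s) diagram_to_landscape(random_diagram(8, s)))
  avg <- average_landscape(ls)
  ts <- runif(100, 0, 16)
  for (k in 1:3) {
    member <- rowMeans(vapply(ls, eval_landscape, numeric(100), k = k, t = ts))
    expect_lt(max(abs(eval_landscape(avg, k, ts) - member)), 1e-9)
  }
  # averaging k identical copies is the identity
  one <- ls[[1L]]
  same <- average_landscape(list(one, one, one))
  expect_lt(max(abs(eval_landscape(same, 1, ts) - eval_landscape(one, 1, ts))), 1e-12)
  # averaging with the zero landscape halves pointwise
  zero <- diagram_to_landscape(persistence_diagram(numeric(0), numeric(0)))
  half <- average_landscape(list(one, zero))
  expect_lt(max(abs(eval_landscape(half, 2, ts) - eval_landscape(one, 2, ts) / 2)), 1e-12)
  expect_error(average_landscape(list()), "empty")
})

test_that("L1 and sup distances match closed forms on tents", {
  tent <- diagram_to_landscape(tent_diagram(c(0, 2)))
  zero <- diagram_to_landscape(persistence_diagram(numeric(0), numeric(0)))
  expect_equal(landscape_distance(tent, zero, "L1"), 1)    # 1/2 * 2 * 1
  expect_equal(landscape_distance(tent, zero, "sup"), 1)   # peak height
  expect_error(landscape_distance(tent, zero, "L7"), "arg")
})

test_that("L1 distances agree with numerical integration", {
  for (s in 1:6) {
    a <- diagram_to_landscape(random_diagram(6, s))
    b <- diagram_to_landscape(random_diagram(9, s + 50))
    expect_lt(abs(landscape_distance(a, b, "L1") - oracle_landscape_l1(a, b)),
              1e-6)
  }
})

test_that("landscape distances behave like metrics", {
  set.seed(7)
  ls <- lapply(1:6, function(s) diagram_to_landscape(random_diagram(7, s + 20)))
  for (norm in c("L1", "sup")) {
    for (i in 1:3) {
      expect_equal(landscape_distance(ls[[i]], ls[[i]], norm), 0)
      for (j in 4:6)
        expect_equal(landscape_distance(ls[[i]], ls[[j]], norm),
                     landscape_distance(ls[[j]], ls[[i]], norm))
    }
    # triangle inequality on random triples
    for (tri in list(c(1, 2, 3), c(2, 4, 6), c(1, 5, 3))) {
      d12 <- landscape_distance(ls[[tri[1]]], ls[[tri[2]]], norm)
      d23 <- landscape_distance(ls[[tri[2]]], ls[[tri[3]]], norm)
      d13 <- landscape_distance(ls[[tri[1]]], ls[[tri[3]]], norm)
      expect_lte(d13, d12 + d23 + 1e-9)
    }
  }
})

test_that("peaks invert to their diagram pairs", {
  l1 <- diagram_to_landscape(tent_diagram(c(2, 6)))
  expect_equal(as.numeric(peak_to_pair(l1, 1, c(0, 10))), c(2, 6))

  l2 <- diagram_to_landscape(tent_diagram(c(0, 6), c(1, 3)))
  expect_equal(as.numeric(peak_to_pair(l2, 2, c(0, 6))), c(1, 3))

  l3 <- diagram_to_landscape(tent_diagram(c(0, 4), c(6, 10)))
  expect_equal(as.numeric(peak_to_pair(l3, 1, c(5, 12))), c(6, 10))
  expect_equal(as.numeric(peak_to_pair(l3, 1, c(0, 5))), c(0, 4))
  expect_error(peak_to_pair(l3, 1, c(4.5, 5.5)), "no strict local maximum")
  expect_error(peak_to_pair(l3, 9, c(0, 10)), "not present")

  # round trip on a random diagram with distinct tents
  d <- persistence_diagram(c(0, 10, 22), c(6, 18, 31))
  l <- diagram_to_landscape(d)
  for (r in 1:3) {
    bd <- d$pairs[r, ]
    got <- peak_to_pair(l, 1, c(bd[1L] - 0.5, bd[2L] + 0.5))
    expect_equal(as.numeric(got), unname(bd), tolerance = 1e-9)
  }
})

test_that("landscape JSON round-trips", {
  l <- diagram_to_landscape(random_diagram(8, 123))
  path <- tempfile(fileext = ".json")
  write_landscape_json(l, path)
  back <- read_landscape_json(path)
  expect_equal(length(back$layers), length(l$layers))
  ts <- seq(0, 16, length.out = 50)
  for (k in seq_along(l$layers))
    expect_equal(eval_landscape(back, k, ts), eval_landscape(l, k, ts))
})
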
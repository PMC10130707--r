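# Synthetic trefoil generator, unknotted partner, noise model.

test_that("tail-free curves have a full-span core and shallow label", {
  crv <- make_open_trefoil(30, c(0, 0), seed = 1)
  expect_equal(crv$knot_core, c(1L, 30L))
  expect_equal(crv$depth_category, "shallow")
  expect_true(crv$knotted)
})

test_that("spacing statistics and sizes match the request", {
  crv <- make_open_trefoil(100, c(100, 100), spacing = 3.8, seed = 4)
  expect_equal(nrow(crv$points), 300L)
  gaps <- sqrt(rowSums(diff(crv$points)^2))
  expect_lt(abs(mean(gaps) / 3.8 - 1), 0.05)
  expect_true(all(gaps > 0))
  expect_equal(crv$knot_core, c(101L, 200L))
})

test_that("generation is a pure function of parameters and seed", {
  a <- make_open_trefoil(40, c(10, 6), seed = 77)
  b <- make_open_trefoil(40, c(10, 6), seed = 77)
  expect_identical(a$points, b$points)
  c <- make_open_trefoil(40, c(10, 6), seed = 78)
  expect_false(identical(a$points, c$points))
})

test_that("depth label responds to the min-tail fraction as documented", {
  # growing both tails raises min(tail)/total monotonically ...
  fr <- vapply(c(0L, 2L, 6L, 12L, 20L, 30L), function(tl) {
    crv <- make_open_trefoil(40, c(tl, tl), seed = 5)
    min(crv$params$tail_lengths) / nrow(crv$points)
  }, 0)
  expect_true(all(diff(fr) > 0))
  # ... and eventually flips the label shallow -> neither -> deep
  expect_equal(make_open_trefoil(40, c(2, 2), seed = 5)$depth_category, "shallow")
  expect_equal(make_open_trefoil(40, c(12, 12), seed = 5)$depth_category, "neither")
  expect_equal(make_open_trefoil(40, c(20, 20), seed = 5)$depth_category, "deep")
})

test_that("the open arc retains exactly one essential projected crossing", {
  crv <- make_open_trefoil(60, c(0, 0), seed = 1, core_jitter = 0)
  cr <- trefoil_crossings(crv)
  expect_equal(nrow(cr), 1L)
  expect_gt(cr$sep, 0)
  expect_true(cr$window_start >= 1 && cr$window_end <= 60)
  expect_equal(cr$z_over, -cr$z_under, tolerance = 1e-9)  # symmetric strands
})

test_that("the unknotted partner differs only inside the window", {
  crv <- make_open_trefoil(40, c(10, 10), seed = 3)
  cr <- trefoil_crossings(crv)
  best <- which.max(cr$sep)
  window <- c(cr$window_start[best], cr$window_end[best])
  un <- make_unknotted_partner(crv, window)

  moved <- which(rowSums(abs(un$points - crv$points)) > 0)
  expect_true(all(moved >= window[1] & moved <= window[2]))
  outside <- setdiff(seq_len(nrow(crv$points)), window[1]:window[2])
  expect_identical(un$points[outside, ], crv$points[outside, ])

  # displacement bounded by the pass distance (2 x local strand separation)
  disp <- sqrt(rowSums((un$points - crv$points)^2))
  expect_lte(max(disp), 2 * cr$sep[best] + 1e-9)
  expect_false(un$knotted)
  expect_equal(un$knot_core, crv$knot_core)

  expect_error(make_unknotted_partner(crv, c(200, 300)), "inside the curve")
})

test_that("gaussian noise has the advertised moments and determinism", {
  crv <- make_open_trefoil(40, c(5, 5), seed = 9)
  expect_identical(add_noise(crv, 0, seed = 1)$points, crv$points)
  n1 <- add_noise(crv, 0.4, seed = 11)
  n2 <- add_noise(crv, 0.4, seed = 11)
  expect_identical(n1$points, n2$points)
  expect_false(identical(add_noise(crv, 0.4, seed = 12)$points, n1$points))
  expect_error(add_noise(crv, -1), ">= 0")

  big <- point_cloud(matrix(0, 10000, 3), source_id = "big")
  noisy <- add_noise(big, 1, seed = 3)
  sds <- apply(noisy$points, 2, sd)
  expect_true(all(sds >= 0.97 & sds <= 1.03))
  expect_identical(noisy$provenance, big$provenance)
})
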
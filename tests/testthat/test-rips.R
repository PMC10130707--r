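# Degree-1 Rips persistence: enclosing radius, diagrams, representative
# cycles, invariances. Frozen expected values for the square and hexagon
# were computed with the full-reduction oracle in helper-oracles.R.

test_that("enclosing radius follows the min-max definition", {
  expect_equal(enclosing_radius(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(enclosing_radius(rbind(c(0, 0, 0), c(5, 0, 0))), 5)
  expect_equal(enclosing_radius(square_cloud()), sqrt(2))
  expect_error(enclosing_radius(matrix(0, 0, 3)), "empty")
})

test_that("unit square and hexagon diagrams match the reduction oracle", {
  sq <- rips_diagram_h1(square_cloud())
  expect_equal(unname(sq$pairs), matrix(c(1, sqrt(2)), 1), tolerance = 1e-12)
  hx <- rips_diagram_h1(hexagon_cloud())
  expect_equal(unname(hx$pairs), matrix(c(1, sqrt(3)), 1), tolerance = 1e-12)
})

test_that("three points give an empty diagram, as do tiny clouds", {
  P <- rbind(c(0, 0, 0), c(2, 0.3, 0), c(1, 1.7, 0.5))
  expect_equal(nrow(rips_diagram_h1(P)$pairs), 0L)
  expect_equal(nrow(rips_diagram_h1(P[1:2, ])$pairs), 0L)
})

test_that("diagrams equal the naive oracle on random clouds", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(4:25, 1)
    P <- random_cloud(n, s)
    got <- rips_diagram_h1(P)
    exp <- oracle_rips_h1(P)
    expect_equal(unname(sort_pairs(got$pairs[!got$censored, , drop = FALSE])),
                 unname(sort_pairs(exp$pairs)), tolerance = 0)
  }
})

test_that("truncated filtrations flag right-censored classes like the oracle", {
  for (s in c(3, 8, 21)) {
    P <- random_cloud(18, s)
    thr <- enclosing_radius(P) * 0.45
    got <- rips_diagram_h1(P, max_scale = thr)
    exp <- oracle_rips_h1(P, threshold = thr)
    expect_equal(unname(sort_pairs(got$pairs[!got$censored, , drop = FALSE])),
                 unname(sort_pairs(exp$pairs)), tolerance = 0)
    expect_equal(sum(got$censored), nrow(exp$censored))
    if (any(got$censored))
      expect_equal(sort(got$pairs[got$censored, 1L]), sort(exp$censored[, 1L]))
  }
})

test_that("diagrams are invariant under rigid motions", {
  P <- random_cloud(20, 31)
  d0 <- rips_diagram_h1(P)
  for (s in 1:3) {
    d1 <- rips_diagram_h1(rigid_motion(P, s))
    expect_equal(sort_pairs(d1$pairs), sort_pairs(d0$pairs), tolerance = 1e-9)
  }
})

test_that("representative cycles are the expected polygon boundaries", {
  cy <- representative_cycle(square_cloud(), c(1, sqrt(2)))
  sides <- t(apply(cy$edges, 1, sort))
  expect_equal(sides[order(sides[, 1], sides[, 2]), ],
               rbind(c(1, 2), c(1, 4), c(2, 3), c(3, 4)))
  cy6 <- representative_cycle(hexagon_cloud(), c(1, sqrt(3)))
  expect_equal(nrow(cy6$edges), 6L)
  expect_equal(sort(unique(as.vector(cy6$edges))), 1:6)
})

test_that("every cycle is a mod-2 cycle living at its birth scale", {
  crv <- make_open_trefoil(40, c(8, 8), seed = 6)
  dgm <- rips_diagram_h1(crv)
  expect_gt(nrow(dgm$pairs), 0L)
  P <- crv$points
  for (q in seq_len(nrow(dgm$pairs))) {
    cyc <- representative_cycle(dgm, dgm$pairs[q, ])
    deg <- table(as.vector(cyc$edges))
    expect_true(all(deg %% 2 == 0))
    lens <- sqrt(rowSums((P[cyc$edges[, 1L], ] - P[cyc$edges[, 2L], ])^2))
    expect_lte(max(lens), dgm$pairs[q, 1L] + 1e-9)
  }
  expect_error(representative_cycle(dgm, c(0.123, 0.456)), "not found")
})

test_that("censored pairs refuse cycle extraction with guidance", {
  # a 12-gon's loop is born ~0.52 and only dies ~1.93; truncating at 1
  # leaves it right-censored
  circ <- cbind(cos(2 * pi * (0:11) / 12), sin(2 * pi * (0:11) / 12), 0)
  d <- rips_diagram_h1(circ, max_scale = 1)
  expect_equal(sum(d$censored), 1L)
  i <- which(d$censored)
  expect_equal(unname(d$pairs[i, 2L]), 1)
  expect_error(representative_cycle(d, d$pairs[i, ]), "enclosing_radius")
})

test_that("diagram CSV round-trips with the censor flag", {
  d <- rips_diagram_h1(make_open_trefoil(30, c(4, 4), seed = 8))
  path <- tempfile(fileext = ".csv")
  write_diagram_csv(d, path)
  back <- read_diagram_csv(path)
  expect_equal(back$pairs, d$pairs)
  expect_equal(back$censored, d$censored)
})
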
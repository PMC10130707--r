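# Backbone parsing and point-cloud interpolation.

test_that("read_backbone reads C-alpha traces verbatim", {
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  lines <- pdb_from_coords(coords)
  ch <- read_backbone(lines, "A")
  expect_s3_class(ch, "backbone_chain")
  expect_equal(nrow(ch$coords), 3L)
  expect_equal(ch$coords, coords)
  expect_equal(ch$resno, 1:3)
})

test_that("missing chains error and name the available ones", {
  lines <- pdb_from_coords(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  expect_error(read_backbone(lines, "Z"), "available chains: A")
  expect_error(read_backbone("REMARK nothing here", "A"), "no ATOM records")
})

test_that("altloc duplicates resolve to the highest occupancy", {
  lines <- c(
    pdb_ca_line(1, 1, 0, 0, 0, altloc = "A", occ = 0.6),
    pdb_ca_line(2, 1, 9, 9, 9, altloc = "B", occ = 0.4),
    pdb_ca_line(3, 2, 3.8, 0, 0))
  ch <- read_backbone(lines, "A")
  expect_equal(nrow(ch$coords), 2L)
  expect_equal(ch$coords[1L, ], c(0, 0, 0))

  # occupancy tie: altloc letter order wins
  lines2 <- c(
    pdb_ca_line(1, 1, 9, 9, 9, altloc = "B", occ = 0.5),
    pdb_ca_line(2, 1, 0, 0, 0, altloc = "A", occ = 0.5),
    pdb_ca_line(3, 2, 3.8, 0, 0))
  expect_equal(read_backbone(lines2, "A")$coords[1L, ], c(0, 0, 0))
})

test_that("multi-model files honour model_index", {
  l1 <- pdb_from_coords(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  l2 <- pdb_from_coords(rbind(c(1, 0, 0), c(4.8, 0, 0)))
  lines <- c("MODEL        1", l1, "ENDMDL", "MODEL        2", l2, "ENDMDL")
  expect_equal(read_backbone(lines, "A", model_index = 2L)$coords[1L, 1L], 1)
  expect_error(read_backbone(lines, "A", model_index = 3L), "model 3")
})

test_that("interpolation matches the five-equidistant-points convention", {
  ch <- backbone_chain("seg", 1:2, rbind(c(0, 0, 0), c(6, 0, 0)))
  cl <- suppressWarnings(interpolate_cloud(ch, 5L))
  expect_equal(cl$points[, 1L], 0:6)
  expect_equal(cl$points[, 2L], rep(0, 7))

  # n residues, k interior points -> n + k (n - 1) points
  for (n in c(2L, 5L, 10L)) for (k in c(0L, 2L, 5L)) {
    chain <- backbone_chain("x", seq_len(n), cbind(seq_len(n) * 3.8, 0, 0))
    expect_equal(nrow(interpolate_cloud(chain, k)$points), n + k * (n - 1L))
  }
})

test_that("interior points are collinear and equidistant, and the map is deterministic", {
  set.seed(42)
  P <- matrix(rnorm(15, sd = 3), 5, 3)
  ch <- backbone_chain("r", 1:5, P)
  cl <- suppressWarnings(interpolate_cloud(ch, 5L))
  expect_identical(cl$points,
                   suppressWarnings(interpolate_cloud(ch, 5L))$points)
  for (i in 1:4) {
    seg <- which(cl$provenance$segment == i & cl$provenance$fraction > 0 &
                   cl$provenance$fraction < 1)
    pts <- cl$points[seg, ]
    expect_equal(nrow(pts), 5L)
    d <- P[i + 1L, ] - P[i, ]
    for (r in seq_len(5L))
      expect_lt(max(abs(pts[r, ] - (P[i, ] + r / 6 * d))), 1e-9)
  }
  expect_error(interpolate_cloud(ch, -1), "non-negative")
})

test_that("points_per_gap = 0 returns the bare C-alpha cloud", {
  P <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(5, 5, 5))
  ch <- backbone_chain("bare", 1:3, P)
  cl <- suppressWarnings(interpolate_cloud(ch, 0L))
  expect_equal(cl$points, P)
})

test_that("chain breaks interpolate across with a warning", {
  ch <- backbone_chain("gap", c(1L, 2L, 10L),
                       rbind(c(0, 0, 0), c(3.8, 0, 0), c(30, 0, 0)))
  expect_warning(interpolate_cloud(ch, 1L), "4.5")
})

test_that("cloud CSV round-trips", {
  crv <- make_open_trefoil(30, c(3, 3), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_cloud_csv(crv, path)
  back <- read_cloud_csv(path)
  expect_equal(back$points, crv$points)
  expect_equal(back$provenance, crv$provenance)
})

test_that("metadata tables are validated", {
  path <- tempfile(fileext = ".csv")
  md <- data.frame(structure_id = "3KZK", chain = "A",
                   homology_class = "AOTC", depth_category = "deep",
                   knot_core_start = 172, knot_core_end = 251)
  write.csv(md, path, row.names = FALSE)
  expect_equal(read_metadata(path)$homology_class, "AOTC")
  md$depth_category <- "bottomless"
  write.csv(md, path, row.names = FALSE)
  expect_error(read_metadata(path), "depth_category")
  write.csv(md[, -2], path, row.names = FALSE)
  expect_error(read_metadata(path), "missing column")
})
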
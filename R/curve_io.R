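# Backbone extraction and point-cloud interpolation.
#
# A protein structure is modelled as the piecewise-linear curve through its
# C-alpha atoms; the Rips input is that curve resampled with a fixed number
# of equidistant interior points per C-alpha--C-alpha segment.

#' Construct a backbone chain object
#'
#' Low-level constructor used by [read_backbone()] and by the synthetic-curve
#' generator. Coordinates are in Angstrom.
#'
#' @param id structure identifier, e.g. `"3KZK_A"`.
#' @param resno integer vector of residue numbers, strictly increasing.
#' @param coords numeric matrix with one row per residue and columns x, y, z.
#' @param annotations optional list with elements `homology_class`,
#'   `depth_category` (one of `"deep"`, `"shallow"`, `"neither"`) and
#'   `knot_core` (length-2 residue-number interval, inclusive).
#' @return an object of class `backbone_chain`.
#' @export
backbone_chain <- function(id, resno, coords, annotations = list()) {
  coords <- as.matrix(coords)
  assert_that(nrow(coords) >= 2L, "a backbone chain needs at least 2 residues")
  assert_that(nrow(coords) == length(resno),
              "resno and coords must have matching length")
  assert_that(all(is.finite(coords)), "backbone coordinates must be finite")
  assert_that(all(diff(resno) > 0), "residue numbers must be strictly increasing")
  if (!is.null(annotations$depth_category))
    match.arg(annotations$depth_category, c("deep", "shallow", "neither"))
  structure(list(id = id,
                 resno = as.integer(resno),
                 coords = unname(coords[, 1:3, drop = FALSE]),
                 annotations = annotations),
            class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("<backbone_chain %s: %d residues (%d..%d)>\n",
              x$id, nrow(x$coords), x$resno[1L], x$resno[length(x$resno)]))
  invisible(x)
}

#' Read the C-alpha backbone of one chain from a PDB file
#'
#' Parses ATOM records (fixed-column PDB format) and returns the ordered
#' C-alpha trace of the requested chain. Alternate locations are resolved to
#' the highest-occupancy altloc (ties broken by altloc letter); insertion
#' codes keep file order; coordinates are copied verbatim in Angstrom.
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @param chain_id one-letter chain identifier; defaults to the first chain
#'   present.
#' @param model_index 1-based model number for multi-model files (default 1,
#'   also used when the file has no MODEL records).
#' @param id optional label for the result; default `"<basename>_<chain>"`.
#' @return a [backbone_chain()].
#' @examples
#' lines <- c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C")
#' read_backbone(lines, "A")
#' @export
read_backbone <- function(pdb, chain_id = NULL, model_index = 1L, id = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(pdb))
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
    if (is.null(id)) id <- "pdb"
  }

  # model bookkeeping: files without MODEL records are a single model 1
  model_of <- integer(length(lines))
  cur <- 1L; seen_model <- FALSE
  starts <- startsWith(lines, "MODEL")
  ends <- startsWith(lines, "ENDMDL")
  for (k in seq_along(lines)) {
    if (starts[k]) {
      cur <- suppressWarnings(as.integer(substr(lines[k], 11, 14)))
      if (is.na(cur)) cur <- if (seen_model) cur else 1L
      seen_model <- TRUE
    }
    model_of[k] <- cur
    if (ends[k]) cur <- cur + 1L
  }
  n_models <- if (seen_model) max(model_of[startsWith(lines, "ATOM")], 1L) else 1L
  assert_that(model_index >= 1L && model_index <= n_models,
              sprintf("model %d not present (file has %d model(s))",
                      model_index, n_models))

  atom <- startsWith(lines, "ATOM  ") & model_of == model_index
  rec <- lines[atom]
  assert_that(length(rec) > 0L, "no ATOM records in requested model")

  name <- trimws(substr(rec, 13, 16))
  chains <- substr(rec, 22, 22)
  ca <- name == "CA"
  assert_that(any(ca), "no C-alpha atoms in requested model")
  avail <- sort(unique(chains[ca]))
  if (is.null(chain_id)) chain_id <- avail[1L]
  if (!chain_id %in% avail)
    stop(sprintf("chain '%s' not found; available chains: %s",
                 chain_id, paste(avail, collapse = ", ")), call. = FALSE)

  sel <- ca & chains == chain_id
  rec <- rec[sel]
  df <- data.frame(
    altloc = substr(rec, 17, 17),
    resno = as.integer(substr(rec, 23, 26)),
    icode = substr(rec, 27, 27),
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(rec, 55, 60))),
    order = seq_along(rec),
    stringsAsFactors = FALSE)
  df$occ[is.na(df$occ)] <- 1

  # one entry per (resno, icode): highest occupancy, ties by altloc letter
  key <- paste(df$resno, df$icode, sep = "|")
  pick <- unlist(lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                        function(ix) {
                          d <- df[ix, ]
                          ix[order(-d$occ, d$altloc)][1L]
                        }), use.names = FALSE)
  df <- df[sort(pick), ]  # preserve file order

  assert_that(nrow(df) >= 2L, "fewer than 2 C-alpha atoms in chain")
  # strictly-increasing residue numbering is required downstream; duplicated
  # numbers from insertion codes are renumbered in file order
  resno <- df$resno
  if (any(diff(resno) <= 0)) resno <- seq_along(resno) + resno[1L] - 1L
  backbone_chain(id = paste(id, chain_id, sep = "_"),
                 resno = resno,
                 coords = cbind(df$x, df$y, df$z))
}

#' Construct a point cloud object
#'
#' @param points numeric matrix (n x 3), ordered along the curve, Angstrom.
#' @param segment integer vector: index of the backbone segment each point
#'   lies on (segment i joins residues i and i+1; a point sitting exactly on
#'   residue i belongs to segment i with fraction 0, the final residue to
#'   segment n-1 with fraction 1).
#' @param fraction numeric vector in \[0, 1\]: fractional position along the
#'   segment.
#' @param source_id label carried through the pipeline.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, segment = NULL, fraction = NULL,
                        source_id = "cloud") {
  points <- unname(as.matrix(points))
  n <- nrow(points)
  assert_that(n >= 2L, "a point cloud needs at least 2 points")
  assert_that(all(is.finite(points)), "point coordinates must be finite")
  if (is.null(segment)) segment <- pmin(seq_len(n), n - 1L)
  if (is.null(fraction)) fraction <- as.numeric(seq_len(n) == n)
  assert_that(all(fraction >= 0 & fraction <= 1),
              "provenance fractions must lie in [0, 1]")
  structure(list(points = points,
                 provenance = data.frame(segment = as.integer(segment),
                                         fraction = as.numeric(fraction)),
                 source_id = source_id),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud %s: %d points>\n", x$source_id, nrow(x$points)))
  invisible(x)
}

#' Interpolate a backbone chain into a dense point cloud
#'
#' Inserts `points_per_gap` equidistant points strictly between each pair of
#' consecutive C-alpha positions (at fractions k/(points_per_gap+1)), so the
#' cloud has `n + points_per_gap * (n - 1)` points for an n-residue chain.
#' `points_per_gap = 0` returns the bare C-alpha cloud. Consecutive C-alpha
#' distances above 4.5 Angstrom (chain breaks) are interpolated across like
#' any other segment, with a warning.
#'
#' @param chain a [backbone_chain()].
#' @param points_per_gap non-negative integer; default 5.
#' @return a [point_cloud()] whose provenance records, for every point, the
#'   backbone segment index and fractional position it came from.
#' @export
interpolate_cloud <- function(chain, points_per_gap = 5L) {
  assert_that(inherits(chain, "backbone_chain"), "`chain` must be a backbone_chain")
  assert_that(length(points_per_gap) == 1L && points_per_gap >= 0 &&
                points_per_gap == round(points_per_gap),
              "`points_per_gap` must be a non-negative integer")
  k <- as.integer(points_per_gap)
  P <- chain$coords
  n <- nrow(P)

  gaps <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-n, , drop = FALSE])^2))
  if (any(gaps > 4.5))
    warning(sprintf("%s: %d consecutive C-alpha gap(s) exceed 4.5 A; interpolating across",
                    chain$id, sum(gaps > 4.5)))

  fr <- seq_len(k) / (k + 1L)
  pts <- vector("list", 2L * n - 1L)
  seg <- vector("list", 2L * n - 1L)
  fra <- vector("list", 2L * n - 1L)
  for (i in seq_len(n - 1L)) {
    pts[[2L * i - 1L]] <- P[i, , drop = FALSE]
    seg[[2L * i - 1L]] <- i
    fra[[2L * i - 1L]] <- 0
    if (k > 0L) {
      pts[[2L * i]] <- outer(1 - fr, P[i, ]) + outer(fr, P[i + 1L, ])
      seg[[2L * i]] <- rep(i, k)
      fra[[2L * i]] <- fr
    }
  }
  pts[[2L * n - 1L]] <- P[n, , drop = FALSE]
  seg[[2L * n - 1L]] <- n - 1L
  fra[[2L * n - 1L]] <- 1

  point_cloud(do.call(rbind, pts),
              segment = unlist(seg), fraction = unlist(fra),
              source_id = chain$id)
}

#' Map cloud point indices to residue numbers
#'
#' Each point is attributed to the nearest residue along its segment
#' (fraction < 0.5 to the segment start, otherwise the segment end).
#'
#' @param cloud a [point_cloud()].
#' @param resno residue numbers of the source chain (default `1..n`,
#'   appropriate for synthetic curves).
#' @return integer vector, one residue number per cloud point.
#' @export
cloud_point_residues <- function(cloud, resno = NULL) {
  seg <- cloud$provenance$segment
  frac <- cloud$provenance$fraction
  idx <- ifelse(frac < 0.5, seg, seg + 1L)
  if (is.null(resno)) return(as.integer(idx))
  resno[idx]
}

#' Read a per-structure metadata table
#'
#' Expected columns: `structure_id`, `chain`, `homology_class`,
#' `depth_category`, `knot_core_start`, `knot_core_end` (residue numbers,
#' both ends inclusive).
#'
#' @param path CSV file path.
#' @return a data.frame, validated.
#' @export
read_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "chain", "homology_class", "depth_category",
            "knot_core_start", "knot_core_end")
  missing <- setdiff(need, names(md))
  assert_that(length(missing) == 0L,
              paste("metadata CSV missing column(s):", paste(missing, collapse = ", ")))
  bad <- !md$depth_category %in% c("deep", "shallow", "neither")
  assert_that(!any(bad), "depth_category must be deep, shallow or neither")
  md
}

#' Write / read a point cloud as CSV
#'
#' Columns: `index`, `x`, `y`, `z`, `segment_index`, `fraction`.
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @return `path`, invisibly (writer); a [point_cloud()] (reader).
#' @export
write_cloud_csv <- function(cloud, path) {
  df <- data.frame(index = seq_len(nrow(cloud$points)),
                   x = cloud$points[, 1], y = cloud$points[, 2],
                   z = cloud$points[, 3],
                   segment_index = cloud$provenance$segment,
                   fraction = cloud$provenance$fraction)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @param source_id label for the cloud read back.
#' @export
read_cloud_csv <- function(path, source_id = NULL) {
  df <- read.csv(path)
  point_cloud(cbind(df$x, df$y, df$z),
              segment = df$segment_index, fraction = df$fraction,
              source_id = source_id %||% sub("\\.csv$", "", basename(path)))
}
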
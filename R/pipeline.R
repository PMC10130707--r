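# End-to-end orchestration of the three experiments: global clustering of a
# curve set, localization of the discriminating feature between a knotted
# and an unknotted group, and the sparsity/noise robustness sweep.

# ---- input assembly ---------------------------------------------------------

# Build the analysis clouds from a pipeline config. Accepted sources:
#   config$curves + config$labels  : prebuilt point clouds and class labels
#   config$synthetic               : generator spec, a named list of classes,
#       each list(n, tail_lengths, n_core, spacing); seeded from config$seed
#   config$pdb_dir + config$metadata (CSV path or data.frame)
# `points_per_gap` interpolation is applied to backbone-like inputs
# (synthetic curves and PDB chains), not to prebuilt clouds.
assemble_curves <- function(config) {
  ppg <- config$points_per_gap %||% 5L
  seed <- config$seed %||% 1L
  if (!is.null(config$curves)) {
    curves <- config$curves
    labels <- config$labels %||% rep("all", length(curves))
    if (is.null(names(curves)))
      names(curves) <- vapply(curves, `[[`, "", "source_id")
    return(list(curves = curves, labels = labels))
  }
  if (!is.null(config$synthetic)) {
    curves <- list(); labels <- character()
    k <- 0L
    for (cls in names(config$synthetic)) {
      spec <- config$synthetic[[cls]]
      for (i in seq_len(spec$n)) {
        k <- k + 1L
        crv <- make_open_trefoil(
          n_core = spec$n_core %||% 60L,
          tail_lengths = spec$tail_lengths %||% c(0L, 0L),
          spacing = spec$spacing %||% 3.8,
          seed = derive_seed(seed, k),
          id = sprintf("%s_%02d", cls, i))
        curves[[crv$source_id]] <- interpolate_synthetic(crv, ppg)
        labels <- c(labels, cls)
      }
    }
    return(list(curves = curves, labels = labels))
  }
  if (!is.null(config$pdb_dir)) {
    md <- config$metadata
    if (is.character(md)) md <- read_metadata(md)
    assert_that(!is.null(md), "PDB input requires a metadata table")
    curves <- list(); labels <- character()
    for (r in seq_len(nrow(md))) {
      path <- file.path(config$pdb_dir,
                        paste0(md$structure_id[r], ".pdb"))
      chain <- tryCatch(read_backbone(path, md$chain[r]),
                        error = function(e) {
                          warning(sprintf("skipping %s: %s",
                                          md$structure_id[r], conditionMessage(e)))
                          NULL
                        })
      if (is.null(chain)) next
      chain$annotations <- list(
        homology_class = md$homology_class[r],
        depth_category = md$depth_category[r],
        knot_core = c(md$knot_core_start[r], md$knot_core_end[r]))
      cloud <- interpolate_cloud(chain, ppg)
      cloud$knot_core <- chain$annotations$knot_core
      cloud$resno <- chain$resno
      curves[[chain$id]] <- cloud
      labels <- c(labels, md$homology_class[r])
    }
    assert_that(length(curves) >= 2L, "fewer than 2 readable structures")
    return(list(curves = curves, labels = labels))
  }
  stop("config must provide curves, a synthetic spec, or a PDB directory")
}

# re-interpolate a synthetic curve as if its points were C-alpha atoms,
# carrying the annotations across
interpolate_synthetic <- function(curve, points_per_gap) {
  if (points_per_gap == 0L) return(curve)
  chain <- backbone_chain(curve$source_id, seq_len(nrow(curve$points)),
                          curve$points)
  # synthetic shell tails legitimately carry a few slightly stretched steps
  cloud <- suppressWarnings(interpolate_cloud(chain, points_per_gap))
  cloud$knot_core <- curve$knot_core
  cloud$depth_category <- curve$depth_category
  cloud$knotted <- curve$knotted
  class(cloud) <- class(curve)
  cloud
}

# Isomap with k raised to the smallest value that connects the k-NN graph
# (well-separated classes disconnect small neighbourhoods).
auto_isomap <- function(dm, k) {
  n <- length(dm$ids)
  k <- min(k, n - 1L)
  k2 <- smallest_connecting_k(dm$values, k)
  if (k2 > k)
    message(sprintf("k-NN graph disconnected at k = %d; using k = %d", k, k2))
  isomap_2d(dm, n_neighbors = k2)
}

# ---- experiment 1: global analysis ------------------------------------------

#' Global topological analysis of a curve set
#'
#' Computes one degree-1 Rips diagram and landscape per curve, the two
#' pairwise distance matrices (W1\[L-inf\] on diagrams, L1 on landscapes)
#' from that same PH, a 2-D Isomap embedding per matrix, and a
#' label-randomization test for every unordered pair of class labels.
#'
#' @param config list (or path to a key-value config file, see
#'   [read_pipeline_config()]). Recognized fields: input source (`curves` +
#'   `labels`, `synthetic` spec, or `pdb_dir` + `metadata`),
#'   `points_per_gap` (5), `max_layers` (10), `metrics`, `n_neighbors` (5),
#'   `n_permutations` (1000), `seed` (1), `output_dir` (optional: write all
#'   artifacts there as CSV/JSON).
#' @return list with `curves`, `labels`, `diagrams`, `landscapes`,
#'   `dist` (named list of [distance_matrix()]s), `embeddings`,
#'   `rtests` (named by `classA|classB`).
#' @export
run_global_analysis <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  inp <- assemble_curves(config)
  max_layers <- config$max_layers %||% 10L
  metrics <- config$metrics %||% c("wasserstein_w1_linf", "landscape_L1")
  seed <- config$seed %||% 1L

  diagrams <- lapply(inp$curves, rips_diagram_h1)
  landscapes <- lapply(diagrams, diagram_to_landscape, max_layers = max_layers)

  dists <- lapply(metrics, function(mname) {
    items <- if (mname == "wasserstein_w1_linf") diagrams else landscapes
    pairwise_distances(items, mname)
  })
  names(dists) <- metrics

  k <- config$n_neighbors %||% 5L
  embeddings <- lapply(dists, function(dm) auto_isomap(dm, k))

  classes <- sort(unique(inp$labels))
  rtests <- list()
  if (length(classes) < 2L) {
    message("fewer than 2 classes: randomization tests skipped")
  } else {
    combos <- utils::combn(classes, 2L)
    for (j in seq_len(ncol(combos))) {
      a <- combos[1L, j]; b <- combos[2L, j]
      rtests[[paste(a, b, sep = "|")]] <- randomization_test(
        landscapes[inp$labels == a], landscapes[inp$labels == b],
        n_permutations = config$n_permutations %||% 1000L,
        seed = derive_seed(seed, 1000L + j))
    }
  }

  out <- list(curves = inp$curves, labels = inp$labels, diagrams = diagrams,
              landscapes = landscapes, dist = dists, embeddings = embeddings,
              rtests = rtests)
  if (!is.null(config$output_dir)) write_global_artifacts(out, config$output_dir)
  out
}

write_global_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(res$diagrams))
    write_diagram_csv(res$diagrams[[id]], file.path(dir, paste0("diagram_", id, ".csv")))
  for (id in names(res$landscapes))
    write_landscape_json(res$landscapes[[id]], file.path(dir, paste0("landscape_", id, ".json")))
  for (mname in names(res$dist))
    write_distance_csv(res$dist[[mname]], file.path(dir, paste0("dist_", mname, ".csv")))
  md <- data.frame(structure_id = names(res$curves), homology_class = res$labels)
  for (mname in names(res$embeddings))
    write_embedding_csv(res$embeddings[[mname]],
                        file.path(dir, paste0("embedding_", mname, ".csv")), md)
  for (pair in names(res$rtests))
    write_randomization_json(res$rtests[[pair]],
                             file.path(dir, paste0("rtest_", gsub("\\|", "_vs_", pair), ".json")),
                             group_ids = strsplit(pair, "|", fixed = TRUE)[[1L]])
  invisible(dir)
}

# ---- experiment 2: localization ---------------------------------------------

#' Localize the landscape feature discriminating knotted from unknotted
#'
#' Computes both group average landscapes and searches all layers for the
#' most prominent strict local maximum `(t*, h)` of the knotted average
#' whose value in the unknotted average at `t*` falls below
#' `absence_threshold * h`. The peak is then mapped to a diagram pair of a
#' representative knotted curve (the one whose discriminating layer is
#' L1-closest to the knotted average), its representative cycle is
#' extracted, resolved to curve indices/residues, and scored for overlap
#' with the annotated knot core. Identical groups have no absent peak and
#' yield the `found = FALSE` branch, not an error.
#'
#' @param knotted,unknotted non-empty lists of point clouds; the knotted
#'   ones must carry a `knot_core` index interval.
#' @param config optional list: `max_layers` (5), `absence_threshold` (0.2),
#'   `points_per_gap` (inputs are used as-is by default).
#' @return object of class `localization_report`: `found`, `layer`,
#'   `peak` (t, height), `pair` (b, d), `representative_id`,
#'   `cycle_residues`, `residue_ranges`, `overlap_fraction`, and
#'   `lambda2_heatmap` (a [distance_matrix()] of lambda_2-only L1 distances
#'   over both groups, the within/between-class heat-map data).
#' @export
localize_discriminating_feature <- function(knotted, unknotted, config = list()) {
  assert_that(length(knotted) > 0L && length(unknotted) > 0L,
              "both groups must be non-empty")
  max_layers <- config$max_layers %||% 5L
  thr <- config$absence_threshold %||% 0.2

  dg_k <- lapply(knotted, rips_diagram_h1)
  dg_u <- lapply(unknotted, rips_diagram_h1)
  ls_k <- lapply(dg_k, diagram_to_landscape, max_layers = max_layers)
  ls_u <- lapply(dg_u, diagram_to_landscape, max_layers = max_layers)
  avg_k <- average_landscape(ls_k)
  avg_u <- average_landscape(ls_u)

  heat_items <- c(ls_k, ls_u)
  names(heat_items) <- make.unique(vapply(heat_items, `[[`, "", "source_id"))
  heatmap <- pairwise_distances(heat_items, "landscape_L1_layer2")

  # scan every layer of the knotted average for peaks absent in the
  # unknotted average
  best <- NULL
  for (k in seq_along(avg_k$layers)) {
    L <- avg_k$layers[[k]]
    t <- L[, 1L]; v <- L[, 2L]; n <- length(t)
    i <- 2L
    while (i <= n - 1L) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (v[i] > v[i - 1L] && j < n && v[i] > v[j + 1L]) {
        tstar <- (t[i] + t[j]) / 2
        h <- v[i]
        other <- eval_landscape(avg_u, k, tstar)
        if (other < thr * h && (is.null(best) || h > best$height))
          best <- list(layer = k, t = tstar, height = h)
      }
      i <- j + 1L
    }
  }

  report <- structure(list(found = FALSE, lambda2_heatmap = heatmap,
                           n_knotted = length(knotted),
                           n_unknotted = length(unknotted)),
                      class = "localization_report")
  if (is.null(best)) return(report)

  k <- best$layer
  rep_ix <- which.min(vapply(ls_k, landscape_distance, 0, b = avg_k,
                             norm = "L1", layers = k))
  rep_ls <- ls_k[[rep_ix]]
  window <- c(best$t - best$height, best$t + best$height)
  pair <- tryCatch(peak_to_pair(rep_ls, k, window),
                   error = function(e) NULL)
  if (is.null(pair)) return(report)

  # snap to the nearest actual diagram point of the representative
  dgm <- dg_k[[rep_ix]]
  dd <- pmax(abs(dgm$pairs[, 1L] - pair[1L]), abs(dgm$pairs[, 2L] - pair[2L]))
  hit <- which.min(dd)
  cyc <- representative_cycle(dgm, dgm$pairs[hit, ])

  cloud <- knotted[[rep_ix]]
  core <- cloud$knot_core
  assert_that(!is.null(core), "knotted curves must carry a knot_core annotation")
  res_idx <- cloud_point_residues(cloud)[cyc$vertices]
  overlap <- mean(res_idx >= core[1L] & res_idx <= core[2L])

  runs <- split(sort(unique(res_idx)),
                cumsum(c(1L, diff(sort(unique(res_idx))) > 1L)))
  ranges <- t(vapply(runs, range, numeric(2L)))

  report$found <- TRUE
  report$layer <- k
  report$peak <- c(t = best$t, height = best$height)
  report$pair <- c(birth = unname(dgm$pairs[hit, 1L]),
                   death = unname(dgm$pairs[hit, 2L]))
  report$representative_id <- cloud$source_id
  report$cycle <- cyc
  report$cycle_residues <- sort(unique(res_idx))
  report$residue_ranges <- ranges
  report$overlap_fraction <- overlap
  report
}

#' @export
print.localization_report <- function(x, ...) {
  if (!x$found) {
    cat("<localization_report: no discriminating peak found>\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<localization_report: lambda_%d peak at t = %.2f (h = %.2f) -> pair (%.2f, %.2f)\n",
    x$layer, x$peak["t"], x$peak["height"], x$pair["birth"], x$pair["death"]))
  cat(sprintf("  representative %s, knot-core overlap %.2f>\n",
              x$representative_id, x$overlap_fraction))
  invisible(x)
}

#' Write a localization report as JSON
#'
#' @param report a `localization_report`.
#' @param path output file.
#' @export
write_localization_json <- function(report, path) {
  obj <- list(found = report$found)
  if (report$found) {
    obj <- c(obj, list(
      layer = report$layer, peak_t = unname(report$peak["t"]),
      peak_height = unname(report$peak["height"]),
      birth = unname(report$pair["birth"]), death = unname(report$pair["death"]),
      representative_id = report$representative_id,
      cycle_edges = unname(as.matrix(report$cycle$edges)),
      residue_ranges = unname(report$residue_ranges),
      overlap_fraction = report$overlap_fraction))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- experiment 3: robustness sweep -----------------------------------------

# leave-one-out nearest-centroid accuracy in a 2-D embedding
loo_nearest_centroid <- function(coords, labels) {
  n <- nrow(coords)
  correct <- logical(n)
  for (i in seq_len(n)) {
    classes <- unique(labels[-i])
    cent <- t(vapply(classes, function(cl)
      colMeans(coords[-i, , drop = FALSE][labels[-i] == cl, , drop = FALSE]),
      numeric(2L)))
    d2 <- rowSums((cent - matrix(coords[i, ], nrow(cent), 2L, byrow = TRUE))^2)
    correct[i] <- classes[which.min(d2)] == labels[i]
  }
  mean(correct)
}

#' Sparsity and noise robustness sweep
#'
#' For every combination of `points_per_gap` and noise level `sigma`, the
#' global stage is rerun on perturbed inputs and summarized as a
#' class-separation score (leave-one-out nearest-centroid accuracy on the
#' 2-D Isomap of the W1\[L-inf\] matrix) plus the class randomization-test
#' p-value; optionally, the localization stage is rerun on a
#' knotted/unknotted partner set and scored for success.
#'
#' @param config list: `curves` + `labels` (base synthetic curves, treated
#'   as C-alpha traces and re-interpolated per condition) or a `synthetic`
#'   spec; `points_per_gap_grid` (default `c(5, 0)`), `sigma_grid` (default
#'   0 plus 8 log-spaced values up to 2 Angstrom), `seed`, `n_neighbors`,
#'   `n_permutations` (default 199 here), and optionally
#'   `localize = list(knotted =, unknotted =)` curve lists.
#' @return data.frame with one row per condition: `points_per_gap`, `sigma`,
#'   `separation_score`, `rtest_p`, and when localization is enabled
#'   `localization_found` and `overlap_fraction`.
#' @export
noise_sweep <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- config$seed %||% 1L
  ppg_grid <- config$points_per_gap_grid %||% c(5L, 0L)
  sigma_grid <- config$sigma_grid %||%
    c(0, exp(seq(log(0.05), log(2), length.out = 8L)))

  base <- assemble_curves(c(config, list(points_per_gap = 0L)))
  rows <- list()
  cond <- 0L
  for (ppg in ppg_grid) {
    clouds0 <- lapply(base$curves, function(crv)
      if (inherits(crv, "synthetic_curve")) interpolate_synthetic(crv, ppg)
      else crv)
    for (sigma in sigma_grid) {
      cond <- cond + 1L
      clouds <- lapply(seq_along(clouds0), function(i)
        add_noise(clouds0[[i]], sigma, seed = derive_seed(seed, cond * 1000L + i)))
      names(clouds) <- names(clouds0)

      diagrams <- lapply(clouds, rips_diagram_h1)
      dm <- pairwise_distances(diagrams, "wasserstein_w1_linf")
      emb <- auto_isomap(dm, config$n_neighbors %||% 5L)
      score <- loo_nearest_centroid(emb$coordinates, base$labels)

      landscapes <- lapply(diagrams, diagram_to_landscape,
                           max_layers = config$max_layers %||% 5L)
      classes <- unique(base$labels)
      p <- NA_real_
      if (length(classes) == 2L) {
        p <- randomization_test(landscapes[base$labels == classes[1L]],
                                landscapes[base$labels == classes[2L]],
                                n_permutations = config$n_permutations %||% 199L,
                                seed = derive_seed(seed, 500L + cond))$p_value
      }

      row <- data.frame(points_per_gap = ppg, sigma = sigma,
                        separation_score = score, rtest_p = p)
      if (!is.null(config$localize)) {
        kn <- lapply(seq_along(config$localize$knotted), function(i)
          add_noise(interpolate_synthetic(config$localize$knotted[[i]], ppg),
                    sigma, seed = derive_seed(seed, cond * 2000L + i)))
        un <- lapply(seq_along(config$localize$unknotted), function(i)
          add_noise(interpolate_synthetic(config$localize$unknotted[[i]], ppg),
                    sigma, seed = derive_seed(seed, cond * 3000L + i)))
        loc <- localize_discriminating_feature(kn, un, config)
        row$localization_found <- loc$found
        row$overlap_fraction <- if (loc$found) loc$overlap_fraction else NA_real_
      }
      rows[[cond]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- config file ------------------------------------------------------------

#' Read a key-value pipeline config file
#'
#' One `key = value` pair per line; `#` starts a comment. Comma-separated
#' values become vectors; numeric-looking values are converted. Synthetic
#' classes use the compact form
#' `synthetic = deep:20:60:30:30, shallow:20:60:3:3`
#' (class : n : n_core : tail1 : tail2).
#'
#' @param path config file.
#' @return a config list for [run_global_analysis()] / [noise_sweep()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    assert_that(length(kv) >= 2L, sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!anyNA(num)) num else parts
  }
  if (!is.null(cfg$synthetic)) {
    spec <- list()
    for (item in cfg$synthetic) {
      f <- strsplit(item, ":", fixed = TRUE)[[1L]]
      assert_that(length(f) == 5L,
                  "synthetic classes need class:n:n_core:tail1:tail2")
      spec[[f[1L]]] <- list(n = as.integer(f[2L]), n_core = as.integer(f[3L]),
                            tail_lengths = as.integer(f[4:5]))
    }
    cfg$synthetic <- spec
  }
  for (key in c("points_per_gap", "max_layers", "n_neighbors",
                "n_permutations", "seed"))
    if (!is.null(cfg[[key]])) cfg[[key]] <- as.integer(cfg[[key]][1L])
  if (!is.null(cfg$points_per_gap_grid))
    cfg$points_per_gap_grid <- as.integer(cfg$points_per_gap_grid)
  cfg
}
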
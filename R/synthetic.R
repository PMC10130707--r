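# Synthetic open trefoil curves with controllable knot depth, a matched
# unknotted partner obtained by a localized strand passage, and Gaussian
# coordinate noise. Ground-truth annotations (knot core, depth category,
# knottedness) are set by construction, which makes every downstream stage
# testable without downloading structures.

#' Generate an annotated open trefoil curve
#'
#' The knotted core samples the standard open trefoil
#' `(sin t + 2 sin 2t, cos t - 2 cos 2t, -sin 3t)` on `[delta, 2*pi - delta]`,
#' rescaled so the mean consecutive-point spacing equals `spacing` (default
#' 3.8 Angstrom, the C-alpha virtual bond length). The knot-depth label
#' follows min(tail)/total length: `deep` at >= 0.25, `shallow` at <= 0.05,
#' otherwise `neither`.
#'
#' Each tail escapes radially from its chain end and then follows a
#' great-circle arc on a sphere enclosing the core (the two termini arc in
#' opposite senses on slightly offset shells). A curve confined to an
#' enclosing sphere can be pushed radially to infinity without crossing the
#' interior core, so tails are entanglement-free by construction, while
#' their arcs hug the core at a fixed clearance and contribute the
#' large-scale degree-1 features through which tail length — knot depth —
#' becomes visible to the pipeline, emulating termini packed against the
#' protein surface. (Perfectly straight radial tails, by contrast,
#' contribute no degree-1 homology at all and would make depth invisible.)
#' The arc directions are intrinsic to the curve frame; seeds enter only
#' through small Gaussian jitter of the core (`core_jitter`) and of the
#' shell points, emulating within-class structural variability, so curves
#' with equal parameters but different seeds are distinct structures of the
#' same fold.
#'
#' @param n_core number of core points (>= 30).
#' @param tail_lengths integer pair: number of tail points prepended /
#'   appended.
#' @param spacing target mean consecutive spacing, Angstrom.
#' @param seed integer seed; the curve is a pure function of
#'   (parameters, seed).
#' @param delta opening gap of the parametric trefoil, radians (default 0.4).
#' @param core_jitter s.d. (Angstrom) of the seeded Gaussian perturbation of
#'   core points (default 0.25; small against the ~5 A persistence of the
#'   core features, see the stability bound).
#' @param id label for the curve.
#' @return a [point_cloud()] with additional class `synthetic_curve` and
#'   fields `knot_core` (index interval), `depth_category`, `knotted`,
#'   `seed`, `params`.
#' @export
make_open_trefoil <- function(n_core = 40L, tail_lengths = c(0L, 0L),
                              spacing = 3.8, seed = 1L, delta = 0.4,
                              core_jitter = 0.25, id = NULL) {
  assert_that(n_core >= 30L, "`n_core` must be >= 30")
  assert_that(spacing > 0, "`spacing` must be positive")
  assert_that(length(tail_lengths) == 2L && all(tail_lengths >= 0),
              "`tail_lengths` must be two non-negative integers")
  tail_lengths <- as.integer(tail_lengths)

  # sample the parametric curve uniformly in arc length (the raw
  # parametrization has ~2x speed variation, which would give unrealistic
  # consecutive spacings), then rescale to the requested mean spacing
  tt <- seq(delta, 2 * pi - delta, length.out = 50L * n_core)
  fine <- cbind(sin(tt) + 2 * sin(2 * tt),
                cos(tt) - 2 * cos(2 * tt),
                -sin(3 * tt))
  arc <- c(0, cumsum(sqrt(rowSums(diff(fine)^2))))
  s_at <- seq(0, arc[length(arc)], length.out = n_core)
  core <- vapply(1:3, function(j) approx(arc, fine[, j], xout = s_at)$y,
                 numeric(n_core))
  steps <- sqrt(rowSums(diff(core)^2))
  core <- core * (spacing / mean(steps))
  if (core_jitter > 0)
    core <- core + with_seed(derive_seed(seed, 3L),
                             matrix(rnorm(length(core), sd = core_jitter),
                                    n_core, 3L))
  centroid <- colMeans(core)

  # Tail construction: a short radial escape from the chain end, then a
  # seeded wandering walk ON the sphere of radius R_shell enclosing the
  # core. A curve confined to an enclosing sphere can be pushed radially to
  # infinity without crossing the interior core, so shell tails are provably
  # entanglement-free, while their arcs hug the core at a fixed clearance
  # and so contribute degree-1 features whose number grows with tail length
  # -- the mechanism by which knot depth becomes visible to the pipeline,
  # emulating termini packed against the protein surface. Tails also keep a
  # 1.5-spacing clearance from each other (up to 100 seeded retries).
  r_shell <- max(sqrt(rowSums((core - matrix(centroid, n_core, 3L,
                                             byrow = TRUE))^2))) + 2.5 * spacing
  # Directions of the two radial escape rays; each tail's shell arc runs on
  # a latitude circle whose pole is the OTHER tail's ray direction, so it
  # keeps a constant angular clearance from that ray. A slow poleward drift
  # turns multi-wrap arcs into a spiral instead of letting them overlap
  # themselves. All of this geometry is intrinsic to the curve frame; seeds
  # only contribute the small point jitter, as in a real homology class.
  dir_end <- function(endpoint) {
    v <- endpoint - centroid
    v / sqrt(sum(v^2))
  }
  u_start <- dir_end(core[1L, ])
  u_end <- dir_end(core[n_core, ])

  grow_tail <- function(endpoint, len, sub_seed, pole, avoid = NULL,
                        w_sign = 1, shell_extra = 0) {
    if (len == 0L) return(NULL)
    r_sh <- r_shell + shell_extra
    with_seed(sub_seed, {
      for (attempt in 1:100) {
        pts <- matrix(0, len, 3L)
        p <- endpoint
        ok <- TRUE
        k <- 0L
        # phase 1: radial escape, landing exactly on the shell (the last
        # step is shortened so the shell transition stays a bond length)
        while (k < len && sqrt(sum((p - centroid)^2)) < r_sh - 1e-9) {
          r <- sqrt(sum((p - centroid)^2))
          p <- p + min(spacing, r_sh - r) * (p - centroid) / r
          k <- k + 1L
          pts[k, ] <- p
        }
        # phase 2: spiral of latitude circles around `pole`
        if (k < len) {
          u <- (p - centroid) / sqrt(sum((p - centroid)^2))
          theta <- acos(max(-1, min(1, sum(u * pole))))
          a <- u - sum(u * pole) * pole
          if (sum(a^2) < 1e-12) { ok <- FALSE; next }  # ray along the pole
          a <- a / sqrt(sum(a^2))
          b <- c(pole[2L] * a[3L] - pole[3L] * a[2L],
                 pole[3L] * a[1L] - pole[1L] * a[3L],
                 pole[1L] * a[2L] - pole[2L] * a[1L])
          phi <- 0
          while (k < len) {
            phi <- phi + w_sign * spacing / (r_sh * sin(theta))
            # slow monotone drift towards (and past) the equator, floored
            # well above the pole: successive wraps stay ~2-3 bond lengths
            # apart instead of overlapping, and the angular clearance from
            # the other tail's ray never drops below 0.4 rad
            theta <- max(theta - 0.06 * spacing / r_sh, 0.4)
            u <- cos(theta) * pole +
              sin(theta) * (cos(phi) * a + sin(phi) * b)
            p <- centroid + r_sh * u + rnorm(3L, sd = 0.1)
            k <- k + 1L
            pts[k, ] <- p
          }
        }
        # safety net: keep the two tails clear of each other
        if (!is.null(avoid) && nrow(pts) > 0L) {
          dmin <- min(apply(pts, 1L, function(q)
            min(sqrt(rowSums((avoid - matrix(q, nrow(avoid), 3L,
                                             byrow = TRUE))^2)))))
          if (dmin < 1.5 * spacing) ok <- FALSE
        }
        if (ok) return(pts)
      }
      stop("tail collision after 100 retries", call. = FALSE)
    })
  }

  t1 <- grow_tail(core[1L, ], tail_lengths[1L], derive_seed(seed, 1L),
                  pole = u_end)
  # the second tail arcs in the opposite sense on a shell offset by more
  # than the inter-tail clearance
  t2 <- grow_tail(core[n_core, ], tail_lengths[2L], derive_seed(seed, 2L),
                  pole = u_start, avoid = t1, w_sign = -1,
                  shell_extra = 2.2 * spacing)
  pts <- rbind(if (!is.null(t1)) t1[rev(seq_len(nrow(t1))), , drop = FALSE],
               core, t2)

  n_total <- nrow(pts)
  core_span <- c(tail_lengths[1L] + 1L, tail_lengths[1L] + n_core)
  depth_frac <- min(tail_lengths) / n_total
  depth <- if (depth_frac >= 0.25) "deep" else if (depth_frac <= 0.05) "shallow" else "neither"

  out <- point_cloud(pts, source_id = id %||% sprintf("trefoil_s%d", seed))
  out$knot_core <- core_span
  out$depth_category <- depth
  out$knotted <- TRUE
  out$seed <- as.integer(seed)
  out$params <- list(n_core = as.integer(n_core), tail_lengths = tail_lengths,
                     spacing = spacing, delta = delta,
                     core_jitter = core_jitter)
  class(out) <- c("synthetic_curve", class(out))
  out
}

#' @export
print.synthetic_curve <- function(x, ...) {
  cat(sprintf("<synthetic_curve %s: %d points, %s, core %d..%d, %s>\n",
              x$source_id, nrow(x$points),
              if (isTRUE(x$knotted)) "knotted" else "unknotted",
              x$knot_core[1L], x$knot_core[2L], x$depth_category))
  invisible(x)
}

#' Locate the crossings of the open trefoil's standard projection
#'
#' Projects the core polyline onto the xy-plane (the generator applies no
#' rotation, so this is the standard diagram of the parametrization) and
#' intersects all non-adjacent segment pairs. For each crossing the segment
#' with larger z at the intersection is the over-strand; the suggested index
#' window (over-strand midpoint +/- `half_width`) is what
#' [make_unknotted_partner()] expects.
#'
#' The closed parametric trefoil has three diagram crossings, but opening
#' the curve at `delta = 0.4` removes the strands of two of them: the open
#' arc retains exactly one crossing (plus, with core jitter, occasional
#' near-degenerate spurious ones with tiny strand separation, which
#' [make_unknotted_partner()] avoids by preferring the largest separation).
#' Switching that essential crossing turns the closure of the curve into
#' the unknot.
#'
#' @param curve a `synthetic_curve`.
#' @param half_width half-width of the suggested windows, in points.
#' @return data.frame with one row per crossing: over/under segment indices
#'   (into the full curve), intersection z on both strands, local strand
#'   separation `sep`, and `window_start`/`window_end`.
#' @export
trefoil_crossings <- function(curve, half_width = 4L) {
  assert_that(inherits(curve, "synthetic_curve"), "`curve` must be a synthetic_curve")
  ix <- curve$knot_core[1L]:curve$knot_core[2L]
  P <- curve$points[ix, , drop = FALSE]
  ns <- nrow(P) - 1L
  res <- list()
  for (i in seq_len(ns - 2L)) {
    for (j in (i + 2L):ns) {
      p <- P[i, 1:2]; r <- P[i + 1L, 1:2] - p
      q <- P[j, 1:2]; s <- P[j + 1L, 1:2] - q
      den <- r[1L] * s[2L] - r[2L] * s[1L]
      if (abs(den) < 1e-12) next
      w <- q - p
      u <- (w[1L] * s[2L] - w[2L] * s[1L]) / den
      v <- (w[1L] * r[2L] - w[2L] * r[1L]) / den
      if (u <= 0 || u >= 1 || v <= 0 || v >= 1) next
      zi <- P[i, 3L] + u * (P[i + 1L, 3L] - P[i, 3L])
      zj <- P[j, 3L] + v * (P[j + 1L, 3L] - P[j, 3L])
      over <- if (zi > zj) i else j
      res[[length(res) + 1L]] <- data.frame(
        seg_a = i, seg_b = j, over_seg = over,
        z_over = max(zi, zj), z_under = min(zi, zj),
        sep = abs(zi - zj))
    }
  }
  assert_that(length(res) > 0L, "no crossings found in projection")
  out <- do.call(rbind, res)
  mid <- ix[1L] - 1L + out$over_seg  # back to full-curve indices
  out$over_seg <- mid
  out$window_start <- pmax(ix[1L], mid - half_width)
  out$window_end <- pmin(ix[length(ix)], mid + 1L + half_width)
  out
}

#' Make the unknotted partner of a synthetic trefoil
#'
#' Applies a localized strand passage: points inside `window` are displaced
#' along the projection axis (z) so the over-strand of one crossing passes to
#' the other side of the under-strand, with a `sin^2` taper that vanishes at
#' the window boundaries. Any single crossing change turns the trefoil
#' diagram into the unknot. Points outside the window are untouched; the
#' knot-core annotation is retained for overlap scoring.
#'
#' @param curve a knotted `synthetic_curve`.
#' @param window length-2 index interval inside the knot core covering the
#'   over-strand of one crossing (see [trefoil_crossings()]); default: the
#'   window of the crossing with the largest strand separation.
#' @param pass_factor peak displacement as a multiple of the local strand
#'   separation (default 2, enough to clear the under-strand).
#' @return a `synthetic_curve` with `knotted = FALSE`.
#' @export
make_unknotted_partner <- function(curve, window = NULL, pass_factor = 2) {
  assert_that(inherits(curve, "synthetic_curve"), "`curve` must be a synthetic_curve")
  n <- nrow(curve$points)
  cr <- trefoil_crossings(curve)
  if (is.null(window)) {
    best <- which.max(cr$sep)
    window <- c(cr$window_start[best], cr$window_end[best])
  }
  assert_that(length(window) == 2L && window[1L] >= 1L && window[2L] <= n &&
                window[1L] < window[2L],
              "`window` must be an index interval inside the curve")

  hit <- which(cr$over_seg >= window[1L] & cr$over_seg + 1L <= window[2L])
  assert_that(length(hit) > 0L,
              "`window` does not cover the over-strand of any crossing")
  hit <- hit[which.max(cr$sep[hit])]
  pass <- pass_factor * cr$sep[hit]
  direction <- if (cr$z_over[hit] >= cr$z_under[hit]) -1 else 1

  idx <- window[1L]:window[2L]
  u <- (idx - window[1L]) / (window[2L] - window[1L])
  out <- curve
  out$points[idx, 3L] <- out$points[idx, 3L] + direction * pass * sin(pi * u)^2
  out$knotted <- FALSE
  out$source_id <- paste0(curve$source_id, "_unknot")
  out$params$window <- as.integer(window)
  out$params$pass_distance <- pass
  out
}

#' Perturb a point cloud with i.i.d. Gaussian coordinate noise
#'
#' Every coordinate of every point receives an independent draw from
#' `N(0, sigma^2)`; provenance and annotations are preserved.
#'
#' @param cloud a [point_cloud()] (or `synthetic_curve`).
#' @param sigma noise standard deviation, Angstrom (>= 0).
#' @param seed integer seed.
#' @return a cloud of the same class with perturbed coordinates.
#' @export
add_noise <- function(cloud, sigma, seed = 1L) {
  assert_that(inherits(cloud, "point_cloud"), "`cloud` must be a point_cloud")
  assert_that(length(sigma) == 1L && sigma >= 0, "`sigma` must be >= 0")
  if (sigma == 0) return(cloud)
  out <- cloud
  out$points <- cloud$points +
    with_seed(seed, matrix(rnorm(length(cloud$points), sd = sigma),
                           nrow(cloud$points), 3L))
  out
}
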
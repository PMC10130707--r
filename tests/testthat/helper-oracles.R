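# Independent oracles. These deliberately share no code with the package:
# plain-R full boundary-matrix reduction for Rips H1, pointwise k-th-largest
# tent evaluation for landscapes, numerical integration for L1 distances,
# and exhaustive matching enumeration for the Wasserstein distance.

# --- naive full-reduction Rips H1 oracle (all simplices, dims 0-2) ----------
oracle_rips_h1 <- function(P, threshold = NULL) {
  P <- as.matrix(P)
  n <- nrow(P)
  D <- as.matrix(dist(P))
  if (is.null(threshold)) threshold <- min(apply(D, 1, max))

  e2 <- t(utils::combn(n, 2L))
  ekeep <- D[e2] <= threshold
  e2 <- e2[ekeep, , drop = FALSE]
  t3 <- if (n >= 3L) t(utils::combn(n, 3L)) else matrix(0L, 0, 3)
  if (nrow(t3) > 0L) {
    d12 <- D[t3[, 1:2, drop = FALSE]]
    d13 <- D[t3[, c(1, 3), drop = FALSE]]
    d23 <- D[t3[, 2:3, drop = FALSE]]
    tdiam <- pmax(d12, d13, d23)
    tkeep <- tdiam <= threshold
    t3 <- t3[tkeep, , drop = FALSE]
    tdiam <- tdiam[tkeep]
  } else tdiam <- numeric(0)

  vm <- rbind(cbind(seq_len(n), 0L, 0L), cbind(e2, 0L), t3)
  diams <- c(rep(0, n), D[e2], tdiam)
  dims <- c(rep(0L, n), rep(1L, nrow(e2)), rep(2L, nrow(t3)))

  ord <- order(diams, dims, vm[, 1L], vm[, 2L], vm[, 3L])
  vm <- vm[ord, , drop = FALSE]; diams <- diams[ord]; dims <- dims[ord]
  m <- nrow(vm)
  pos <- seq_len(m)
  names(pos) <- paste(dims, vm[, 1L], vm[, 2L], vm[, 3L])

  cols <- vector("list", m)        # stored reduced columns (logical masks)
  low_of <- rep(NA_integer_, m)    # pivot row -> owning column
  zeroed <- rep(FALSE, m)          # column reduced to zero
  pairs <- NULL

  for (s in seq_len(m)) {
    v <- vm[s, ]
    rows <- if (dims[s] == 0L) integer(0)
    else if (dims[s] == 1L)
      unname(pos[c(paste(0L, v[1L], 0L, 0L), paste(0L, v[2L], 0L, 0L))])
    else
      unname(pos[c(paste(1L, v[1L], v[2L], 0L),
                   paste(1L, v[1L], v[3L], 0L),
                   paste(1L, v[2L], v[3L], 0L))])
    col <- rep(FALSE, m)
    col[rows] <- TRUE
    low <- if (length(rows) > 0L) max(rows) else 0L
    while (low > 0L) {
      owner <- low_of[low]
      if (is.na(owner)) break
      col <- xor(col, cols[[owner]])
      w <- which(col)
      low <- if (length(w) > 0L) w[length(w)] else 0L
    }
    if (low == 0L) {
      zeroed[s] <- TRUE
    } else {
      low_of[low] <- s
      cols[[s]] <- col
      if (dims[s] == 2L && diams[s] > diams[low])
        pairs <- rbind(pairs, c(diams[low], diams[s]))
    }
  }

  # creator edges (zeroed dim-1 columns) never killed by a triangle are the
  # right-censored classes at the threshold
  creators <- which(dims == 1L & zeroed)
  unpaired <- creators[is.na(low_of[creators])]
  unpaired <- unpaired[diams[unpaired] < threshold]
  censored <- if (length(unpaired) > 0L) cbind(diams[unpaired], threshold)
              else matrix(0, 0, 2)

  list(pairs = if (is.null(pairs)) matrix(0, 0, 2) else pairs,
       censored = censored)
}

# --- pointwise landscape oracle ---------------------------------------------
oracle_landscape_eval <- function(bd, k, ts) {
  vapply(ts, function(t) {
    v <- pmin(t - bd[, 1L], bd[, 2L] - t)
    v <- v[v > 0]
    if (length(v) >= k) sort(v, decreasing = TRUE)[k] else 0
  }, 0)
}

# --- numerical L1 distance between two landscapes ---------------------------
oracle_landscape_l1 <- function(a, b, n_grid = 200001L) {
  ks <- seq_len(max(length(a$layers), length(b$layers)))
  lo <- min(vapply(c(a$layers, b$layers), function(L) min(L[, 1L]), 0))
  hi <- max(vapply(c(a$layers, b$layers), function(L) max(L[, 1L]), 0))
  ts <- seq(lo, hi, length.out = n_grid)
  h <- ts[2L] - ts[1L]
  total <- 0
  for (k in ks) {
    d <- abs(eval_landscape(a, k, ts) - eval_landscape(b, k, ts))
    total <- total + (sum(d) - (d[1L] + d[n_grid]) / 2) * h
  }
  total
}

# --- exhaustive Wasserstein enumeration (diagrams with few points) ----------
oracle_w1_enum <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A); m <- nrow(B)
  best <- Inf
  persB <- if (m > 0L) (B[, 2L] - B[, 1L]) / 2 else numeric(0)
  rec <- function(i, used, acc) {
    if (acc >= best) return(invisible())
    if (i > n) {
      best <<- min(best, acc + sum(persB[!used]))
      return(invisible())
    }
    rec(i + 1L, used, acc + (A[i, 2L] - A[i, 1L]) / 2)
    for (j in seq_len(m)) {
      if (!used[j]) {
        cost <- max(abs(A[i, 1L] - B[j, 1L]), abs(A[i, 2L] - B[j, 2L]))
        rec(i + 1L, replace(used, j, TRUE), acc + cost)
      }
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# --- small random generators used across test files -------------------------
random_cloud <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * 3, 0, 10), n, 3L)
}

random_diagram <- function(m, seed, scale = 10) {
  set.seed(seed)
  b <- runif(m, 0, scale)
  persistence_diagram(b, b + runif(m, 0.01, scale / 2),
                      source_id = sprintf("rand_%d", seed))
}

sort_pairs <- function(pairs) {
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}
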
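# Internal helpers shared across modules.

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed, staying within 32-bit range
# (arithmetic in doubles: exact below 2^53, reduced mod a prime < 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Exact integral of |f| for a piecewise-linear f given by knots (t, y):
# segments crossing zero are split at the crossing.
pl_abs_integral <- function(t, y) {
  if (length(t) < 2L) return(0)
  dt <- diff(t)
  y1 <- y[-length(y)]
  y2 <- y[-1L]
  opposite <- y1 * y2 < 0
  contrib <- ifelse(opposite,
                    (y1^2 + y2^2) / (2 * (abs(y1) + abs(y2))),
                    (abs(y1) + abs(y2)) / 2)
  sum(contrib * dt)
}

# Drop interior knots of a PL function that are collinear with neighbours.
prune_collinear <- function(t, y, tol = 1e-12) {
  n <- length(t)
  if (n <= 2L) return(cbind(t = t, value = y))
  keep <- rep(TRUE, n)
  s1 <- (y[-1L] - y[-n]) / (t[-1L] - t[-n])  # slope into knot i+1
  interior <- 2:(n - 1L)
  keep[interior] <- abs(s1[interior] - s1[interior - 1L]) > tol
  cbind(t = t[keep], value = y[keep])
}
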
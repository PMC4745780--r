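# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (plain R loops, exhaustive searches).

reflect_i <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n - i + 1
  }
  i
}

# exhaustive per-pixel median with mirror borders
oracle_median <- function(img, window) {
  k <- window %/% 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    vals <- numeric(0)
    for (di in -k:k) for (dj in -k:k)
      vals <- c(vals, img[reflect_i(i + di, nr), reflect_i(j + dj, nc)])
    out[i, j] <- median(vals)
  }
  out
}

# exhaustive per-pixel local entropy (bits) over a disc neighborhood
oracle_entropy <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    vals <- mapply(function(di, dj)
      img[reflect_i(i + di, nr), reflect_i(j + dj, nc)],
      offs$di, offs$dj)
    p <- table(vals) / length(vals)
    out[i, j] <- -sum(p * log2(p))
  }
  out
}

# direct per-pixel evaluation of the adaptive threshold formula:
# foreground iff p(x, y) > (Gaussian-weighted block mean) + kappa
oracle_adaptive_mask <- function(img, k, sigma, kappa) {
  nr <- nrow(img); nc <- ncol(img)
  d <- (-k):k
  w <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  w <- w / sum(w)
  out <- matrix(0L, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    acc <- 0
    for (a in seq_along(d)) for (b in seq_along(d))
      acc <- acc + w[a, b] *
        img[reflect_i(i + d[a], nr), reflect_i(j + d[b], nc)]
    out[i, j] <- as.integer(img[i, j] > acc + kappa)
  }
  out
}

# integer-shift cross-correlation argmax (global translation oracle)
oracle_best_shift <- function(a, b, max_shift = 10) {
  best <- c(0, 0); bestv <- -Inf
  for (dx in -max_shift:max_shift) for (dy in -max_shift:max_shift) {
    v <- sum(a * circshift(b, -dx, -dy))
    if (v > bestv) { bestv <- v; best <- c(dx, dy) }
  }
  best
}

# brute-force connected components (8-connectivity) by repeated flooding
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in 1:nc) for (i in 1:nr) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
            mask[qi, qj] != 0 && lab[qi, qj] == 0) {
          lab[qi, qj] <- cur
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# O(n^3) convex hull check: every hull edge keeps all points on one side
oracle_is_hull <- function(pts, hull_idx) {
  h <- pts[hull_idx, , drop = FALSE]
  m <- nrow(h)
  for (e in 1:m) {
    a <- h[e, ]; b <- h[(e %% m) + 1, ]
    cross <- (pts[, 1] - a[1]) * (b[2] - a[2]) -
      (pts[, 2] - a[2]) * (b[1] - a[1])
    if (any(cross > 1e-9) && any(cross < -1e-9)) return(FALSE)
  }
  TRUE
}

# exhaustive minimum-energy labeling of a tiny MRF model (vectorized over
# all 3^n labelings; independent re-derivation of the energy formula)
oracle_mrf_minimum <- function(model) {
  nr <- model$dims[1]; nc <- model$dims[2]
  n <- nr * nc
  stopifnot(n <= 9)
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  u <- matrix(model$unary, n, 3)
  E <- numeric(nrow(grid))
  for (p in 1:n) E <- E + u[p, ][grid[, p]]
  # pixel p (column-major) at row i, col j: horizontal edge to p + nr,
  # vertical edge to p + 1
  if (nc > 1) {
    wh <- as.vector(model$wh)
    idx <- 0
    for (j in 1:(nc - 1)) for (i in 1:nr) {
      p <- i + (j - 1) * nr; idx <- idx + 1
      E <- E + wh[idx] * (grid[, p] != grid[, p + nr])
    }
  }
  if (nr > 1) {
    wv <- as.vector(model$wv)
    idx <- 0
    for (j in 1:nc) for (i in 1:(nr - 1)) {
      p <- i + (j - 1) * nr; idx <- idx + 1
      E <- E + wv[idx] * (grid[, p] != grid[, p + 1])
    }
  }
  min(E)
}

# exact two-sided Mann-Whitney p-value by enumerating all group
# assignments of the pooled sample
oracle_mw_pvalue <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  U_stat <- function(xi, yi) {
    sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  }
  u_obs <- U_stat(x, y)
  mu <- n * length(y) / 2
  combs <- combn(length(pooled), n)
  us <- apply(combs, 2, function(ix)
    U_stat(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# small deterministic random matrix helper
rmat <- function(nr, nc, seed, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(runif(nr * nc, lo, hi), nr, nc)
}
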
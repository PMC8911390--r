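# Independent brute-force oracles. Each is deliberately naive (loops,
# exhaustive enumeration) and shares no code with the package internals.

# Otsu: exhaustive search over all cut values; returns the largest
# intensity assigned to the background class (ties toward the lower cut).
oracleOtsu <- function(v) {
  vals <- sort(unique(v))
  n <- length(v)
  best <- -Inf
  bestCut <- NA
  for (t in vals[-length(vals)]) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo); w1 <- length(hi)
    bcv <- (w0 / n) * (w1 / n) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) {
      best <- bcv
      bestCut <- t
    }
  }
  bestCut
}

reflectIndex <- function(i, n) {
  # symmetric reflection including the edge: ... 2 1 | 1 2 ... n | n n-1 ...
  if (i < 1) return(1 - i)
  if (i > n) return(2 * n + 1 - i)
  i
}

# Disk-majority filter, per-pixel loop with symmetric reflection.
oracleMajorityDisk <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  off <- subset(expand.grid(dy = -r:r, dx = -r:r), dy^2 + dx^2 <= r^2)
  for (i in 1:H) for (j in 1:W) {
    cnt <- 0L
    for (k in seq_len(nrow(off))) {
      ii <- reflectIndex(i + off$dy[k], H)
      jj <- reflectIndex(j + off$dx[k], W)
      if (m[ii, jj]) cnt <- cnt + 1L
    }
    out[i, j] <- 2L * cnt > nrow(off)
  }
  out
}

# Queue-based flood fill labeling.
oracleFloodLabel <- function(m, connectivity = 8L) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  nbrs <- if (connectivity == 8L)
    expand.grid(dy = -1:1, dx = -1:1)[-5, ]
  else data.frame(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  cur <- 0L
  for (j in 1:W) for (i in 1:H) {
    if (!m[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        ii <- p[1] + nbrs$dy[k]; jj <- p[2] + nbrs$dx[k]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Naive windowed mean with symmetric reflection.
oracleWindowMean <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  h <- (k - 1) %/% 2
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    s <- 0
    for (dy in -h:h) for (dx in -h:h)
      s <- s + m[reflectIndex(i + dy, H), reflectIndex(j + dx, W)]
    out[i, j] <- s / k^2
  }
  out
}

# Box counting at one origin with circular shift, explicit tiling loop.
oracleBoxCount <- function(m, r, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  sh <- matrix(FALSE, H, W)
  for (i in 1:H) for (j in 1:W) {
    if (m[i, j]) {
      ii <- ((i - 1 + dy) %% H) + 1
      jj <- ((j - 1 + dx) %% W) + 1
      sh[ii, jj] <- TRUE
    }
  }
  cnt <- 0L
  for (bi in seq(1, H, by = r)) for (bj in seq(1, W, by = r)) {
    blk <- sh[bi:min(bi + r - 1, H), bj:min(bj + r - 1, W), drop = FALSE]
    if (any(blk)) cnt <- cnt + 1L
  }
  cnt
}

# Gliding-box lacunarity via explicit window enumeration.
oracleGlidingBox <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  masses <- c()
  for (i in 1:(H - r + 1)) for (j in 1:(W - r + 1))
    masses <- c(masses, sum(m[i:(i + r - 1), j:(j + r - 1)]))
  mean(masses^2) / mean(masses)^2
}

# Raw sample with exact moments: mean m, sd s, size n.
exactMomentSample <- function(n, m, s, seed) {
  set.seed(seed)
  z <- stats::rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  m + s * z
}

randomMask <- function(H, W, p) matrix(stats::runif(H * W) < p, H, W)
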
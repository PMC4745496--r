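# Brute-force oracles and tiny fixture builders. Everything here is
# deliberately naive -- explicit loops, exhaustive search -- so the fast
# implementations are checked against an independent route.

reflectIdxR <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i + 0
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# rank-order filter by explicitly sorting every window
oracleRankFilter <- function(x, rank, window = 3L) {
  h <- nrow(x); w <- ncol(x)
  half <- window %/% 2
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      vals <- numeric(0)
      for (di in -half:half) {
        for (dj in -half:half) {
          vals <- c(vals, x[reflectIdxR(i + di, h), reflectIdxR(j + dj, w)])
        }
      }
      out[i, j] <- sort(vals)[rank]
    }
  }
  out
}

# pattern-weighted area by enumerating every padded 2x2 window and
# summing the printed weights
oracleArea <- function(b) {
  b <- (b > 0) * 1L
  h <- nrow(b); w <- ncol(b)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- b
  total <- 0
  for (i in seq_len(h + 1)) {
    for (j in seq_len(w + 1)) {
      win <- p[i:(i + 1), j:(j + 1)]
      n <- sum(win)
      total <- total + if (n == 0) 0 else if (n == 1) 1 / 4 else
        if (n == 3) 7 / 8 else if (n == 4) 1 else
          if ((win[1, 1] && win[2, 2]) || (win[1, 2] && win[2, 1])) 3 / 4
          else 1 / 2
    }
  }
  total
}

# exhaustive Otsu: threshold t (on iff intensity > t) maximising the
# between-class variance over all 256 candidate levels
oracleOtsu <- function(gray) {
  best <- -Inf; bestT <- 0
  for (t in 0:254) {
    g1 <- gray[gray <= t]; g2 <- gray[gray > t]
    if (!length(g1) || !length(g2)) next
    w1 <- length(g1) / length(gray); w2 <- 1 - w1
    v <- w1 * w2 * (mean(g1) - mean(g2))^2
    if (v > best) { best <- v; bestT <- t }
  }
  bestT
}

# 8-connected components by breadth-first search
oracleComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextLab <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pi <- (p - 1L) %% h + 1L; pj <- (p - 1L) %/% h + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- pi + di; jj <- pj + dj
        if (ii < 1 || ii > h || jj < 1 || jj > w) next
        q <- (jj - 1L) * h + ii
        if (mask[q] && lab[q] == 0L) { lab[q] <- nextLab; queue <- c(queue, q) }
      }
    }
  }
  lab
}

randomRgb <- function(h, w, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

randomGray <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# SegmentedSample with full control over pixels and mask
segmentedFixture <- function(rgb, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, dim(rgb)[1], dim(rgb)[2])
  tomatovision:::maskedSample(rgb, mask)
}

# flat-colour RGB raster
flatRgb <- function(h, w, color) {
  array(rep(color, each = h * w), dim = c(h, w, 3))
}

# a small rendered dataset shared by pipeline-level tests (cached per
# session); canvas scaled down so the suite stays fast
smallDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateDataset(9, 10, seed = 4, canvas = c(96L, 128L),
                                fruitAxes = c(28, 34))
    cache
  }
})

smallSpec <- function(...) {
  sampleSpec(..., canvas = c(96L, 128L), fruitAxes = c(28, 34))
}
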
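# Independent brute-force oracles used across test files. These stay
# deliberately naive (double loops, dense enumeration) so they share no
# code path with the implementation they check.

# grey-scale dilation: max over a disk of the given radius (loop oracle)
oracleDilate <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di * di + dj * dj > radius * radius) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- max(vals)
  }
  out
}

# local arithmetic mean over a block x block window, truncated at borders
oracleLocalMean <- function(m, block) {
  h <- (block - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - h):min(nr, i + h)
    cj <- max(1, j - h):min(nc, j + h)
    out[i, j] <- mean(m[ri, cj])
  }
  out
}

# 8-connected component count of a logical mask (flood fill oracle)
oracleComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  ncomp <- 0
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    ncomp <- ncomp + 1
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  ncomp
}

# direct 2D Gaussian convolution with replicated borders (loop oracle)
oracleGaussBlur <- function(m, sigma) {
  r <- ceiling(4 * sigma)
  k <- outer(-r:r, -r:r, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), nr); jj <- min(max(j + dj, 1), nc)
      acc <- acc + m[ii, jj] * k[di + r + 1, dj + r + 1]
    }
    out[i, j] <- acc
  }
  out
}

# grid-search nonnegative least squares for one spectrum against a
# two-peak basis with free baseline; returns the best residual sum of
# squares found on the grid
oracleNnlsGrid <- function(y, g1, g2, amax, step) {
  best <- Inf
  for (a1 in seq(0, amax, by = step)) for (a2 in seq(0, amax, by = step)) {
    r0 <- y - a1 * g1 - a2 * g2
    b <- mean(r0)
    rss <- sum((r0 - b)^2)
    if (rss < best) best <- rss
  }
  best
}

# a small smooth sieve image fixture used by several files
makeCleanSieve <- function(diameters, seed = 7, shape = c(192, 192),
                           noise = "none", bias = 0) {
  tr <- sievePlateTruth(diameters, imageShape = shape,
                        biasFieldAmplitude = bias, noiseModel = noise,
                        seed = seed)
  c(simulateSieveImage(tr), list(truthRec = tr))
}
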
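## Per-pixel two-peak spectral unmixing of hyperspectral SRS cubes,
## single-frequency CARS threshold splitting, and motorized-stage tile
## stitching.

#' Build the spectral design matrix of the peak basis
#'
#' Columns are unit-peak Gaussians G(v; center, fwhm) evaluated on the
#' wavenumber axis, one per peak, plus an optional constant baseline
#' column. With the default axis (16 samples) and default basis (2845 and
#' 2920 cm^-1 peaks plus baseline) the matrix is 16 x 3.
#'
#' @param axis a \linkS4class{SpectralAxis}.
#' @param basis a \linkS4class{PeakBasis}; all centers must lie within
#'   the axis range.
#' @return K x m numeric matrix with named columns.
#' @export
buildBasis <- function(axis = SpectralAxis(), basis = PeakBasis()) {
  stopifnot(is(axis, "SpectralAxis"), is(basis, "PeakBasis"))
  w <- axis@wavenumbersCm1
  if (any(basis@centersCm1 < w[1] | basis@centersCm1 > w[length(w)]))
    stop("peak center outside the axis range")
  cols <- vapply(basis@centersCm1, function(cc)
    exp(-4 * log(2) * (w - cc)^2 / basis@fwhmCm1^2), numeric(length(w)))
  colnames(cols) <- paste0("A", basis@centersCm1)
  if (basis@includeBaseline) {
    cols <- cbind(cols, baseline = 1)
  }
  cols
}

#' Fit the peak basis to every pixel of a hyperspectral cube
#'
#' Solves, per pixel, least squares with nonnegativity constraints on the
#' peak amplitudes and an unconstrained constant baseline. The solution
#' is exact: all active sets of the (few) constrained coefficients are
#' enumerated, each reduced problem solved in closed form, and the
#' feasible candidate with the smallest residual selected — for a strictly
#' convex problem this recovers the global NNLS optimum. Fully
#' deterministic and vectorized over pixels.
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param basis a \linkS4class{PeakBasis}.
#' @return an \linkS4class{AmplitudeMaps}.
#' @examples
#' truth <- randomHsiTruth(16, 16, seed = 5)
#' cube <- simulateHsiCube(truth)$cube
#' maps <- fitCube(cube)
#' max(abs(amplitudeMap(maps, 2845) - truth@amp2845))
#' @export
fitCube <- function(cube, basis = PeakBasis()) {
  stopifnot(is(cube, "SpectralCube"), is(basis, "PeakBasis"))
  X <- buildBasis(cube@axis, basis)
  K <- nrow(X); m <- ncol(X)
  if (qr(X)$rank < m)
    stop("rank-deficient design matrix: peaks too close for this axis/fwhm")
  d <- dim(cube@values)
  N <- d[1] * d[2]
  Y <- t(matrix(cube@values, N, K))          # K x N
  p <- length(basis@centersCm1)
  nb <- if (basis@includeBaseline) 1L else 0L
  bestRes <- rep(Inf, N)
  bestBeta <- matrix(0, m, N)
  yss <- colSums(Y^2)
  for (s in 0:(2^p - 1L)) {
    free <- which(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) > 0L)
    colsel <- c(free, if (nb) m else integer(0))
    if (length(colsel)) {
      Xs <- X[, colsel, drop = FALSE]
      beta <- solve(crossprod(Xs), crossprod(Xs, Y))   # ms x N
      fit <- Xs %*% beta
      res <- colSums((Y - fit)^2)
      feas <- if (length(free))
        colSums(beta[seq_along(free), , drop = FALSE] < -1e-10) == 0L
      else rep(TRUE, N)
    } else {
      beta <- NULL; res <- yss; feas <- rep(TRUE, N)
    }
    upd <- feas & res < bestRes
    if (any(upd)) {
      bestRes[upd] <- res[upd]
      bestBeta[, upd] <- 0
      if (length(colsel)) bestBeta[colsel, upd] <- beta[, upd, drop = FALSE]
    }
  }
  amp <- array(0, c(d[1], d[2], p))
  for (i in seq_len(p))
    amp[, , i] <- matrix(pmax(bestBeta[i, ], 0), d[1], d[2])
  baselineM <- if (nb) matrix(bestBeta[m, ], d[1], d[2]) else
    matrix(0, d[1], d[2])
  rms <- matrix(sqrt(pmax(bestRes, 0) / K), d[1], d[2])
  new("AmplitudeMaps", amplitudes = amp, centersCm1 = basis@centersCm1,
      baseline = baselineM, residualRms = rms)
}

#' Split a single-frequency CARS image at an intensity threshold
#'
#' Partitions the image into the pixels at or below the threshold
#' (non-resonant background, membranes, nuclei) and those strictly above
#' it (lipid droplets): every pixel lands in exactly one mask.
#'
#' @param img a \linkS4class{PixelGrid2D}.
#' @param threshold finite intensity threshold.
#' @return list with logical matrices \code{below} (value <= threshold)
#'   and \code{above} (value > threshold).
#' @export
thresholdSplit <- function(img, threshold) {
  stopifnot(is(img, "PixelGrid2D"), is.finite(threshold))
  below <- img@values <= threshold
  list(below = below, above = !below)
}

#' Integer-pixel phase correlation between two equally sized images
#'
#' Returns the integer shift (dy, dx) maximizing the phase-correlation
#' surface, restricted to |shift| <= \code{maxShift} per axis; applying
#' the shift to \code{moving} aligns it to \code{reference}.
#'
#' @param reference,moving numeric matrices of identical shape.
#' @param maxShift search radius in pixels (default 10).
#' @return integer vector c(dy, dx).
#' @export
phaseCorrelate <- function(reference, moving, maxShift = 10L) {
  stopifnot(identical(dim(reference), dim(moving)))
  Fa <- stats::fft(reference)
  Fb <- stats::fft(moving)
  R <- Fa * Conj(Fb)
  mag <- Mod(R)
  ## regularized whitening: keeps low-power frequencies (smooth images)
  ## from injecting numerical noise into the correlation surface
  R <- R / (mag + 0.01 * max(mag, 1e-300))
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  nr <- nrow(r); nc <- ncol(r)
  wrap <- function(i, n) ifelse(i - 1L > n %/% 2L, i - 1L - n, i - 1L)
  dy <- wrap(seq_len(nr), nr); dx <- wrap(seq_len(nc), nc)
  allow <- outer(abs(dy) <= maxShift, abs(dx) <= maxShift)
  r[!allow] <- -Inf
  k <- which.max(r)
  i <- (k - 1L) %% nr + 1L; j <- (k - 1L) %/% nr + 1L
  c(dy = dy[i], dx = dx[j])
}

#' Stitch a grid of tiles into one mosaic
#'
#' Places equally sized tiles (row-major list order) on a regular grid
#' with the given nominal overlap, optionally refines each tile's
#' position against its left (or top) neighbor by integer-pixel phase
#' correlation on the overlap strips, and linearly blends overlapping
#' regions (ramp weights toward tile edges). Identical overlap content
#' stitches seamlessly.
#'
#' @param tiles list of \linkS4class{PixelGrid2D} (or numeric matrices)
#'   sharing one shape, in row-major grid order.
#' @param gridRows,gridCols grid layout; gridRows * gridCols must equal
#'   the number of tiles.
#' @param overlapPx nominal overlap between adjacent tiles in pixels
#'   (>= 0).
#' @param refine refine placements by phase correlation (default FALSE).
#' @param maxShiftPx refinement search radius in pixels (default 5).
#' @return a \linkS4class{PixelGrid2D} mosaic (pixel size taken from the
#'   first tile; 1 nm when plain matrices are given).
#' @export
stitchTiles <- function(tiles, gridRows, gridCols, overlapPx = 0L,
                        refine = FALSE, maxShiftPx = 5L) {
  if (length(tiles) != gridRows * gridCols)
    stop("gridRows * gridCols must equal the number of tiles")
  px <- if (is(tiles[[1]], "PixelGrid2D")) tiles[[1]]@pixelSizeNm else 1
  mats <- lapply(tiles, function(t)
    if (is(t, "PixelGrid2D")) t@values else as.matrix(t))
  d0 <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d0), logical(1))))
    stop("all tiles must share one shape")
  h <- d0[1]; w <- d0[2]; v <- as.integer(overlapPx)
  if (v < 0 || v >= min(h, w)) stop("overlapPx must be in [0, tile size)")
  ## 0-based placement offsets (row, col) per tile
  offs <- matrix(0L, length(mats), 2L)
  tileAt <- function(r, c) (r - 1L) * gridCols + c
  for (r in seq_len(gridRows)) for (c in seq_len(gridCols)) {
    k <- tileAt(r, c)
    if (r == 1L && c == 1L) next
    if (c > 1L) {                       # align to left neighbor
      nb <- tileAt(r, c - 1L)
      nominal <- offs[nb, ] + c(0L, w - v)
    } else {                            # align to top neighbor
      nb <- tileAt(r - 1L, c)
      nominal <- offs[nb, ] + c(h - v, 0L)
    }
    if (refine && v > 0L) {
      if (c > 1L) {
        refStrip <- mats[[nb]][, (w - v + 1L):w, drop = FALSE]
        movStrip <- mats[[k]][, 1:v, drop = FALSE]
      } else {
        refStrip <- mats[[nb]][(h - v + 1L):h, , drop = FALSE]
        movStrip <- mats[[k]][1:v, , drop = FALSE]
      }
      sh <- phaseCorrelate(refStrip, movStrip, maxShift = maxShiftPx)
      nominal <- nominal + as.integer(sh)
    }
    offs[k, ] <- nominal
  }
  offs[, 1] <- offs[, 1] - min(offs[, 1])
  offs[, 2] <- offs[, 2] - min(offs[, 2])
  outR <- max(offs[, 1]) + h; outC <- max(offs[, 2]) + w
  num <- matrix(0, outR, outC); den <- matrix(0, outR, outC)
  cap <- max(v, 1L)
  wr <- pmin(pmin(seq_len(h), h + 1L - seq_len(h)), cap)
  wc <- pmin(pmin(seq_len(w), w + 1L - seq_len(w)), cap)
  wt <- outer(wr, wc)
  for (k in seq_along(mats)) {
    ri <- offs[k, 1] + seq_len(h); ci <- offs[k, 2] + seq_len(w)
    num[ri, ci] <- num[ri, ci] + mats[[k]] * wt
    den[ri, ci] <- den[ri, ci] + wt
  }
  out <- num / pmax(den, .Machine$double.eps)
  out[den == 0] <- 0
  PixelGrid2D(out, px)
}

#' Compose fitted amplitude maps into an RGB display image
#'
#' Maps the lipid peak (2845 cm^-1) to yellow, the protein peak
#' (2920 cm^-1) to magenta, and an optional SHG channel to green, each
#' normalized to its own maximum, following the usual CRS display
#' convention.
#'
#' @param maps an \linkS4class{AmplitudeMaps} fitted with peaks at 2845
#'   and 2920 cm^-1.
#' @param shg optional numeric matrix (same shape) of SHG intensities.
#' @return rows x cols x 3 array with values in [0, 1].
#' @export
composeRgb <- function(maps, shg = NULL) {
  stopifnot(is(maps, "AmplitudeMaps"))
  nrm <- function(m) { mx <- max(m); if (mx > 0) m / mx else m }
  lip <- nrm(amplitudeMap(maps, 2845))
  pro <- nrm(amplitudeMap(maps, 2920))
  g <- if (is.null(shg)) matrix(0, nrow(lip), ncol(lip)) else nrm(shg)
  rgb <- array(0, c(nrow(lip), ncol(lip), 3L))
  rgb[, , 1] <- pmin(1, lip + pro)        # yellow + magenta share red
  rgb[, , 2] <- pmin(1, lip + g)
  rgb[, , 3] <- pmin(1, pro)
  rgb
}
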
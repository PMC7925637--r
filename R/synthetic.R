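## Seeded generators for all three analysis stages. Every generator is a
## pure function of its arguments: the RNG is scoped with withr::with_seed
## so global RNG state is never consulted or disturbed.

#' Draw fenestra diameters from a named size distribution
#'
#' Generates true pore diameters for sieve-plate simulation. The
#' shifted-exponential option emulates the exponentially decaying diameter
#' distribution observed in human LSECs over the 90-320 nm range: density
#' proportional to exp(-(d - offset)/scale) for d >= offset.
#'
#' @param n number of diameters to draw (>= 0).
#' @param kind one of "uniform" (params \code{min}, \code{max}),
#'   "lognormal" (params \code{meanlog}, \code{sdlog}, nm scale) or
#'   "shifted-exponential" (params \code{offset}, \code{scale}, nm).
#' @param params named list of distribution parameters (see \code{kind}).
#' @param seed integer seed; identical (n, kind, params, seed) give
#'   identical output.
#' @return numeric vector of n positive diameters in nm.
#' @examples
#' d <- sampleDiameters(5, "shifted-exponential",
#'                      list(offset = 90, scale = 40), seed = 1)
#' all(d >= 90)
#' @export
sampleDiameters <- function(n, kind = c("uniform", "lognormal",
                                        "shifted-exponential"),
                            params = list(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("n must be a nonnegative integer")
  kind <- match.arg(kind)
  p <- params
  chk <- function(nm) {
    if (is.null(p[[nm]]) || !is.finite(p[[nm]]))
      stop("missing or invalid parameter '", nm, "' for kind '", kind, "'")
    p[[nm]]
  }
  d <- switch(kind,
    "uniform" = {
      lo <- chk("min"); hi <- chk("max")
      if (lo <= 0 || hi <= lo) stop("uniform needs 0 < min < max")
      if (n == 0) numeric(0) else
        withr::with_seed(seed, stats::runif(n, lo, hi))
    },
    "lognormal" = {
      ml <- chk("meanlog"); sl <- chk("sdlog")
      if (sl <= 0) stop("lognormal needs sdlog > 0")
      if (n == 0) numeric(0) else
        withr::with_seed(seed, stats::rlnorm(n, ml, sl))
    },
    "shifted-exponential" = {
      off <- chk("offset"); sc <- chk("scale")
      if (sc <= 0) stop("shifted-exponential needs scale > 0")
      if (off < 0) stop("shifted-exponential needs offset >= 0")
      if (n == 0) numeric(0) else
        withr::with_seed(seed, off + stats::rexp(n, rate = 1 / sc))
    })
  d
}

#' Build a sieve-plate ground-truth record with randomly placed pores
#'
#' Places pores of the given diameters uniformly at random inside the
#' image, rejecting placements closer than \code{minSeparationFactor}
#' times the larger of the two pore diameters, and keeping every pore
#' (plus a PSF-sized guard band) away from the border. Defaults emulate
#' SR-SIM imaging of CellMask-stained LSEC membranes: 40 nm reconstructed
#' pixels, ~100 nm lateral PSF FWHM, uneven staining brightness, and
#' Poisson photon noise with gaussian read noise.
#'
#' @param diametersNm true pore diameters in nm.
#' @param imageShape integer (rows, cols), default c(256, 256).
#' @param pixelSizeNm pixel pitch in nm (default 40).
#' @param psfFwhmNm lateral PSF FWHM in nm (default 100).
#' @param membraneLevel expected membrane photon count (default 200,
#'   i.e. shot-noise SNR ~ 14).
#' @param backgroundLevel expected photon count inside a pore (default 0).
#' @param biasFieldAmplitude relative staining-unevenness amplitude in
#'   [0, 1) (default 0.2).
#' @param noiseModel "none", "poisson", "gaussian" or "poisson+gaussian".
#' @param readNoiseSd gaussian read-noise SD in counts (default 3).
#' @param minSeparationFactor centers of pores i, j must be at least this
#'   factor times max(d_i, d_j) apart (default 1.5).
#' @param centersNm optional n x 2 matrix of (x, y) centers in nm; when
#'   given, placement sampling is skipped.
#' @param seed integer seed controlling placement, bias field and noise.
#' @return a \linkS4class{SievePlateTruth}.
#' @export
sievePlateTruth <- function(diametersNm, imageShape = c(256L, 256L),
                            pixelSizeNm = 40, psfFwhmNm = 100,
                            membraneLevel = 200, backgroundLevel = 0,
                            biasFieldAmplitude = 0.2,
                            noiseModel = "poisson+gaussian",
                            readNoiseSd = 3, minSeparationFactor = 1.5,
                            centersNm = NULL, seed = 1L) {
  imageShape <- as.integer(imageShape)
  n <- length(diametersNm)
  if (is.null(centersNm)) {
    centersNm <- .placePores(diametersNm, imageShape, pixelSizeNm,
                             psfFwhmNm, minSeparationFactor, seed)
  } else {
    centersNm <- matrix(as.numeric(centersNm), ncol = 2L)
    if (nrow(centersNm) != n) stop("one center per diameter required")
  }
  new("SievePlateTruth", centersNm = centersNm,
      diametersNm = as.numeric(diametersNm), pixelSizeNm = as.numeric(pixelSizeNm),
      imageShape = imageShape, psfFwhmNm = as.numeric(psfFwhmNm),
      membraneLevel = as.numeric(membraneLevel),
      backgroundLevel = as.numeric(backgroundLevel),
      biasFieldAmplitude = as.numeric(biasFieldAmplitude),
      noiseModel = noiseModel, readNoiseSd = as.numeric(readNoiseSd),
      seed = as.integer(seed))
}

## Rejection-sample pore centers (nm, x along columns / y along rows).
.placePores <- function(diametersNm, imageShape, pixelSizeNm, psfFwhmNm,
                        sepFactor, seed) {
  n <- length(diametersNm)
  if (n == 0) return(matrix(numeric(0), ncol = 2L))
  extX <- (imageShape[2] - 1) * pixelSizeNm
  extY <- (imageShape[1] - 1) * pixelSizeNm
  withr::with_seed(seed, {
    centers <- matrix(NA_real_, n, 2L)
    for (i in seq_len(n)) {
      m <- diametersNm[i] / 2 + psfFwhmNm  # guard band: radius + PSF
      if (2 * m >= min(extX, extY))
        stop("image too small to place a pore of diameter ",
             diametersNm[i], " nm")
      ok <- FALSE
      for (try in seq_len(20000L)) {
        cand <- c(stats::runif(1, m, extX - m), stats::runif(1, m, extY - m))
        if (i == 1L) { ok <- TRUE } else {
          prev <- centers[seq_len(i - 1L), , drop = FALSE]
          dd <- sqrt((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2)
          minSep <- sepFactor * pmax(diametersNm[seq_len(i - 1L)], diametersNm[i])
          ok <- all(dd >= minSep)
        }
        if (ok) { centers[i, ] <- cand; break }
      }
      if (!ok) stop("could not place pore ", i,
                    " with the requested separation; enlarge the image")
    }
    centers
  })
}

## Smooth multiplicative staining bias: 1 + sum of 2-4 low-frequency
## cosine modes with random orientation and phase, total amplitude A so
## that the field stays within [1 - A, 1 + A].
.biasField <- function(imageShape, amplitude) {
  nr <- imageShape[1]; nc <- imageShape[2]
  if (amplitude <= 0) return(matrix(1, nr, nc))
  k <- sample(2:4, 1L)
  a <- stats::runif(k, 0.5, 1); a <- a / sum(a) * amplitude
  yy <- matrix(seq_len(nr) / nr, nr, nc)
  xx <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  b <- matrix(1, nr, nc)
  for (j in seq_len(k)) {
    fx <- stats::runif(1, 0.3, 1.5) * sample(c(-1, 1), 1)
    fy <- stats::runif(1, 0.3, 1.5) * sample(c(-1, 1), 1)
    ph <- stats::runif(1, 0, 2 * pi)
    b <- b + a[j] * cos(2 * pi * (fx * xx + fy * yy) + ph)
  }
  b
}

## Anti-aliased disk coverage: fraction of each pixel covered by the
## disk, estimated on a 5x5 subpixel grid (bias < 0.04 px^2 per pixel).
.diskCoverage <- function(imageShape, cxPx, cyPx, radiusPx) {
  nr <- imageShape[1]; nc <- imageShape[2]
  sub <- 5L
  off <- (seq_len(sub) - (sub + 1) / 2) / sub
  r0 <- max(0L, floor(cyPx - radiusPx - 1)); r1 <- min(nr - 1L, ceiling(cyPx + radiusPx + 1))
  c0 <- max(0L, floor(cxPx - radiusPx - 1)); c1 <- min(nc - 1L, ceiling(cxPx + radiusPx + 1))
  rows <- r0:r1; cols <- c0:c1
  cov <- matrix(0, length(rows), length(cols))
  for (oy in off) for (ox in off) {
    dy <- outer(rows + oy - cyPx, rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols + ox - cxPx)
    cov <- cov + (dy * dy + dx * dx <= radiusPx^2)
  }
  list(rows = rows + 1L, cols = cols + 1L, coverage = cov / sub^2)
}

#' Render a synthetic sieve-plate membrane image
#'
#' Renders the stained membrane at \code{membraneLevel} modulated by a
#' smooth multiplicative bias field, carves out each pore as an
#' anti-aliased dark disk at \code{backgroundLevel}, convolves with a
#' Gaussian PSF of the recorded FWHM, and applies the noise model. The
#' returned truth record is the input, unchanged, so detections can be
#' scored against it.
#'
#' @param truth a \linkS4class{SievePlateTruth}.
#' @return list with elements \code{image} (a \linkS4class{PixelGrid2D})
#'   and \code{truth} (the input record).
#' @examples
#' tr <- sievePlateTruth(c(200, 250), imageShape = c(64, 64),
#'                       biasFieldAmplitude = 0, noiseModel = "none",
#'                       seed = 3)
#' sim <- simulateSieveImage(tr)
#' dim(pixelValues(sim$image))
#' @export
simulateSieveImage <- function(truth) {
  stopifnot(is(truth, "SievePlateTruth"))
  shp <- truth@imageShape
  px <- truth@pixelSizeNm
  n <- length(truth@diametersNm)
  ## bounds check: every disk must fit inside the image
  if (n) {
    cx <- truth@centersNm[, 1] / px; cy <- truth@centersNm[, 2] / px
    r <- truth@diametersNm / 2 / px
    if (any(cx - r < -0.5) || any(cx + r > shp[2] - 0.5) ||
        any(cy - r < -0.5) || any(cy + r > shp[1] - 0.5))
      stop("pore out of image bounds")
  }
  withr::with_seed(truth@seed, {
    bias <- .biasField(shp, truth@biasFieldAmplitude)
    memb <- truth@membraneLevel * bias
    covTot <- matrix(0, shp[1], shp[2])
    if (n) {
      for (i in seq_len(n)) {
        dc <- .diskCoverage(shp, truth@centersNm[i, 1] / px,
                            truth@centersNm[i, 2] / px,
                            truth@diametersNm[i] / 2 / px)
        covTot[dc$rows, dc$cols] <- pmin(1, covTot[dc$rows, dc$cols] + dc$coverage)
      }
    }
    img <- memb * (1 - covTot) + truth@backgroundLevel * covTot
    sigmaPx <- truth@psfFwhmNm / (2 * sqrt(2 * log(2))) / px
    if (sigmaPx > 0.05)
      img <- .gaussBlur(img, sigmaPx)
    img <- switch(truth@noiseModel,
      "none" = img,
      "poisson" = matrix(stats::rpois(length(img), pmax(img, 0)),
                         nrow(img), ncol(img)),
      "gaussian" = img + matrix(stats::rnorm(length(img), 0, truth@readNoiseSd),
                                nrow(img), ncol(img)),
      "poisson+gaussian" = matrix(stats::rpois(length(img), pmax(img, 0)),
                                  nrow(img), ncol(img)) +
        matrix(stats::rnorm(length(img), 0, truth@readNoiseSd),
               nrow(img), ncol(img)))
    list(image = PixelGrid2D(img, px), truth = truth)
  })
}

## Gaussian blur with replicated borders (EBImage gblur uses circular
## boundaries; replication avoids wrap-around artifacts at image edges).
.gaussBlur <- function(m, sigmaPx) {
  pad <- 2L * as.integer(ceiling(3 * sigmaPx)) + 2L
  nr <- nrow(m); nc <- ncol(m)
  big <- m[c(rep(1L, pad), seq_len(nr), rep(nr, pad)),
           c(rep(1L, pad), seq_len(nc), rep(nc, pad))]
  sm <- EBImage::gblur(big, sigma = sigmaPx)
  as.matrix(sm)[pad + seq_len(nr), pad + seq_len(nc)]
}

#' Build a random hyperspectral ground truth emulating liver tissue
#'
#' The lipid amplitude map (2845 cm^-1) is a dense collection of Gaussian
#' droplet-like blobs (emulating microvesicular steatosis), the protein
#' map (2920 cm^-1) a high-contrast cellular background (hepatocytes
#' against sinusoidal gaps), and the baseline a small smooth offset; all
#' nonnegative.
#'
#' @param nrow,ncol spatial shape (default 64 x 64).
#' @param nDroplets number of lipid droplets (default 30).
#' @param peakFwhmCm1 Gaussian peak FWHM recorded in the truth (default
#'   40 cm^-1).
#' @param noiseSd additive gaussian noise SD recorded in the truth, in
#'   the same units as the amplitudes (default 0).
#' @param seed integer seed.
#' @return an \linkS4class{HsiTruth}.
#' @export
randomHsiTruth <- function(nrow = 64L, ncol = 64L, nDroplets = 30L,
                           peakFwhmCm1 = 40, noiseSd = 0, seed = 1L) {
  withr::with_seed(seed, {
    yy <- matrix(seq_len(nrow), nrow, ncol)
    xx <- matrix(rep(seq_len(ncol), each = nrow), nrow, ncol)
    lipid <- matrix(0, nrow, ncol)
    for (i in seq_len(nDroplets)) {
      cx <- stats::runif(1, 1, ncol); cy <- stats::runif(1, 1, nrow)
      r <- stats::runif(1, 1.5, 5); amp <- stats::runif(1, 0.3, 1.5)
      lipid <- lipid + amp * exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * r^2))
    }
    ## protein: hepatocytes (high) against sinusoidal gaps (low) - a
    ## soft-thresholded smooth random field with strong contrast
    raw <- .gaussBlur(matrix(stats::runif(nrow * ncol), nrow, ncol), 3)
    z <- (raw - stats::median(raw)) / max(stats::sd(raw), 1e-12)
    protein <- 0.1 + 0.9 / (1 + exp(-3 * z))
    baseline <- 0.05 + 0.03 * sin(2 * pi * (xx + yy) / (nrow + ncol))
    new("HsiTruth", amp2845 = lipid, amp2920 = protein,
        baseline = baseline, peakFwhmCm1 = as.numeric(peakFwhmCm1),
        noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
  })
}

#' Synthesize a hyperspectral SRS cube from ground-truth maps
#'
#' Per pixel, the spectrum is baseline + A2845 G(v; 2845, fwhm) +
#' A2920 G(v; 2920, fwhm) + gaussian noise, where G is a unit-peak
#' Gaussian, sampled on the given wavenumber axis (default 2790-3020
#' cm^-1 in 15 cm^-1 steps, 16 samples).
#'
#' @param truth an \linkS4class{HsiTruth}.
#' @param axis a \linkS4class{SpectralAxis} (default acquisition grid).
#' @param pixelSizeUm pixel pitch recorded in the cube (default 0.5 um).
#' @return list with elements \code{cube} (a \linkS4class{SpectralCube})
#'   and \code{truth} (the input record).
#' @export
simulateHsiCube <- function(truth, axis = SpectralAxis(), pixelSizeUm = 0.5) {
  stopifnot(is(truth, "HsiTruth"), is(axis, "SpectralAxis"))
  w <- axis@wavenumbersCm1
  g <- function(center) exp(-4 * log(2) * (w - center)^2 / truth@peakFwhmCm1^2)
  d <- dim(truth@amp2845)
  K <- length(w)
  cube <- array(0, c(d[1], d[2], K))
  g1 <- g(2845); g2 <- g(2920)
  for (k in seq_len(K))
    cube[, , k] <- truth@baseline + truth@amp2845 * g1[k] + truth@amp2920 * g2[k]
  if (truth@noiseSd > 0)
    cube <- cube + withr::with_seed(truth@seed,
      array(stats::rnorm(length(cube), 0, truth@noiseSd), dim(cube)))
  list(cube = SpectralCube(cube, axis, pixelSizeUm), truth = truth)
}

#' Anti-aliased uniform disk phantom for OPT tests
#'
#' @param n side length in pixels.
#' @param radiusPx disk radius in pixels (default 0.35 n).
#' @param value disk intensity (default 1).
#' @param centerPx optional (x, y) center in 0-based pixels (default the
#'   image center).
#' @param pixelSizeUm pixel pitch in um (default 1).
#' @return a \linkS4class{PhantomImage}.
#' @export
diskPhantom <- function(n, radiusPx = 0.35 * n, value = 1, centerPx = NULL,
                        pixelSizeUm = 1) {
  n <- as.integer(n)
  if (is.null(centerPx)) centerPx <- c((n - 1) / 2, (n - 1) / 2)
  dc <- .diskCoverage(c(n, n), centerPx[1], centerPx[2], radiusPx)
  g <- matrix(0, n, n)
  g[dc$rows, dc$cols] <- value * dc$coverage
  PhantomImage(g, pixelSizeUm)
}

#' Forward-project a phantom into an OPT sinogram
#'
#' Computes parallel-beam line integrals of the phantom: row a of the
#' sinogram is the projection at angle \code{(a-1) * stepDeg}. Path
#' length is measured in detector pixels, so the sum over detector bins
#' of each noiseless projection equals the sum of the phantom pixels (up
#' to bilinear interpolation loss at the support edge). The default
#' geometry emulates the OPT acquisition: 600 views over 360 degrees at
#' a 0.6 degree step.
#'
#' @param phantom a \linkS4class{PhantomImage}.
#' @param nAngles number of projection angles (default 600).
#' @param stepDeg angular step in degrees (default 0.6).
#' @param noiseSd additive gaussian noise SD on the line integrals
#'   (default 0).
#' @param seed integer seed for the noise.
#' @return a \linkS4class{ProjectionSet} whose detector spacing equals
#'   the phantom pixel size.
#' @export
simulateOptProjections <- function(phantom, nAngles = 600L, stepDeg = 0.6,
                                   noiseSd = 0, seed = 1L) {
  stopifnot(is(phantom, "PhantomImage"))
  g <- phantom@grid
  if (length(g) == 0L) stop("empty phantom")
  if (nAngles < 1L) stop("need at least one angle")
  if (nAngles * stepDeg > 360 + 1e-6)
    stop("angular range exceeds 360 degrees")
  nr <- nrow(g); nc <- ncol(g)
  nDet <- max(nr, nc)
  cDet <- (nDet - 1) / 2
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  tIdx <- (0:(nDet - 1)) - cDet          # detector coordinate
  sIdx <- (0:(nDet - 1)) - cDet          # integration coordinate
  tt <- rep(tIdx, times = nDet)
  ss <- rep(sIdx, each = nDet)
  angles <- (seq_len(nAngles) - 1L) * stepDeg
  sino <- matrix(0, nAngles, nDet)
  for (a in seq_len(nAngles)) {
    th <- angles[a] * pi / 180
    x <- cx + tt * cos(th) - ss * sin(th)
    y <- cy + tt * sin(th) + ss * cos(th)
    v <- .bilinearAt(g, y, x)
    sino[a, ] <- rowSums(matrix(v, nDet, nDet))
  }
  if (noiseSd > 0)
    sino <- sino + withr::with_seed(seed,
      matrix(stats::rnorm(length(sino), 0, noiseSd), nAngles, nDet))
  ProjectionSet(sino, angles, phantom@pixelSizeUm)
}

## Vectorized bilinear lookup at fractional (row, col) 0-based positions;
## zero outside the grid.
.bilinearAt <- function(g, y, x) {
  nr <- nrow(g); nc <- ncol(g)
  i0 <- floor(y); j0 <- floor(x)
  fy <- y - i0; fx <- x - j0
  v <- numeric(length(y))
  ok <- i0 >= -1 & i0 <= nr - 1 & j0 >= -1 & j0 <= nc - 1
  if (!any(ok)) return(v)
  gAt <- function(i, j) {
    inb <- i >= 0 & i <= nr - 1 & j >= 0 & j <= nc - 1
    out <- numeric(length(i))
    out[inb] <- g[cbind(i[inb] + 1L, j[inb] + 1L)]
    out
  }
  i0k <- i0[ok]; j0k <- j0[ok]; fyk <- fy[ok]; fxk <- fx[ok]
  v[ok] <- gAt(i0k, j0k) * (1 - fyk) * (1 - fxk) +
    gAt(i0k + 1, j0k) * fyk * (1 - fxk) +
    gAt(i0k, j0k + 1) * (1 - fyk) * fxk +
    gAt(i0k + 1, j0k + 1) * fyk * fxk
  v
}
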
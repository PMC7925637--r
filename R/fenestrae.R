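## Fenestrae identification and sizing in super-resolution membrane
## images. Pipeline: 2x bilinear upsampling -> brightness flattening by a
## grey-scale dilation envelope -> inversion -> local-mean adaptive
## threshold -> distance-transform markers -> marker-based watershed
## split -> equivalent-diameter sizing with [95, 320] nm retention.

#' Preprocess a membrane image for fenestrae detection
#'
#' Expands the image to double the pixel count per axis (bilinear), evens
#' out the staining brightness by dividing by a grey-scale dilation of
#' the upsampled image (disk structuring element), inverts the result so
#' pores become bright, and rescales to [0, 1].
#'
#' @param img a \linkS4class{PixelGrid2D}, at least 8 x 8.
#' @param params a \linkS4class{FenestraeParams}.
#' @return a \linkS4class{PixelGrid2D} with 2x the pixels per axis and
#'   half the pixel size, values in [0, 1] with pores bright.
#' @export
preprocessMembrane <- function(img, params = FenestraeParams()) {
  stopifnot(is(img, "PixelGrid2D"), is(params, "FenestraeParams"))
  v <- img@values
  if (nrow(v) < 8L || ncol(v) < 8L) stop("image must be at least 8 x 8")
  if (max(v) <= 0) stop("degenerate input: all-zero image cannot be flattened")
  f <- params@upsampleFactor
  up <- as.matrix(EBImage::resize(v, w = f * nrow(v), h = f * ncol(v),
                                  filter = "bilinear"))
  brush <- EBImage::makeBrush(2L * params@dilationRadiusPx + 1L, shape = "disc")
  env <- as.matrix(EBImage::dilate(up, brush))
  eps <- 1e-8 * max(env)
  flat <- up / pmax(env, eps)
  inv <- max(flat) - flat
  rng <- range(inv)
  out <- if (diff(rng) > 0) (inv - rng[1]) / diff(rng) else inv * 0
  PixelGrid2D(out, img@pixelSizeNm / f)
}

## Local arithmetic mean over a block x block window via an integral
## image; windows are truncated at the borders (mean over the in-bounds
## part), keeping the estimate unbiased at edges.
.localMean <- function(m, block) {
  h <- (block - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ii <- matrix(0, nr + 1L, nc + 1L)
  ii[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r0 <- pmax(seq_len(nr) - h - 1L, 0L); r1 <- pmin(seq_len(nr) + h, nr)
  c0 <- pmax(seq_len(nc) - h - 1L, 0L); c1 <- pmin(seq_len(nc) + h, nc)
  S <- ii[r1 + 1L, c1 + 1L] - ii[r0 + 1L, c1 + 1L] -
    ii[r1 + 1L, c0 + 1L] + ii[r0 + 1L, c0 + 1L]
  area <- outer(r1 - r0, c1 - c0)
  S / area
}

#' Segment fenestrae by adaptive thresholding and watershed splitting
#'
#' Binarizes the preprocessed image with a local-mean adaptive threshold
#' (pixels strictly above local mean + \code{thresholdOffset} are
#' foreground), finds watershed markers as local maxima of the
#' Gaussian-smoothed Euclidean distance transform subject to a minimum
#' mutual separation, splits touching pores by marker-based watershed
#' (seeded region growing on the distance transform restricted to the
#' mask), and removes labels touching the image border.
#'
#' @param preImg the output of \code{\link{preprocessMembrane}} (pixel
#'   size already halved).
#' @param params a \linkS4class{FenestraeParams}.
#' @return integer label matrix (0 = background, 1..K = pores) with the
#'   upsampled pixel size attached as attribute \code{pixelSizeNm}.
#' @export
segmentFenestrae <- function(preImg, params = FenestraeParams()) {
  stopifnot(is(preImg, "PixelGrid2D"), is(params, "FenestraeParams"))
  v <- preImg@values
  if (params@blockSizePx > min(dim(v)))
    stop("blockSizePx larger than the image")
  lm <- .localMean(v, params@blockSizePx)
  mask <- v > lm + params@thresholdOffset    # equality -> background
  out <- matrix(0L, nrow(v), ncol(v))
  if (any(mask)) {
    dm <- as.matrix(EBImage::distmap(mask))
    ## light smoothing regularizes distance plateaus without flattening
    ## the saddle between two touching pores (a wider kernel can invert
    ## the two-lobe topology at fenestra scale)
    dsm <- .gaussBlur(dm, 0.5)
    dsm[!mask] <- 0
    sepPx <- params@minPeakSeparationNm / preImg@pixelSizeNm
    markers <- .findMarkers(dsm, mask, sepPx)
    if (nrow(markers)) {
      seeds <- matrix(0L, nrow(v), ncol(v))
      seeds[markers] <- seq_len(nrow(markers))
      lab <- as.matrix(EBImage::propagate(dsm, seeds = seeds, mask = mask))
      out <- .dropBorderLabels(matrix(as.integer(lab), nrow(v), ncol(v)))
    }
  }
  attr(out, "pixelSizeNm") <- preImg@pixelSizeNm
  out
}

## Local maxima of dsm within the mask with minimum mutual separation
## sepPx: candidates are maxima over a disk neighborhood, then a greedy
## pass ordered by (-height, row, col) enforces the exact separation.
## Every 8-connected mask component is guaranteed at least one marker.
.findMarkers <- function(dsm, mask, sepPx) {
  r <- max(1L, as.integer(floor(sepPx)))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  dil <- as.matrix(EBImage::dilate(dsm, brush))
  cand <- which(mask & dsm > 0 & dsm >= dil - 1e-12, arr.ind = TRUE)
  comp <- .label8(mask)
  pick <- matrix(integer(0), 0L, 2L)
  if (nrow(cand)) {
    o <- order(-dsm[cand], cand[, 1L], cand[, 2L])
    cand <- cand[o, , drop = FALSE]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      prev <- cand[keep, , drop = FALSE]
      d2 <- (prev[, 1L] - cand[i, 1L])^2 + (prev[, 2L] - cand[i, 2L])^2
      if (all(d2 >= sepPx^2)) keep[i] <- TRUE
    }
    pick <- cand[keep, , drop = FALSE]
  }
  ## components whose every candidate was suppressed get their argmax back
  have <- unique(comp[pick])
  for (k in setdiff(setdiff(unique(as.vector(comp)), 0L), have)) {
    idx <- which(comp == k)
    best <- idx[which.max(dsm[idx])]
    pick <- rbind(pick, cbind((best - 1L) %% nrow(dsm) + 1L,
                              (best - 1L) %/% nrow(dsm) + 1L))
  }
  pick
}

## 8-connected labeling of a logical mask (two-pass union-find).
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    nb <- integer(0)
    if (i > 1L && mask[i - 1L, j]) nb <- c(nb, lab[i - 1L, j])
    if (j > 1L && mask[i, j - 1L]) nb <- c(nb, lab[i, j - 1L])
    if (i > 1L && j > 1L && mask[i - 1L, j - 1L]) nb <- c(nb, lab[i - 1L, j - 1L])
    if (i < nr && j > 1L && mask[i + 1L, j - 1L]) nb <- c(nb, lab[i + 1L, j - 1L])
    if (!length(nb)) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
    } else {
      roots <- vapply(nb, find, integer(1))
      m <- min(roots)
      lab[i, j] <- m
      for (rt in roots) parent[rt] <- m
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  lab
}

## Remove labels touching the border, relabel 1..K in first-appearance
## order (column-major), keep it deterministic.
.dropBorderLabels <- function(lab) {
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- setdiff(border, 0L)
  if (length(border)) lab[lab %in% border] <- 0L
  keep <- setdiff(unique(as.vector(lab)), 0L)
  if (length(keep)) {
    remap <- integer(max(keep)); remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Measure labelled fenestrae and apply the diameter size filter
#'
#' Computes, per label, the equivalent-area circle diameter
#' d = 2 sqrt(area / pi) * pixelSize (on the upsampled grid) and the
#' centroid reported on the original grid (0-based, pixel centers).
#' Records with d < \code{dMinNm} or d > \code{dMaxNm} are excluded: below
#' 95 nm a detection is under the SR-SIM resolution limit, above 320 nm it
#' is considered a membrane hole rather than a fenestra. Bounds are
#' inclusive.
#'
#' @param labels integer label matrix from \code{\link{segmentFenestrae}}.
#' @param pixelSizeNmUpsampled pixel size of the upsampled grid in nm
#'   (half the original); taken from the labels attribute when NULL.
#' @param params a \linkS4class{FenestraeParams}.
#' @param roiId,cellId identifiers attached to every record.
#' @return data.frame with columns roi_id, cell_id, row_px, col_px
#'   (0-based centroid on the original grid), area_px_upsampled,
#'   diameter_nm; zero rows when nothing is retained.
#' @export
measureFenestrae <- function(labels, pixelSizeNmUpsampled = NULL,
                             params = FenestraeParams(),
                             roiId = "roi1", cellId = "cell1") {
  if (is.null(pixelSizeNmUpsampled))
    pixelSizeNmUpsampled <- attr(labels, "pixelSizeNm")
  stopifnot(is.numeric(pixelSizeNmUpsampled), pixelSizeNmUpsampled > 0)
  empty <- data.frame(roi_id = character(0), cell_id = character(0),
                      row_px = numeric(0), col_px = numeric(0),
                      area_px_upsampled = integer(0), diameter_nm = numeric(0))
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (!length(ids)) return(empty)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lb <- labels[idx]
  area <- as.integer(table(factor(lb, levels = sort(ids))))
  rowc <- tapply(idx[, 1L] - 1, lb, mean)   # 0-based, upsampled grid
  colc <- tapply(idx[, 2L] - 1, lb, mean)
  f <- 2  # centroids reported on the original grid
  d <- 2 * sqrt(area / pi) * pixelSizeNmUpsampled
  rec <- data.frame(roi_id = roiId, cell_id = cellId,
                    row_px = as.numeric(rowc) / f,
                    col_px = as.numeric(colc) / f,
                    area_px_upsampled = area, diameter_nm = d)
  rec <- rec[rec$diameter_nm >= params@dMinNm & rec$diameter_nm <= params@dMaxNm, ]
  rownames(rec) <- NULL
  rec
}

#' Bin retained fenestra diameters into a size histogram
#'
#' Bins of \code{binWidthNm} over \code{histRangeNm} (default 10 nm bins
#' over 90-320 nm), half-open [low, high) except the last bin, which is
#' closed. The modal bin is the most populated one (ties broken toward
#' the smallest lower edge). The tail-decay length is 1 / |slope| of a
#' log-linear least-squares fit to the nonzero bin counts from the modal
#' bin upward, NA when fewer than 3 such bins exist.
#'
#' @param records data.frame from \code{\link{measureFenestrae}} (or any
#'   frame with a \code{diameter_nm} column), already size-filtered.
#' @param params a \linkS4class{FenestraeParams}.
#' @return a \linkS4class{SizeHistogram}.
#' @export
buildSizeHistogram <- function(records, params = FenestraeParams()) {
  d <- records$diameter_nm
  edges <- seq(params@histRangeNm[1], params@histRangeNm[2],
               by = params@binWidthNm)
  if (length(d) && (any(d < edges[1]) || any(d > edges[length(edges)])))
    stop("record outside the histogram range: size filter inconsistent")
  nb <- length(edges) - 1L
  if (length(d)) {
    bin <- findInterval(d, edges, rightmost.closed = TRUE)
    counts <- tabulate(bin, nbins = nb)
  } else counts <- integer(nb)
  nTot <- sum(counts)
  modal <- if (nTot == 0L) NA_real_ else edges[which.max(counts)]
  decay <- NA_real_
  if (nTot > 0L) {
    im <- which.max(counts)
    upper <- im:nb
    nz <- upper[counts[upper] > 0L]
    if (length(nz) >= 3L) {
      centers <- edges[nz] + params@binWidthNm / 2
      fit <- stats::lm(log(counts[nz]) ~ centers)
      sl <- stats::coef(fit)[2]
      if (is.finite(sl) && abs(sl) > 0) decay <- 1 / abs(sl)
    }
  }
  new("SizeHistogram", binEdgesNm = edges, counts = as.integer(counts),
      nTotal = as.integer(nTot), modalBinLowerEdgeNm = modal,
      tailDecayNm = decay)
}

#' Draw detection circles into an annotation channel
#'
#' For every record, draws a circle of diameter twice the measured
#' equivalent diameter, centered at the detection centroid, into a
#' separate annotation channel; doubling makes small fenestrae easy to
#' spot by eye. Source pixels are never modified. Records whose centroid
#' falls outside the image are skipped with a warning.
#'
#' @param img the original \linkS4class{PixelGrid2D} the records were
#'   measured on.
#' @param records data.frame from \code{\link{measureFenestrae}}.
#' @return an \linkS4class{OverlayImage}.
#' @export
renderOverlay <- function(img, records) {
  stopifnot(is(img, "PixelGrid2D"))
  v <- img@values
  ann <- matrix(0, nrow(v), ncol(v))
  nDrawn <- 0L
  for (i in seq_len(nrow(records))) {
    cy <- records$row_px[i]; cx <- records$col_px[i]
    if (cy < 0 || cy > nrow(v) - 1 || cx < 0 || cx > ncol(v) - 1) {
      warning("record ", i, " centroid outside the image; skipped")
      next
    }
    rPx <- records$diameter_nm[i] / img@pixelSizeNm  # radius = 2d/2
    nSteps <- max(16L, as.integer(ceiling(8 * pi * rPx)))
    th <- seq(0, 2 * pi, length.out = nSteps + 1L)[-1L]
    rr <- round(cy + rPx * sin(th)) + 1
    cc <- round(cx + rPx * cos(th)) + 1
    ok <- rr >= 1 & rr <= nrow(v) & cc >= 1 & cc <= ncol(v)
    ann[cbind(rr[ok], cc[ok])] <- 1
    nDrawn <- nDrawn + 1L
  }
  new("OverlayImage", source = img, annotation = ann, nDrawn = nDrawn)
}

#' Run the full fenestrae pipeline on one region of interest
#'
#' Composes preprocessing, segmentation, sizing/filtering, histogramming
#' and overlay rendering. Fully deterministic: identical (image, params)
#' give bit-identical results.
#'
#' @param img a \linkS4class{PixelGrid2D} membrane image.
#' @param params a \linkS4class{FenestraeParams}.
#' @param roiId,cellId identifiers carried into every record, so records
#'   from many regions of interest can be pooled into one histogram.
#' @return list with \code{records} (data.frame), \code{histogram}
#'   (\linkS4class{SizeHistogram}) and \code{overlay}
#'   (\linkS4class{OverlayImage}).
#' @examples
#' tr <- sievePlateTruth(c(200, 250), imageShape = c(96, 96),
#'                       biasFieldAmplitude = 0, noiseModel = "none",
#'                       seed = 2)
#' res <- detectFenestrae(simulateSieveImage(tr)$image)
#' nrow(res$records)
#' @export
detectFenestrae <- function(img, params = FenestraeParams(),
                            roiId = "roi1", cellId = "cell1") {
  pre <- preprocessMembrane(img, params)
  labels <- segmentFenestrae(pre, params)
  records <- measureFenestrae(labels, pre@pixelSizeNm, params, roiId, cellId)
  histogram <- buildSizeHistogram(records, params)
  overlay <- renderOverlay(img, records)
  list(records = records, histogram = histogram, overlay = overlay)
}

#' Match detections to ground-truth pores
#'
#' Greedy nearest-neighbor matching (by center distance, closest pairs
#' first) between detected records and a truth table, with a maximum
#' match distance. Used to score parameter recovery on synthetic data.
#'
#' @param records data.frame from \code{\link{measureFenestrae}}.
#' @param truth a \linkS4class{SievePlateTruth}.
#' @param maxDistNm maximum allowed center distance for a match
#'   (default 100 nm).
#' @return list with \code{matches} (data.frame: record index, truth
#'   index, distance_nm, d_est_nm, d_true_nm), \code{recall},
#'   \code{precision}, and \code{medianAbsDiamErrNm}.
#' @export
matchToTruth <- function(records, truth, maxDistNm = 100) {
  stopifnot(is(truth, "SievePlateTruth"))
  px <- truth@pixelSizeNm
  nR <- nrow(records); nT <- length(truth@diametersNm)
  if (nR == 0L || nT == 0L) {
    return(list(matches = data.frame(record = integer(0), truth = integer(0),
                                     distance_nm = numeric(0),
                                     d_est_nm = numeric(0), d_true_nm = numeric(0)),
                recall = if (nT == 0L) NA_real_ else 0,
                precision = if (nR == 0L) NA_real_ else 0,
                medianAbsDiamErrNm = NA_real_))
  }
  dx <- outer(records$col_px * px, truth@centersNm[, 1], "-")
  dy <- outer(records$row_px * px, truth@centersNm[, 2], "-")
  D <- sqrt(dx^2 + dy^2)
  ord <- order(D)
  usedR <- logical(nR); usedT <- logical(nT)
  m <- list()
  for (k in ord) {
    if (D[k] > maxDistNm) break
    i <- (k - 1L) %% nR + 1L; j <- (k - 1L) %/% nR + 1L
    if (usedR[i] || usedT[j]) next
    usedR[i] <- TRUE; usedT[j] <- TRUE
    m[[length(m) + 1L]] <- c(i, j, D[k])
  }
  mm <- if (length(m)) do.call(rbind, m) else matrix(numeric(0), 0L, 3L)
  matches <- data.frame(record = as.integer(mm[, 1]),
                        truth = as.integer(mm[, 2]),
                        distance_nm = mm[, 3],
                        d_est_nm = records$diameter_nm[mm[, 1]],
                        d_true_nm = truth@diametersNm[mm[, 2]])
  list(matches = matches,
       recall = nrow(matches) / nT,
       precision = nrow(matches) / nR,
       medianAbsDiamErrNm = if (nrow(matches))
         stats::median(abs(matches$d_est_nm - matches$d_true_nm)) else NA_real_)
}
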
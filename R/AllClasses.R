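## Central S4 containers. All image matrices are stored row-major in the
## usual R sense: dim 1 = image row (y), dim 2 = image column (x).
## Reported pixel coordinates are 0-based with centroids at pixel centers.

#' PixelGrid2D: a 2D intensity image with physical pixel size
#'
#' The unit of all 2D image processing in the package: a finite real-valued
#' intensity matrix (arbitrary units) plus the physical pixel pitch in nm.
#'
#' @slot values numeric matrix of finite intensities.
#' @slot pixelSizeNm positive numeric scalar, pixel pitch in nm.
#' @export
setClass("PixelGrid2D",
  representation(values = "matrix", pixelSizeNm = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@values)) return("values must be numeric")
    if (any(!is.finite(object@values))) return("values must be finite (no NA/NaN/Inf)")
    if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
        object@pixelSizeNm <= 0) return("pixelSizeNm must be a positive scalar")
    TRUE
  })

#' Construct a PixelGrid2D
#'
#' @param values numeric matrix of finite intensities.
#' @param pixelSizeNm positive pixel pitch in nm.
#' @return a \linkS4class{PixelGrid2D}.
#' @examples
#' img <- PixelGrid2D(matrix(1, 8, 8), pixelSizeNm = 40)
#' pixelSize(img)
#' @export
PixelGrid2D <- function(values, pixelSizeNm) {
  new("PixelGrid2D", values = values, pixelSizeNm = as.numeric(pixelSizeNm))
}

#' SpectralAxis: the wavenumber sampling of a hyperspectral cube
#'
#' @slot wavenumbersCm1 strictly increasing numeric vector (cm^-1),
#'   length >= 3.
#' @export
setClass("SpectralAxis",
  representation(wavenumbersCm1 = "numeric"),
  validity = function(object) {
    w <- object@wavenumbersCm1
    if (length(w) < 3L) return("axis needs at least 3 samples")
    if (any(!is.finite(w))) return("axis must be finite")
    if (any(diff(w) <= 0)) return("axis must be strictly increasing")
    TRUE
  })

#' Construct a SpectralAxis
#'
#' The default reproduces the acquisition grid used for hyperspectral SRS
#' of liver tissue: 2790 to 3020 cm^-1 in 15 cm^-1 steps (16 samples),
#' covering the CH2 symmetric (2845 cm^-1, lipid) and anti-symmetric
#' (2920 cm^-1, protein-associated) stretching resonances.
#'
#' @param wavenumbersCm1 strictly increasing numeric vector in cm^-1.
#' @return a \linkS4class{SpectralAxis}.
#' @examples
#' length(wavenumbers(SpectralAxis()))  # 16
#' @export
SpectralAxis <- function(wavenumbersCm1 = seq(2790, 3020, by = 15)) {
  new("SpectralAxis", wavenumbersCm1 = as.numeric(wavenumbersCm1))
}

#' SpectralCube: an x-y-wavenumber hyperspectral image stack
#'
#' @slot values 3D numeric array (rows, cols, K) of finite intensities.
#' @slot axis the \linkS4class{SpectralAxis}; K must equal its length.
#' @slot pixelSizeUm positive pixel pitch in um.
#' @export
setClass("SpectralCube",
  representation(values = "array", axis = "SpectralAxis", pixelSizeUm = "numeric"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a 3D array (rows, cols, K)")
    if (any(!is.finite(object@values))) return("values must be finite")
    if (d[3L] != length(object@axis@wavenumbersCm1))
      return("third dimension must match the spectral axis length")
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
      return("pixelSizeUm must be a positive scalar")
    TRUE
  })

#' Construct a SpectralCube
#'
#' @param values 3D array (rows, cols, K).
#' @param axis a \linkS4class{SpectralAxis} with K wavenumbers.
#' @param pixelSizeUm positive pixel pitch in um.
#' @return a \linkS4class{SpectralCube}.
#' @export
SpectralCube <- function(values, axis = SpectralAxis(), pixelSizeUm = 0.5) {
  new("SpectralCube", values = values, axis = axis,
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' PeakBasis: the parametric Raman peak model for spectral unmixing
#'
#' Describes the preselected spectra fitted to every pixel: unit-amplitude
#' Gaussian peaks at fixed centers plus an optional constant baseline.
#' Defaults target the lipid CH2 symmetric stretch at 2845 cm^-1 and the
#' protein-associated anti-symmetric CH stretch at 2920 cm^-1.
#'
#' @slot centersCm1 numeric vector of peak centers (cm^-1).
#' @slot fwhmCm1 positive full width at half maximum (cm^-1).
#' @slot includeBaseline logical; fit a per-pixel constant offset.
#' @export
setClass("PeakBasis",
  representation(centersCm1 = "numeric", fwhmCm1 = "numeric",
                 includeBaseline = "logical"),
  validity = function(object) {
    if (length(object@centersCm1) < 1L) return("need at least one peak center")
    if (any(!is.finite(object@centersCm1))) return("centers must be finite")
    if (length(object@fwhmCm1) != 1L || object@fwhmCm1 <= 0)
      return("fwhmCm1 must be a positive scalar")
    if (length(object@includeBaseline) != 1L || is.na(object@includeBaseline))
      return("includeBaseline must be TRUE or FALSE")
    TRUE
  })

#' Construct a PeakBasis
#'
#' @param centersCm1 peak centers in cm^-1 (default lipid 2845 and
#'   protein 2920).
#' @param fwhmCm1 Gaussian FWHM in cm^-1 (default 40).
#' @param includeBaseline include a constant per-pixel baseline column
#'   (default TRUE).
#' @return a \linkS4class{PeakBasis}.
#' @export
PeakBasis <- function(centersCm1 = c(2845, 2920), fwhmCm1 = 40,
                      includeBaseline = TRUE) {
  new("PeakBasis", centersCm1 = as.numeric(centersCm1),
      fwhmCm1 = as.numeric(fwhmCm1), includeBaseline = includeBaseline)
}

#' AmplitudeMaps: per-pixel results of the hyperspectral fit
#'
#' @slot amplitudes 3D array (rows, cols, nPeaks) of nonnegative fitted
#'   peak amplitudes, one plane per peak center.
#' @slot centersCm1 peak centers matching the third dimension.
#' @slot baseline numeric matrix of per-pixel baseline coefficients
#'   (all zero when the basis had no baseline column).
#' @slot residualRms nonnegative numeric matrix of per-pixel residual RMS.
#' @export
setClass("AmplitudeMaps",
  representation(amplitudes = "array", centersCm1 = "numeric",
                 baseline = "matrix", residualRms = "matrix"),
  validity = function(object) {
    d <- dim(object@amplitudes)
    if (length(d) != 3L) return("amplitudes must be (rows, cols, nPeaks)")
    if (d[3L] != length(object@centersCm1))
      return("one amplitude plane per peak center required")
    if (!identical(d[1:2], dim(object@baseline)) ||
        !identical(d[1:2], dim(object@residualRms)))
      return("all maps must share the cube's spatial shape")
    if (any(object@amplitudes < -1e-12)) return("amplitudes must be nonnegative")
    if (any(object@residualRms < 0)) return("residual RMS must be nonnegative")
    TRUE
  })

#' ProjectionSet: an angular stack of parallel-beam line integrals
#'
#' One OPT sinogram: row a holds the projection acquired at
#' \code{anglesDeg[a]}. Line integrals are in pixel units (path length
#' measured in detector pixels), so the sum over detector bins of a
#' projection equals the sum of the projected image's pixels.
#'
#' @slot sinogram numeric matrix (nAngles x nDetector) of finite reals.
#' @slot anglesDeg increasing numeric vector with uniform step.
#' @slot detectorSpacingUm positive detector pixel pitch in um.
#' @export
setClass("ProjectionSet",
  representation(sinogram = "matrix", anglesDeg = "numeric",
                 detectorSpacingUm = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@sinogram))) return("sinogram must be finite")
    if (nrow(object@sinogram) != length(object@anglesDeg))
      return("one sinogram row per angle required")
    st <- diff(object@anglesDeg)
    if (length(st) && (any(st <= 0) || diff(range(st)) > 1e-9))
      return("angles must be increasing with a uniform step")
    if (length(object@detectorSpacingUm) != 1L || object@detectorSpacingUm <= 0)
      return("detectorSpacingUm must be a positive scalar")
    TRUE
  })

#' Construct a ProjectionSet
#'
#' @param sinogram nAngles x nDetector matrix of line integrals.
#' @param anglesDeg increasing, uniformly spaced angles in degrees.
#' @param detectorSpacingUm detector pixel pitch in um.
#' @return a \linkS4class{ProjectionSet}.
#' @export
ProjectionSet <- function(sinogram, anglesDeg, detectorSpacingUm = 1) {
  new("ProjectionSet", sinogram = sinogram, anglesDeg = as.numeric(anglesDeg),
      detectorSpacingUm = as.numeric(detectorSpacingUm))
}

#' ReconSlice: a reconstructed tomographic cross-section
#'
#' @slot values n x n numeric matrix; pixels outside the inscribed
#'   reconstruction circle are zero.
#' @slot pixelSizeUm positive pixel pitch in um (equals the detector
#'   spacing of the source sinogram).
#' @export
setClass("ReconSlice",
  representation(values = "matrix", pixelSizeUm = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@values))) return("values must be finite")
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
      return("pixelSizeUm must be a positive scalar")
    TRUE
  })

#' PhantomImage: a nonnegative test object for OPT simulation
#'
#' @slot grid nonnegative finite numeric matrix.
#' @slot pixelSizeUm positive pixel pitch in um.
#' @export
setClass("PhantomImage",
  representation(grid = "matrix", pixelSizeUm = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@grid))) return("grid must be finite")
    if (any(object@grid < 0)) return("grid must be nonnegative")
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
      return("pixelSizeUm must be a positive scalar")
    TRUE
  })

#' Construct a PhantomImage
#'
#' @param grid nonnegative numeric matrix.
#' @param pixelSizeUm positive pixel pitch in um.
#' @return a \linkS4class{PhantomImage}.
#' @export
PhantomImage <- function(grid, pixelSizeUm = 1) {
  new("PhantomImage", grid = grid, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' SievePlateTruth: ground truth of a simulated sieve-plate image
#'
#' Records everything the simulator rendered: pore centers and true
#' diameters (nm), image geometry, the lateral PSF width, membrane and
#' background levels, the bias-field strength and the noise model, plus
#' the seed, so every synthetic image is reproducible and every detection
#' can be matched back to a true pore.
#'
#' @slot centersNm n x 2 matrix of (x, y) pore centers in nm, where x runs
#'   along image columns and y along image rows, origin at the center of
#'   pixel (0, 0).
#' @slot diametersNm positive pore diameters in nm.
#' @slot pixelSizeNm positive pixel pitch in nm.
#' @slot imageShape integer (rows, cols).
#' @slot psfFwhmNm lateral PSF full width at half maximum in nm.
#' @slot membraneLevel expected photon count of the stained membrane.
#' @slot backgroundLevel expected photon count inside a pore.
#' @slot biasFieldAmplitude relative amplitude of the multiplicative
#'   staining bias field, in [0, 1).
#' @slot noiseModel one of "none", "poisson", "gaussian",
#'   "poisson+gaussian".
#' @slot readNoiseSd gaussian read-noise standard deviation (counts).
#' @slot seed integer RNG seed.
#' @export
setClass("SievePlateTruth",
  representation(centersNm = "matrix", diametersNm = "numeric",
                 pixelSizeNm = "numeric", imageShape = "integer",
                 psfFwhmNm = "numeric", membraneLevel = "numeric",
                 backgroundLevel = "numeric", biasFieldAmplitude = "numeric",
                 noiseModel = "character", readNoiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    n <- length(object@diametersNm)
    if (nrow(object@centersNm) != n)
      return("one center per diameter required")
    if (n && any(object@diametersNm <= 0)) return("diameters must be positive")
    if (object@pixelSizeNm <= 0) return("pixelSizeNm must be positive")
    if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
      return("imageShape must be (rows, cols) >= 1")
    if (object@psfFwhmNm <= 0) return("psfFwhmNm must be positive")
    if (object@membraneLevel <= 0) return("membraneLevel must be positive")
    if (object@biasFieldAmplitude < 0 || object@biasFieldAmplitude >= 1)
      return("biasFieldAmplitude must be in [0, 1)")
    if (!object@noiseModel %in% c("none", "poisson", "gaussian",
                                  "poisson+gaussian"))
      return("unknown noiseModel")
    TRUE
  })

#' HsiTruth: ground truth of a simulated hyperspectral cube
#'
#' @slot amp2845 nonnegative matrix, true lipid-peak amplitude map.
#' @slot amp2920 nonnegative matrix, true protein-peak amplitude map.
#' @slot baseline numeric matrix, true constant-baseline map.
#' @slot peakFwhmCm1 positive Gaussian FWHM used for both peaks (cm^-1).
#' @slot noiseSd nonnegative additive gaussian noise SD.
#' @slot seed integer RNG seed.
#' @export
setClass("HsiTruth",
  representation(amp2845 = "matrix", amp2920 = "matrix", baseline = "matrix",
                 peakFwhmCm1 = "numeric", noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (!identical(dim(object@amp2845), dim(object@amp2920)) ||
        !identical(dim(object@amp2845), dim(object@baseline)))
      return("the two amplitude maps and the baseline map must share one shape")
    if (any(object@amp2845 < 0) || any(object@amp2920 < 0))
      return("amplitude maps must be nonnegative")
    if (object@peakFwhmCm1 <= 0) return("peakFwhmCm1 must be positive")
    if (object@noiseSd < 0) return("noiseSd must be nonnegative")
    TRUE
  })

#' FenestraeParams: tunable parameters of the fenestrae pipeline
#'
#' @slot upsampleFactor fixed 2: images are expanded to double the pixel
#'   count per axis before processing.
#' @slot dilationRadiusPx disk radius (upsampled px) of the grey-scale
#'   dilation used as the staining-envelope estimate.
#' @slot blockSizePx odd window size (upsampled px) of the local-mean
#'   adaptive threshold.
#' @slot thresholdOffset offset added to the local mean; pixels strictly
#'   above local mean + offset are foreground. The one knob meant to be
#'   adjusted from image to image.
#' @slot minPeakSeparationNm minimum separation between watershed markers.
#' @slot dMinNm lower retention bound on the equivalent diameter (95 nm,
#'   the SR-SIM resolution limit; smaller detections are discarded).
#' @slot dMaxNm upper retention bound (320 nm; larger objects are membrane
#'   holes rather than fenestrae).
#' @slot binWidthNm histogram bin width in nm.
#' @slot histRangeNm histogram range (low, high) in nm.
#' @export
setClass("FenestraeParams",
  representation(upsampleFactor = "integer", dilationRadiusPx = "integer",
                 blockSizePx = "integer", thresholdOffset = "numeric",
                 minPeakSeparationNm = "numeric", dMinNm = "numeric",
                 dMaxNm = "numeric", binWidthNm = "numeric",
                 histRangeNm = "numeric"),
  validity = function(object) {
    if (object@upsampleFactor != 2L) return("upsampleFactor is fixed at 2")
    if (object@dilationRadiusPx < 1L) return("dilationRadiusPx must be >= 1")
    if (object@blockSizePx < 3L || object@blockSizePx %% 2L == 0L)
      return("blockSizePx must be an odd integer >= 3")
    if (object@minPeakSeparationNm <= 0) return("minPeakSeparationNm must be positive")
    if (object@dMinNm >= object@dMaxNm) return("dMinNm must be < dMaxNm")
    if (length(object@histRangeNm) != 2L || diff(object@histRangeNm) <= 0)
      return("histRangeNm must be (low, high) with low < high")
    nb <- diff(object@histRangeNm) / object@binWidthNm
    if (abs(nb - round(nb)) > 1e-9)
      return("binWidthNm must divide the histogram range")
    TRUE
  })

#' Construct FenestraeParams
#'
#' @param dilationRadiusPx disk radius in upsampled px (default 15).
#' @param blockSizePx odd adaptive-threshold window in upsampled px
#'   (default 51).
#' @param thresholdOffset local-mean offset, on the [0, 1] scale of the
#'   preprocessed image (default 0.3, about half the pore contrast above
#'   the membrane level, which places the cut near the half-intensity
#'   contour of a blurred pore); increase to suppress noise, reduce to
#'   catch faint pores. Meant to be tuned per image.
#' @param minPeakSeparationNm minimum marker separation (default 95 nm,
#'   the smallest credible pore).
#' @param dMinNm,dMaxNm retained diameter range, inclusive (defaults 95
#'   and 320 nm).
#' @param binWidthNm histogram bin width (default 10 nm).
#' @param histRangeNm histogram range (default 90 to 320 nm).
#' @return a \linkS4class{FenestraeParams}.
#' @export
FenestraeParams <- function(dilationRadiusPx = 15L, blockSizePx = 51L,
                            thresholdOffset = 0.3, minPeakSeparationNm = 95,
                            dMinNm = 95, dMaxNm = 320, binWidthNm = 10,
                            histRangeNm = c(90, 320)) {
  new("FenestraeParams", upsampleFactor = 2L,
      dilationRadiusPx = as.integer(dilationRadiusPx),
      blockSizePx = as.integer(blockSizePx),
      thresholdOffset = as.numeric(thresholdOffset),
      minPeakSeparationNm = as.numeric(minPeakSeparationNm),
      dMinNm = as.numeric(dMinNm), dMaxNm = as.numeric(dMaxNm),
      binWidthNm = as.numeric(binWidthNm),
      histRangeNm = as.numeric(histRangeNm))
}

#' SizeHistogram: the binned fenestra diameter distribution
#'
#' Bins are half-open [low, high) except the last, which is closed.
#'
#' @slot binEdgesNm increasing bin edges in nm.
#' @slot counts nonnegative integer counts, one per bin.
#' @slot nTotal total number of binned records.
#' @slot modalBinLowerEdgeNm lower edge of the most populated bin
#'   (ties broken toward the smallest edge); NA when empty.
#' @slot tailDecayNm exponential decay length (nm) of a log-linear fit to
#'   nonzero bin counts from the modal bin upward; NA when fewer than 3
#'   nonzero bins are available.
#' @export
setClass("SizeHistogram",
  representation(binEdgesNm = "numeric", counts = "integer",
                 nTotal = "integer", modalBinLowerEdgeNm = "numeric",
                 tailDecayNm = "numeric"),
  validity = function(object) {
    if (length(object@counts) != length(object@binEdgesNm) - 1L)
      return("counts must have one entry per bin")
    if (any(diff(object@binEdgesNm) <= 0)) return("bin edges must increase")
    if (any(object@counts < 0L)) return("counts must be nonnegative")
    if (sum(object@counts) != object@nTotal)
      return("sum of counts must equal nTotal")
    TRUE
  })

#' OverlayImage: a source image plus a circle-annotation channel
#'
#' The source pixels are never modified; detections are drawn into a
#' separate binary annotation channel of the same (original-grid) shape.
#'
#' @slot source the annotated \linkS4class{PixelGrid2D}.
#' @slot annotation numeric matrix, 1 on drawn circle perimeters, 0
#'   elsewhere.
#' @slot nDrawn number of circles drawn (records whose centroid lay
#'   inside the image).
#' @export
setClass("OverlayImage",
  representation(source = "PixelGrid2D", annotation = "matrix",
                 nDrawn = "integer"),
  validity = function(object) {
    if (!identical(dim(object@annotation), dim(object@source@values)))
      return("annotation must match the source image shape")
    TRUE
  })

## ---- show methods ----

setMethod("show", "PixelGrid2D", function(object) {
  d <- dim(object@values)
  cat(sprintf("PixelGrid2D: %d x %d px, %.6g nm/px, range [%.4g, %.4g]\n",
              d[1], d[2], object@pixelSizeNm,
              min(object@values), max(object@values)))
})

setMethod("show", "SpectralAxis", function(object) {
  w <- object@wavenumbersCm1
  cat(sprintf("SpectralAxis: %d samples, %.6g - %.6g cm^-1\n",
              length(w), w[1], w[length(w)]))
})

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectralCube: %d x %d px, %d wavenumbers (%.6g - %.6g cm^-1), %.6g um/px\n",
              d[1], d[2], d[3], object@axis@wavenumbersCm1[1],
              object@axis@wavenumbersCm1[d[3]], object@pixelSizeUm))
})

setMethod("show", "AmplitudeMaps", function(object) {
  d <- dim(object@amplitudes)
  cat(sprintf("AmplitudeMaps: %d x %d px, peaks at %s cm^-1, mean residual RMS %.4g\n",
              d[1], d[2], paste(object@centersCm1, collapse = ", "),
              mean(object@residualRms)))
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@sinogram)
  st <- if (d[1] > 1) diff(object@anglesDeg[1:2]) else NA_real_
  cat(sprintf("ProjectionSet: %d angles (step %.4g deg) x %d detector bins, %.6g um/bin\n",
              d[1], st, d[2], object@detectorSpacingUm))
})

setMethod("show", "ReconSlice", function(object) {
  d <- dim(object@values)
  cat(sprintf("ReconSlice: %d x %d px, %.6g um/px\n", d[1], d[2],
              object@pixelSizeUm))
})

setMethod("show", "PhantomImage", function(object) {
  d <- dim(object@grid)
  cat(sprintf("PhantomImage: %d x %d px, %.6g um/px\n", d[1], d[2],
              object@pixelSizeUm))
})

setMethod("show", "SievePlateTruth", function(object) {
  cat(sprintf("SievePlateTruth: %d pores, %d x %d px at %.4g nm/px, PSF FWHM %.4g nm, noise '%s', seed %d\n",
              length(object@diametersNm), object@imageShape[1],
              object@imageShape[2], object@pixelSizeNm, object@psfFwhmNm,
              object@noiseModel, object@seed))
})

setMethod("show", "HsiTruth", function(object) {
  d <- dim(object@amp2845)
  cat(sprintf("HsiTruth: %d x %d px, peak FWHM %.4g cm^-1, noise SD %.4g, seed %d\n",
              d[1], d[2], object@peakFwhmCm1, object@noiseSd, object@seed))
})

setMethod("show", "FenestraeParams", function(object) {
  cat(sprintf(paste0("FenestraeParams: upsample x%d, dilation r=%d px, ",
                     "block %d px, offset %.4g, min sep %.4g nm, ",
                     "retain [%.4g, %.4g] nm\n"),
              object@upsampleFactor, object@dilationRadiusPx,
              object@blockSizePx, object@thresholdOffset,
              object@minPeakSeparationNm, object@dMinNm, object@dMaxNm))
})

setMethod("show", "SizeHistogram", function(object) {
  cat(sprintf("SizeHistogram: %d fenestrae in %d bins [%.4g, %.4g] nm; modal bin %s nm; tail decay %s nm\n",
              object@nTotal, length(object@counts), min(object@binEdgesNm),
              max(object@binEdgesNm),
              ifelse(is.na(object@modalBinLowerEdgeNm), "NA",
                     format(object@modalBinLowerEdgeNm)),
              ifelse(is.na(object@tailDecayNm), "NA",
                     format(signif(object@tailDecayNm, 4)))))
})

setMethod("show", "OverlayImage", function(object) {
  cat(sprintf("OverlayImage: %d circles drawn on %d x %d px image\n",
              object@nDrawn, nrow(object@annotation), ncol(object@annotation)))
})
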
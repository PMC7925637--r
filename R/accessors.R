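#' @describeIn PixelGrid2D intensity matrix.
#' @param x object to access.
#' @export
setMethod("pixelValues", "PixelGrid2D", function(x) x@values)

#' @describeIn ReconSlice reconstructed values.
#' @param x object to access.
#' @export
setMethod("pixelValues", "ReconSlice", function(x) x@values)

#' @describeIn PhantomImage phantom grid.
#' @param x object to access.
#' @export
setMethod("pixelValues", "PhantomImage", function(x) x@grid)

#' @describeIn SpectralCube the (rows, cols, K) data array.
#' @param x object to access.
#' @export
setMethod("pixelValues", "SpectralCube", function(x) x@values)

#' @describeIn PixelGrid2D pixel pitch in nm.
#' @export
setMethod("pixelSize", "PixelGrid2D", function(x) x@pixelSizeNm)

#' @describeIn ReconSlice pixel pitch in um.
#' @export
setMethod("pixelSize", "ReconSlice", function(x) x@pixelSizeUm)

#' @describeIn PhantomImage pixel pitch in um.
#' @export
setMethod("pixelSize", "PhantomImage", function(x) x@pixelSizeUm)

#' @describeIn SpectralCube pixel pitch in um.
#' @export
setMethod("pixelSize", "SpectralCube", function(x) x@pixelSizeUm)

#' @describeIn SpectralAxis the wavenumber grid.
#' @param x object to access.
#' @export
setMethod("wavenumbers", "SpectralAxis", function(x) x@wavenumbersCm1)

#' @describeIn SpectralCube the wavenumber grid of the cube's axis.
#' @export
setMethod("wavenumbers", "SpectralCube", function(x) x@axis@wavenumbersCm1)

#' @describeIn ProjectionSet the sinogram matrix.
#' @param x object to access.
#' @export
setMethod("sinogram", "ProjectionSet", function(x) x@sinogram)

#' @describeIn ProjectionSet projection angles in degrees.
#' @export
setMethod("projectionAngles", "ProjectionSet", function(x) x@anglesDeg)

#' @describeIn AmplitudeMaps fitted amplitude map of the peak at
#'   \code{center} cm^-1.
#' @param x object to access.
#' @param center peak center in cm^-1.
#' @export
setMethod("amplitudeMap", "AmplitudeMaps", function(x, center) {
  i <- match(center, x@centersCm1)
  if (is.na(i))
    stop("no fitted peak at ", center, " cm^-1; available: ",
         paste(x@centersCm1, collapse = ", "))
  x@amplitudes[, , i]
})

#' @describeIn AmplitudeMaps per-pixel baseline coefficients.
#' @export
setMethod("baselineMap", "AmplitudeMaps", function(x) x@baseline)

#' @describeIn AmplitudeMaps per-pixel residual RMS.
#' @export
setMethod("residualMap", "AmplitudeMaps", function(x) x@residualRms)

#' @describeIn SizeHistogram bin edges in nm.
#' @param x object to access.
#' @export
setMethod("binEdges", "SizeHistogram", function(x) x@binEdgesNm)

#' @describeIn SizeHistogram per-bin counts.
#' @export
setMethod("binCounts", "SizeHistogram", function(x) x@counts)

#' @describeIn SizeHistogram lower edge of the modal bin (nm).
#' @export
setMethod("modalBin", "SizeHistogram", function(x) x@modalBinLowerEdgeNm)

#' @describeIn SizeHistogram exponential tail-decay length (nm).
#' @export
setMethod("tailDecay", "SizeHistogram", function(x) x@tailDecayNm)

#' @describeIn SievePlateTruth n x 2 matrix of true (x, y) centers in nm.
#' @param x object to access.
#' @export
setMethod("trueCenters", "SievePlateTruth", function(x) x@centersNm)

#' @describeIn SievePlateTruth true diameters in nm.
#' @export
setMethod("trueDiameters", "SievePlateTruth", function(x) x@diametersNm)

#' Ground-truth pore table of a simulated sieve plate
#'
#' @param truth a \linkS4class{SievePlateTruth}.
#' @return data.frame with columns \code{x_nm}, \code{y_nm},
#'   \code{diameter_nm}, one row per rendered pore.
#' @export
truthTable <- function(truth) {
  stopifnot(is(truth, "SievePlateTruth"))
  data.frame(x_nm = truth@centersNm[, 1], y_nm = truth@centersNm[, 2],
             diameter_nm = truth@diametersNm)
}
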
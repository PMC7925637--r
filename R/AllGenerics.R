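#' @import methods
NULL

#' Pixel values of an image-like object
#'
#' @param x a \linkS4class{PixelGrid2D}, \linkS4class{ReconSlice},
#'   \linkS4class{PhantomImage} or \linkS4class{SpectralCube}.
#' @return a numeric matrix (or 3D array for a cube).
#' @export
setGeneric("pixelValues", function(x) standardGeneric("pixelValues"))

#' Physical pixel size
#'
#' Returns the pixel pitch of an image-like object in its native unit
#' (nm for super-resolution membrane images, um for OPT/CRS data).
#'
#' @param x an image-like object.
#' @return a positive numeric scalar.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Wavenumber axis of a spectral object
#'
#' @param x a \linkS4class{SpectralAxis} or \linkS4class{SpectralCube}.
#' @return strictly increasing numeric vector of wavenumbers (cm^-1).
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Sinogram matrix of a projection set
#'
#' @param x a \linkS4class{ProjectionSet}.
#' @return numeric matrix, one row per projection angle.
#' @export
setGeneric("sinogram", function(x) standardGeneric("sinogram"))

#' Projection angles in degrees
#'
#' @param x a \linkS4class{ProjectionSet}.
#' @return increasing numeric vector of angles (degrees).
#' @export
setGeneric("projectionAngles", function(x) standardGeneric("projectionAngles"))

#' Fitted peak-amplitude map
#'
#' @param x an \linkS4class{AmplitudeMaps} object.
#' @param center peak center in cm^-1 selecting the map (must match one of
#'   the fitted peak centers).
#' @return nonnegative numeric matrix of per-pixel peak amplitudes.
#' @export
setGeneric("amplitudeMap", function(x, center) standardGeneric("amplitudeMap"))

#' Fitted per-pixel baseline map
#'
#' @param x an \linkS4class{AmplitudeMaps} object.
#' @return numeric matrix of per-pixel constant-baseline coefficients.
#' @export
setGeneric("baselineMap", function(x) standardGeneric("baselineMap"))

#' Per-pixel residual RMS of the spectral fit
#'
#' @param x an \linkS4class{AmplitudeMaps} object.
#' @return nonnegative numeric matrix.
#' @export
setGeneric("residualMap", function(x) standardGeneric("residualMap"))

#' Histogram bin edges (nm)
#'
#' @param x a \linkS4class{SizeHistogram}.
#' @return increasing numeric vector of bin edges in nm.
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' Histogram bin counts
#'
#' @param x a \linkS4class{SizeHistogram}.
#' @return nonnegative integer vector, one count per bin.
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' Lower edge of the modal histogram bin (nm)
#'
#' @param x a \linkS4class{SizeHistogram}.
#' @return numeric scalar, or NA when the histogram is empty.
#' @export
setGeneric("modalBin", function(x) standardGeneric("modalBin"))

#' Exponential tail-decay constant of the size distribution (nm)
#'
#' @param x a \linkS4class{SizeHistogram}.
#' @return numeric scalar (nm), or NA when fewer than three nonzero bins
#'   lie at or above the modal bin.
#' @export
setGeneric("tailDecay", function(x) standardGeneric("tailDecay"))

#' True pore centers of a simulated sieve plate
#'
#' @param x a \linkS4class{SievePlateTruth}.
#' @return n x 2 numeric matrix of (x, y) positions in nm.
#' @export
setGeneric("trueCenters", function(x) standardGeneric("trueCenters"))

#' True pore diameters of a simulated sieve plate
#'
#' @param x a \linkS4class{SievePlateTruth}.
#' @return numeric vector of diameters in nm.
#' @export
setGeneric("trueDiameters", function(x) standardGeneric("trueDiameters"))
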
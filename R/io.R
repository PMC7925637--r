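## TIFF readers/writers with plain-text sidecar metadata, CSV export of
## fenestra records and histograms, and structured-text run configs.
##
## TIFF storage is 32-bit, single channel. The writer only represents
## the [0, 1] range (quantized at 2^-32), so intensities are divided by
## a power-of-two scale before writing and the scale is recorded in the
## sidecar (`<file>.meta`, key=value lines) together with pixel size and
## any axis/geometry metadata; round-trips are exact to ~2e-10 relative.
## Pixel sizes for user data must come from the sidecar or an explicit
## argument - never a silent default.

.sidecarPath <- function(path) paste0(path, ".meta")

.writeMeta <- function(path, fields) {
  writeLines(paste0(names(fields), "=", vapply(fields, function(x)
    format(x, digits = 17, scientific = FALSE), character(1))),
    .sidecarPath(path))
}

.readMeta <- function(path) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  ln <- readLines(sp, warn = FALSE)
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  out <- lapply(kv, function(x) paste(x[-1], collapse = "="))
  names(out) <- vapply(kv, `[[`, character(1), 1L)
  out
}

.powTwoScale <- function(mx) {
  if (mx <= 1) 1 else 2^ceiling(log2(mx))
}

## store (m - offset) / scale in [0, 1]; offset only when negatives occur
.writeFloatTiff <- function(m, path) {
  off <- min(m, 0)
  scale <- .powTwoScale(max(m - off, 0))
  suppressWarnings(tiff::writeTIFF((m - off) / scale, path,
                                   bits.per.sample = 32L, reduce = FALSE))
  list(scale = scale, offset = off)
}

.writeFloatTiffStack <- function(planes, path) {
  off <- min(vapply(planes, min, numeric(1)), 0)
  mx <- max(vapply(planes, max, numeric(1)) - off, 0)
  scale <- .powTwoScale(mx)
  suppressWarnings(tiff::writeTIFF(lapply(planes, function(p) (p - off) / scale),
                                   path, bits.per.sample = 32L, reduce = FALSE))
  list(scale = scale, offset = off)
}

#' Write a PixelGrid2D as a 32-bit TIFF with sidecar metadata
#'
#' @param img a \linkS4class{PixelGrid2D} with nonnegative values.
#' @param path output TIFF path; a `<path>.meta` sidecar holding pixel
#'   size and intensity scale is written next to it.
#' @return invisibly, the path.
#' @export
writePixelGrid <- function(img, path) {
  stopifnot(is(img, "PixelGrid2D"))
  sc <- .writeFloatTiff(img@values, path)
  .writeMeta(path, list(kind = "pixelgrid2d",
                        pixel_size_nm = img@pixelSizeNm, scale = sc$scale,
                        offset = sc$offset))
  invisible(path)
}

#' Read a 2D TIFF as a PixelGrid2D
#'
#' @param path TIFF path.
#' @param pixelSizeNm optional pixel size override in nm; wins over
#'   sidecar metadata. With neither, an error is raised - user data never
#'   gets a silent default pixel size.
#' @return a \linkS4class{PixelGrid2D}.
#' @export
readPixelGrid <- function(path, pixelSizeNm = NULL) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L && dim(m)[3] == 1L) m <- m[, , 1L]
  meta <- .readMeta(path)
  scale <- if (!is.null(meta$scale)) as.numeric(meta$scale) else 1
  off <- if (!is.null(meta$offset)) as.numeric(meta$offset) else 0
  px <- pixelSizeNm
  if (is.null(px) && !is.null(meta$pixel_size_nm))
    px <- as.numeric(meta$pixel_size_nm)
  if (is.null(px))
    stop("pixel size unknown: supply pixelSizeNm or provide sidecar metadata")
  PixelGrid2D(m * scale + off, px)
}

#' Write a SpectralCube as a multi-page 32-bit TIFF with sidecar
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param path output TIFF path (one page per wavenumber).
#' @return invisibly, the path.
#' @export
writeSpectralCube <- function(cube, path) {
  stopifnot(is(cube, "SpectralCube"))
  K <- dim(cube@values)[3]
  planes <- lapply(seq_len(K), function(k) cube@values[, , k])
  sc <- .writeFloatTiffStack(planes, path)
  w <- cube@axis@wavenumbersCm1
  .writeMeta(path, list(kind = "spectralcube",
                        axis_start_cm1 = w[1],
                        axis_step_cm1 = w[2] - w[1],
                        axis_count = length(w),
                        pixel_size_um = cube@pixelSizeUm, scale = sc$scale,
                        offset = sc$offset))
  invisible(path)
}

#' Read a multi-page TIFF as a SpectralCube
#'
#' @param path TIFF path.
#' @param axisStart,axisStep optional axis override (cm^-1): start and
#'   step of a uniform wavenumber grid matching the page count. Sidecar
#'   metadata is used when absent; with neither, an error is raised.
#' @param pixelSizeUm optional pixel-size override in um.
#' @return a \linkS4class{SpectralCube}.
#' @export
readSpectralCube <- function(path, axisStart = NULL, axisStep = NULL,
                             pixelSizeUm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- .readMeta(path)
  scale <- if (!is.null(meta$scale)) as.numeric(meta$scale) else 1
  off <- if (!is.null(meta$offset)) as.numeric(meta$offset) else 0
  if (is.null(axisStart) && !is.null(meta$axis_start_cm1)) {
    axisStart <- as.numeric(meta$axis_start_cm1)
    axisStep <- as.numeric(meta$axis_step_cm1)
  }
  if (is.null(axisStart) || is.null(axisStep))
    stop("spectral axis unknown: supply axisStart/axisStep or sidecar metadata")
  if (is.null(pixelSizeUm)) {
    if (is.null(meta$pixel_size_um))
      stop("pixel size unknown: supply pixelSizeUm or sidecar metadata")
    pixelSizeUm <- as.numeric(meta$pixel_size_um)
  }
  K <- length(pages)
  d <- dim(pages[[1]])
  cube <- array(0, c(d[1], d[2], K))
  for (k in seq_len(K)) cube[, , k] <- pages[[k]] * scale + off
  axis <- SpectralAxis(axisStart + axisStep * (0:(K - 1L)))
  SpectralCube(cube, axis, pixelSizeUm)
}

#' Write a ProjectionSet as a 32-bit TIFF sinogram with sidecar
#'
#' @param proj a \linkS4class{ProjectionSet}.
#' @param path output TIFF path (rows = angles, cols = detector bins).
#' @return invisibly, the path.
#' @export
writeProjectionSet <- function(proj, path) {
  stopifnot(is(proj, "ProjectionSet"))
  sc <- .writeFloatTiff(proj@sinogram, path)
  .writeMeta(path, list(kind = "projectionset",
                        start_deg = proj@anglesDeg[1],
                        step_deg = if (length(proj@anglesDeg) > 1)
                          diff(proj@anglesDeg[1:2]) else 0,
                        detector_spacing_um = proj@detectorSpacingUm,
                        scale = sc$scale, offset = sc$offset))
  invisible(path)
}

#' Read a TIFF sinogram as a ProjectionSet
#'
#' @param path TIFF path (rows = angles, cols = detector bins).
#' @param stepDeg optional angular step override (degrees).
#' @param detectorSpacingUm optional detector spacing override (um).
#' @param startDeg first angle (default 0 unless in the sidecar).
#' @return a \linkS4class{ProjectionSet}.
#' @export
readProjectionSet <- function(path, stepDeg = NULL, detectorSpacingUm = NULL,
                              startDeg = NULL) {
  m <- tiff::readTIFF(path)
  meta <- .readMeta(path)
  scale <- if (!is.null(meta$scale)) as.numeric(meta$scale) else 1
  off <- if (!is.null(meta$offset)) as.numeric(meta$offset) else 0
  if (is.null(stepDeg)) {
    if (is.null(meta$step_deg))
      stop("angular step unknown: supply stepDeg or sidecar metadata")
    stepDeg <- as.numeric(meta$step_deg)
  }
  if (is.null(startDeg))
    startDeg <- if (!is.null(meta$start_deg)) as.numeric(meta$start_deg) else 0
  if (is.null(detectorSpacingUm)) {
    if (is.null(meta$detector_spacing_um))
      stop("detector spacing unknown: supply detectorSpacingUm or sidecar metadata")
    detectorSpacingUm <- as.numeric(meta$detector_spacing_um)
  }
  ProjectionSet(m * scale + off,
                startDeg + stepDeg * (0:(nrow(m) - 1L)), detectorSpacingUm)
}

#' Load a TIFF as the matching analysis container
#'
#' Dispatch: a 2D file becomes a \linkS4class{PixelGrid2D} (with
#' \code{pixelSizeNm}) or a \linkS4class{ProjectionSet} (with
#' \code{stepDeg}); a multi-page file with an axis specification becomes
#' a \linkS4class{SpectralCube}. Sidecar metadata written by this
#' package's writers makes all arguments optional; explicit arguments
#' win over metadata. Missing pixel size or axis raises an error.
#'
#' @param path TIFF path.
#' @param pixelSizeNm pixel size override for 2D images (nm).
#' @param axisStart,axisStep spectral axis override (cm^-1).
#' @param stepDeg angular step override for sinograms (degrees).
#' @param detectorSpacingUm detector spacing override (um).
#' @param pixelSizeUm pixel size override for cubes (um).
#' @return a \linkS4class{PixelGrid2D}, \linkS4class{SpectralCube} or
#'   \linkS4class{ProjectionSet}.
#' @export
loadImage <- function(path, pixelSizeNm = NULL, axisStart = NULL,
                      axisStep = NULL, stepDeg = NULL,
                      detectorSpacingUm = NULL, pixelSizeUm = NULL) {
  meta <- .readMeta(path)
  kind <- meta$kind
  if (is.null(kind)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    kind <- if (length(pages) > 1L) {
      if (is.null(axisStart)) stop("multi-page TIFF needs axisStart/axisStep")
      "spectralcube"
    } else if (!is.null(stepDeg)) "projectionset"
    else "pixelgrid2d"
  }
  switch(kind,
    pixelgrid2d = readPixelGrid(path, pixelSizeNm = pixelSizeNm),
    spectralcube = readSpectralCube(path, axisStart = axisStart,
                                    axisStep = axisStep,
                                    pixelSizeUm = pixelSizeUm),
    projectionset = readProjectionSet(path, stepDeg = stepDeg,
                                      detectorSpacingUm = detectorSpacingUm),
    stop("unknown image kind '", kind, "'"))
}

## full-precision numeric formatting so CSV round-trips are bit-exact
.fmtNum <- function(x) {
  trimws(vapply(x, function(v) formatC(v, digits = 17, format = "g"),
                character(1)))
}

#' Save fenestra records and histogram as CSV files
#'
#' Writes `<prefix>_records.csv` (columns roi_id, cell_id, row_px,
#' col_px, area_px_upsampled, diameter_nm) and `<prefix>_histogram.csv`
#' (bin_low_nm, bin_high_nm, count). Numerics are written at full
#' precision, so reloading reproduces the records bit-exactly.
#'
#' @param records data.frame from \code{\link{measureFenestrae}}.
#' @param histogram a \linkS4class{SizeHistogram} (or NULL to skip).
#' @param pathPrefix output path prefix.
#' @return invisibly, a character vector of the written paths.
#' @export
saveRecords <- function(records, histogram = NULL, pathPrefix) {
  rp <- paste0(pathPrefix, "_records.csv")
  out <- data.frame(roi_id = records$roi_id, cell_id = records$cell_id,
                    row_px = .fmtNum(records$row_px),
                    col_px = .fmtNum(records$col_px),
                    area_px_upsampled = records$area_px_upsampled,
                    diameter_nm = .fmtNum(records$diameter_nm))
  utils::write.csv(out, rp, row.names = FALSE, quote = FALSE)
  paths <- rp
  if (!is.null(histogram)) {
    stopifnot(is(histogram, "SizeHistogram"))
    hp <- paste0(pathPrefix, "_histogram.csv")
    e <- histogram@binEdgesNm
    utils::write.csv(data.frame(bin_low_nm = e[-length(e)],
                                bin_high_nm = e[-1],
                                count = histogram@counts),
                     hp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, hp)
  }
  invisible(paths)
}

#' Reload fenestra records written by \code{saveRecords}
#'
#' @param path the `<prefix>_records.csv` file.
#' @return data.frame with the original column types.
#' @export
readRecords <- function(path) {
  df <- utils::read.csv(path, colClasses = c(roi_id = "character",
                                             cell_id = "character",
                                             row_px = "numeric",
                                             col_px = "numeric",
                                             area_px_upsampled = "integer",
                                             diameter_nm = "numeric"))
  df
}

#' Write a run configuration as a structured text file
#'
#' One key=value pair per line; every run log records the fully resolved
#' configuration including the seed, so any run is reproducible from its
#' log alone.
#'
#' @param config named list of scalar parameters; must include
#'   \code{seed}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeRunConfig <- function(config, path) {
  if (is.null(config$seed)) stop("config must record a seed")
  writeLines(paste0(names(config), "=", vapply(config, function(x)
    paste(format(x, digits = 17, scientific = FALSE), collapse = ","),
    character(1))), path)
  invisible(path)
}

#' Read a structured-text run configuration
#'
#' @param path config path written by \code{\link{writeRunConfig}} (or
#'   hand-written key=value lines).
#' @return named list of character values (callers coerce as needed).
#' @export
readRunConfig <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  out <- lapply(kv, function(x) paste(x[-1], collapse = "="))
  names(out) <- vapply(kv, `[[`, character(1), 1L)
  out
}
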
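#' Save / load a B-scan series
#'
#' A series is written into a directory as either a multi-page TIFF
#' (`frames.tif`, 8- or 16-bit grayscale) or a directory of numbered PNG
#' frames (`frames/frame_NNNN.png`, 8-bit), always with a JSON metadata
#' sidecar `meta.json` carrying fps, pixel pitch, source id and frame
#' geometry. Loading a saved series reproduces the quantized intensities
#' bit-exactly and the metadata exactly.
#'
#' @param series a [BScanSeries-class].
#' @param path directory to write into (created if needed).
#' @param format `"tiff"` (default) or `"png"`.
#' @param bits bits per sample for TIFF output (8 or 16).
#' @return `saveSeries()` returns `path` invisibly; `loadSeries()` returns
#'   a [BScanSeries-class].
#' @examples
#' cfg <- phantomConfig(imageHeightPx = 32, imageWidthPx = 32)
#' s <- generatePhantomSeries(cfg, airJetProtocol(0.2, 0.2, 0.2))$series
#' d <- file.path(tempdir(), "series-example")
#' saveSeries(s, d)
#' s2 <- loadSeries(d)
#' @export
saveSeries <- function(series, path, format = c("tiff", "png"), bits = 16L) {
  stopifnot(is(series, "BScanSeries"))
  format <- match.arg(format)
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fr <- series@frames
  nF <- dim(fr)[3L]
  if (format == "tiff") {
    pages <- lapply(seq_len(nF), function(k) fr[, , k])
    tiff::writeTIFF(pages, file.path(path, "frames.tif"),
                    bits.per.sample = bits)
  } else {
    fd <- file.path(path, "frames")
    dir.create(fd, showWarnings = FALSE)
    for (k in seq_len(nF)) {
      png::writePNG(fr[, , k], file.path(fd, sprintf("frame_%04d.png", k)))
    }
  }
  meta <- list(
    source_id = series@sourceId, fps = series@fps,
    axial_pitch_um = series@axialPitchUm,
    lateral_pitch_um = series@lateralPitchUm,
    n_frames = nF, height_px = dim(fr)[1L], width_px = dim(fr)[2L],
    format = format, bits = as.integer(if (format == "png") 8L else bits)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveSeries
#' @export
loadSeries <- function(path) {
  metaPath <- file.path(path, "meta.json")
  if (!file.exists(metaPath)) {
    stop(sprintf("format error: missing metadata sidecar '%s'", metaPath))
  }
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  for (f in c("fps", "axial_pitch_um", "lateral_pitch_um")) {
    if (is.null(meta[[f]])) {
      stop(sprintf("format error: sidecar missing field '%s'", f))
    }
  }
  tifPath <- file.path(path, "frames.tif")
  if (file.exists(tifPath)) {
    pages <- tiff::readTIFF(tifPath, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else {
    fd <- file.path(path, "frames")
    files <- sort(list.files(fd, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("format error: no frames.tif or frames/*.png found")
    pages <- lapply(files, png::readPNG)
  }
  pages <- lapply(pages, toGrayscale)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("format error: frames have inconsistent shapes")
  }
  d <- dim(pages[[1L]])
  fr <- array(unlist(pages, use.names = FALSE), dim = c(d, length(pages)))
  new("BScanSeries",
    frames = fr, fps = as.numeric(meta$fps),
    axialPitchUm = as.numeric(meta$axial_pitch_um),
    lateralPitchUm = as.numeric(meta$lateral_pitch_um),
    sourceId = as.character(meta$source_id %||% "series")
  )
}

#' Save / load a stack of binary masks
#'
#' Masks are written as a multi-page 8-bit TIFF of \{0,1\} bytes parallel
#' to the frame stack they belong to.
#'
#' @param masks an `H x W x T` array (or `H x W` matrix) of 0/1 values.
#' @param path file path of the TIFF to write/read.
#' @return `loadMaskStack()` returns an integer `H x W x T` array.
#' @export
saveMaskStack <- function(masks, path) {
  if (is.matrix(masks)) masks <- array(masks, dim = c(dim(masks), 1L))
  stopifnot(length(dim(masks)) == 3L, all(masks %in% c(0, 1)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(seq_len(dim(masks)[3L]), function(k) masks[, , k] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname saveMaskStack
#' @export
loadMaskStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, toGrayscale)
  d <- dim(pages[[1L]])
  arr <- array(as.integer(unlist(pages) > 0.5), dim = c(d, length(pages)))
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
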
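#' Convert a frame to grayscale
#'
#' Three-channel (channels-last) rasters are reduced with the Rec.601
#' luminance weights 0.299/0.587/0.114; already-gray frames are returned
#' unchanged. Intensities stay in `[0, 1]`.
#'
#' @param frame an `H x W` matrix, an `H x W x 1` or an `H x W x 3` array.
#' @return an `H x W` matrix.
#' @examples
#' toGrayscale(array(0.5, c(4, 4, 3)))[1, 1]  # 0.5
#' @export
toGrayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  d <- dim(frame)
  if (length(d) == 3L && d[3] == 1L) return(frame[, , 1L])
  if (length(d) == 3L && d[3] == 3L) {
    return(0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L])
  }
  stop("format error: frame must be 2-D or have 1 or 3 channels (channels last)")
}

#' Centre crop to a square window
#'
#' Extracts a `sizePx x sizePx` window centred on the frame; when the
#' margin is odd the extra row/column is dropped from the bottom/right.
#' Frames smaller than the window are an error (no padding).
#'
#' @param frame an `H x W` matrix with both dimensions `>= sizePx`.
#' @param sizePx side length of the crop (default 997, the standard square
#'   used on real scans).
#' @return a `sizePx x sizePx` matrix.
#' @examples
#' dim(cropCenter(matrix(0, 1200, 1100), 997))
#' @export
cropCenter <- function(frame, sizePx = 997L) {
  stopifnot(is.matrix(frame))
  sizePx <- as.integer(sizePx)
  if (sizePx < 1L) stop("sizePx must be positive")
  d <- dim(frame)
  if (any(d < sizePx)) {
    stop(sprintf(
      "dimension error: frame %d x %d smaller than crop size %d",
      d[1], d[2], sizePx
    ))
  }
  r0 <- (d[1] - sizePx) %/% 2L
  c0 <- (d[2] - sizePx) %/% 2L
  frame[r0 + seq_len(sizePx), c0 + seq_len(sizePx), drop = FALSE]
}

#' Gaussian denoising with reflective boundaries
#'
#' Separable 2-D Gaussian convolution with symmetric (reflective) boundary
#' handling. `sigmaPx = 0` is the identity; constant frames are fixed
#' points for any sigma.
#'
#' @param frame an `H x W` matrix.
#' @param sigmaPx Gaussian standard deviation in pixels (>= 0, default 1).
#' @return the smoothed `H x W` matrix.
#' @examples
#' f <- matrix(rnorm(64^2), 64, 64)
#' var(as.vector(gaussianDenoise(f, 2))) < var(as.vector(f))
#' @export
gaussianDenoise <- function(frame, sigmaPx = 1) {
  stopifnot(is.matrix(frame))
  if (sigmaPx < 0) stop("sigmaPx must be >= 0")
  if (sigmaPx == 0) return(frame)
  r <- max(1L, as.integer(ceiling(3 * sigmaPx)))
  kern <- stats::dnorm(seq(-r, r), sd = sigmaPx)
  kern <- kern / sum(kern)
  out <- .convolveReflect(frame, kern, margin = 1L)
  .convolveReflect(out, kern, margin = 2L)
}

# 1-D convolution along rows (margin 1) or columns (margin 2) with
# half-sample symmetric padding (d c b a | a b c d | d c b a).
.convolveReflect <- function(m, kern, margin) {
  r <- (length(kern) - 1L) %/% 2L
  n <- dim(m)[margin]
  p <- ((1L - r):(n + r) - 1L) %% (2L * n)   # fold positions into one period
  pad <- ifelse(p < n, p + 1L, 2L * n - p)
  if (margin == 1L) {
    mp <- m[pad, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kern)) {
      out <- out + kern[j] * mp[j + seq_len(n) - 1L, , drop = FALSE]
    }
  } else {
    mp <- m[, pad, drop = FALSE]
    out <- matrix(0, nrow(m), n)
    for (j in seq_along(kern)) {
      out <- out + kern[j] * mp[, j + seq_len(n) - 1L, drop = FALSE]
    }
  }
  out
}

#' Run the image-conditioning chain over a series
#'
#' Applies grayscale conversion (a no-op for already-gray stacks), an
#' optional centre crop and Gaussian denoising to every frame of a
#' [BScanSeries-class]. The chain is deterministic.
#'
#' @param series a [BScanSeries-class].
#' @param cropPx side of the centre crop, or `NULL` to skip cropping.
#' @param sigmaPx Gaussian sigma in pixels (0 skips smoothing).
#' @return the processed [BScanSeries-class].
#' @export
preprocessSeries <- function(series, cropPx = NULL, sigmaPx = 1) {
  stopifnot(is(series, "BScanSeries"))
  fr <- series@frames
  nF <- dim(fr)[3L]
  first <- fr[, , 1L]
  if (!is.null(cropPx)) first <- cropCenter(first, cropPx)
  out <- array(0, dim = c(dim(first), nF))
  for (k in seq_len(nF)) {
    f <- fr[, , k]
    if (!is.null(cropPx)) f <- cropCenter(f, cropPx)
    f <- gaussianDenoise(f, sigmaPx)
    out[, , k] <- pmin(pmax(f, 0), 1)
  }
  new("BScanSeries",
    frames = out, fps = series@fps, axialPitchUm = series@axialPitchUm,
    lateralPitchUm = series@lateralPitchUm, sourceId = series@sourceId
  )
}
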
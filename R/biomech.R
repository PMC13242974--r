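#' Extract the central A-scan of a frame
#'
#' Returns the middle column of a B-scan — the axial intensity profile on
#' the jet axis. For even widths the left-of-centre column is used.
#'
#' @param frame an `H x W` matrix with `W >= 1`.
#' @return a numeric vector of length `H`.
#' @examples
#' extractCenterline(matrix(1:12, 3, 4))
#' @export
extractCenterline <- function(frame) {
  stopifnot(is.matrix(frame))
  if (ncol(frame) < 1L || nrow(frame) < 1L) stop("dimension error: empty frame")
  frame[, (ncol(frame) + 1L) %/% 2L]
}

#' Composite axial profile over a frame window
#'
#' Element-wise mean of the central A-scans of the frames in `frameWindow`,
#' the averaged depth-profile representation used to visualize the
#' indentation response.
#'
#' @param series a [BScanSeries-class].
#' @param frameWindow integer vector of frame indices (non-empty).
#' @return a numeric vector of length `H`.
#' @export
compositeProfile <- function(series, frameWindow = seq_len(nFrames(series))) {
  stopifnot(is(series, "BScanSeries"))
  if (!length(frameWindow)) stop("domain error: empty frame window")
  if (any(frameWindow < 1L | frameWindow > nFrames(series))) {
    stop("domain error: frame window out of range")
  }
  prof <- vapply(frameWindow, function(k) extractCenterline(series@frames[, , k]),
                 numeric(dim(series@frames)[1L]))
  rowMeans(as.matrix(prof))
}

#' Track the depth of the segmented layer over time
#'
#' Reduces each per-frame mask to a scalar depth within a central lateral
#' band (default the central 10% of columns): `mask_centroid` takes the
#' mean row of mask pixels in the band (the centre of the segmented skin
#' location), `top_boundary` the minimum row. Depths are pixel-centre
#' depths, `(row - 0.5) *` axial pitch.
#'
#' @param series a [BScanSeries-class].
#' @param masks `H x W x T` array of 0/1 masks, one page per frame.
#' @param landmark `"mask_centroid"` (default) or `"top_boundary"`.
#' @param centralFraction width of the central band as a fraction of the
#'   image width (default 0.1).
#' @return a [DepthTrace-class].
#' @export
trackDepth <- function(series, masks, landmark = c("mask_centroid", "top_boundary"),
                       centralFraction = 0.1) {
  stopifnot(is(series, "BScanSeries"))
  landmark <- match.arg(landmark)
  if (is.matrix(masks)) masks <- array(masks, dim = c(dim(masks), 1L))
  d <- dim(series@frames)
  if (!identical(dim(masks), d)) {
    stop(sprintf(
      "dimension error: mask stack %s does not match frames %s",
      paste(dim(masks), collapse = "x"), paste(d, collapse = "x")
    ))
  }
  W <- d[2L]
  half <- max(1L, floor(W * centralFraction / 2))
  jc <- (W + 1L) %/% 2L
  band <- max(1L, jc - half):min(W, jc + half)
  apMm <- series@axialPitchUm / 1000
  nF <- d[3L]
  depth <- numeric(nF)
  for (k in seq_len(nF)) {
    sub <- masks[, band, k, drop = FALSE]
    rows <- which(sub == 1L, arr.ind = TRUE)[, 1L]
    if (!length(rows)) {
      stop(sprintf("tracking error: empty central-band mask in frame %d", k))
    }
    r <- if (landmark == "mask_centroid") mean(rows) else min(rows)
    depth[k] <- (r - 0.5) * apMm
  }
  new("DepthTrace",
    tS = (seq_len(nF) - 1) / series@fps, depthMm = depth, landmark = landmark
  )
}

#' Displacement over the indentation protocol
#'
#' Baseline depth is the mean tracked depth over the pre-pressure window;
#' maximum depth is the per-frame maximum over the pressure-on window
#' (optionally after a 3-frame running median that suppresses single-frame
#' tracking outliers); displacement is their difference, floored at zero.
#'
#' @param trace a [DepthTrace-class] spanning the full protocol.
#' @param protocol an [AirJetProtocol-class].
#' @param smooth `"none"` (default) or `"median3"`.
#' @return a list with `baselineMm`, `maxMm` and `deltaDMm`.
#' @export
displacement <- function(trace, protocol, smooth = c("none", "median3")) {
  stopifnot(is(trace, "DepthTrace"), is(protocol, "AirJetProtocol"))
  smooth <- match.arg(smooth)
  total <- protocol@preS + protocol@onS + protocol@postS
  if (max(trace@tS) < protocol@preS + protocol@onS - 1e-9) {
    stop("domain error: trace shorter than the protocol's on-window")
  }
  d <- trace@depthMm
  if (smooth == "median3" && length(d) >= 3L) {
    d <- stats::runmed(d, 3L, endrule = "keep")
  }
  pre <- trace@tS < protocol@preS
  on <- trace@tS >= protocol@preS & trace@tS < protocol@preS + protocol@onS
  if (!any(pre) || !any(on)) {
    stop("domain error: trace does not cover both pre and on windows")
  }
  baseline <- mean(d[pre])
  maxDepth <- max(d[on])
  list(
    baselineMm = baseline, maxMm = maxDepth,
    deltaDMm = max(0, maxDepth - baseline)
  )
}

#' Structural stiffness coefficient K = F / delta-d
#'
#' The ratio of applied force to induced displacement, the
#' geometry-inclusive stiffness measure used for layered tissue. A
#' non-positive displacement has no defined stiffness and is an error
#' rather than an infinity.
#'
#' @param forceN applied force in newtons (>= 0).
#' @param deltaDMm displacement in millimetres (> 0).
#' @param baselineDepthMm,maxDepthMm optional depths carried through into
#'   the result.
#' @return a [StiffnessResult-class].
#' @examples
#' stiffness(0.5, 0.5)  # K = 1 N/mm
#' @export
stiffness <- function(forceN, deltaDMm, baselineDepthMm = NA_real_,
                      maxDepthMm = NA_real_) {
  if (forceN < 0) stop("domain error: force must be >= 0")
  if (!is.finite(deltaDMm) || deltaDMm <= 0) {
    stop("undefined-stiffness error: displacement must be > 0")
  }
  new("StiffnessResult",
    forceN = forceN, deltaDMm = deltaDMm, kNPerMm = forceN / deltaDMm,
    baselineDepthMm = baselineDepthMm, maxDepthMm = maxDepthMm
  )
}

#' Quantify stiffness for a series + mask stack
#'
#' Convenience wrapper chaining [trackDepth()], [displacement()],
#' [jetForce()] and [stiffness()].
#'
#' @param series a [BScanSeries-class].
#' @param masks `H x W x T` 0/1 mask stack.
#' @param protocol an [AirJetProtocol-class].
#' @param landmark,smooth passed to [trackDepth()] / [displacement()].
#' @return a [StiffnessResult-class].
#' @export
quantifyStiffness <- function(series, masks, protocol,
                              landmark = "mask_centroid", smooth = "none") {
  trace <- trackDepth(series, masks, landmark)
  disp <- displacement(trace, protocol, smooth)
  stiffness(jetForce(protocol), disp$deltaDMm,
            baselineDepthMm = disp$baselineMm, maxDepthMm = disp$maxMm)
}
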
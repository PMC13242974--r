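#' Construct a phantom configuration
#'
#' Builds a validated [PhantomConfig-class]. Defaults mirror the OCT
#' acquisition geometry (7.5 um axial and 10 um lateral pitch, 10 fps) on a
#' desk-scale 512 x 512 raster; the full 997 x 997 raster used on real
#' scans is supported by setting the size explicitly.
#'
#' @param imageHeightPx,imageWidthPx raster size in pixels.
#' @param axialPitchUm,lateralPitchUm pixel pitch in micrometres.
#' @param fps frame rate (frames per second).
#' @param scTopDepthMm resting depth of the stratum-corneum upper boundary.
#' @param scThicknessMm thickness of the stratum-corneum band, mm.
#' @param nDeeperLayers number of tissue layers below the SC band; the
#'   remaining imaged depth is split equally among them.
#' @param layerContrasts mean intensities in `[0,1]`; first element is the
#'   SC band, the rest the deeper layers.
#' @param airIntensity mean intensity of the air gap above the surface.
#' @param speckleContrast SD/mean of the multiplicative gamma speckle.
#' @param attenuationPerMm exponential attenuation below the surface.
#' @param indentSigmaMm lateral Gaussian width of the pressure dent, mm.
#' @param kTrueNPerMm ground-truth structural stiffness, N/mm.
#' @param seed integer seed for the speckle noise.
#' @return a [PhantomConfig-class] object.
#' @examples
#' cfg <- phantomConfig(imageHeightPx = 64, imageWidthPx = 64)
#' @export
phantomConfig <- function(imageHeightPx = 512L, imageWidthPx = 512L,
                          axialPitchUm = 7.5, lateralPitchUm = 10,
                          fps = 10, scTopDepthMm = 0.2, scThicknessMm = 0.15,
                          nDeeperLayers = 2L,
                          layerContrasts = c(0.85, 0.45, 0.30),
                          airIntensity = 0.03, speckleContrast = 0.3,
                          attenuationPerMm = 0.8, indentSigmaMm = 1.0,
                          kTrueNPerMm = 1.0, seed = 1L) {
  new("PhantomConfig",
    imageHeightPx = as.integer(imageHeightPx),
    imageWidthPx = as.integer(imageWidthPx),
    axialPitchUm = axialPitchUm, lateralPitchUm = lateralPitchUm,
    fps = fps, scTopDepthMm = scTopDepthMm, scThicknessMm = scThicknessMm,
    nDeeperLayers = as.integer(nDeeperLayers),
    layerContrasts = layerContrasts, airIntensity = airIntensity,
    speckleContrast = speckleContrast, attenuationPerMm = attenuationPerMm,
    indentSigmaMm = indentSigmaMm, kTrueNPerMm = kTrueNPerMm,
    seed = as.integer(seed)
  )
}

#' Construct an air-jet protocol
#'
#' @param preS,onS,postS window durations in seconds (default 5/5/5).
#' @param pressurePa gauge pressure of the jet in pascals.
#' @param nozzleDiameterMm bore diameter of the air port (default 2 mm).
#' @return an [AirJetProtocol-class] object.
#' @examples
#' airJetProtocol(pressurePa = 1e5)
#' @export
airJetProtocol <- function(preS = 5, onS = 5, postS = 5,
                           pressurePa = 5e4, nozzleDiameterMm = 2) {
  new("AirJetProtocol",
    preS = preS, onS = onS, postS = postS,
    pressurePa = pressurePa, nozzleDiameterMm = nozzleDiameterMm
  )
}

#' Analytic surface-displacement waveform of the indentation protocol
#'
#' Displacement of the tissue surface at the jet centre as a function of
#' time: zero throughout the pre-pressure baseline, a smoothstep rise over
#' `rampS` seconds to a plateau of `deltaMaxMm` during the pressure-on
#' window, and a symmetric smoothstep decay back to zero at the start of
#' the recovery window.
#'
#' @param tS time(s) in seconds; must lie within `[0, preS + onS + postS]`.
#' @param protocol an [AirJetProtocol-class].
#' @param deltaMaxMm plateau displacement in millimetres (>= 0).
#' @param rampS ramp duration in seconds (default 0.5).
#' @return displacement in millimetres, same length as `tS`.
#' @examples
#' p <- airJetProtocol()
#' displacementWaveform(7.5, p, deltaMaxMm = 0.5)  # plateau -> 0.5
#' @export
displacementWaveform <- function(tS, protocol, deltaMaxMm, rampS = 0.5) {
  stopifnot(is(protocol, "AirJetProtocol"))
  if (deltaMaxMm < 0) stop("deltaMaxMm must be >= 0")
  if (rampS <= 0) stop("rampS must be > 0")
  total <- protocol@preS + protocol@onS + protocol@postS
  if (any(tS < 0 | tS > total)) {
    stop(sprintf("time out of protocol range [0, %g] s", total))
  }
  smoothstep <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    u * u * (3 - 2 * u)
  }
  up <- smoothstep((tS - protocol@preS) / rampS)
  down <- smoothstep((tS - protocol@preS - protocol@onS) / rampS)
  deltaMaxMm * (up - down)
}

#' Applied force of the air jet
#'
#' Force transmitted by the jet, computed as gauge pressure times the
#' nozzle bore area: `F = p * pi * (d/2)^2`, with the 2 mm bore giving
#' 0.3142 N at 100 kPa.
#'
#' @param protocol an [AirJetProtocol-class], or a gauge pressure in
#'   pascals when `nozzleDiameterMm` is also given.
#' @param nozzleDiameterMm nozzle bore in millimetres (scalar form only).
#' @return force in newtons.
#' @examples
#' jetForce(1e5, 2)  # 0.3142 N
#' @export
jetForce <- function(protocol, nozzleDiameterMm = NULL) {
  if (is(protocol, "AirJetProtocol")) {
    p <- protocol@pressurePa
    d <- protocol@nozzleDiameterMm
  } else {
    p <- protocol
    d <- nozzleDiameterMm
    if (is.null(d)) stop("nozzleDiameterMm required with a scalar pressure")
  }
  if (p < 0) stop("pressure must be >= 0")
  p * pi * (d / 2000)^2
}

#' Generate a synthetic deforming B-scan series with ground truth
#'
#' Renders a layered, speckled phantom B-scan time series under the given
#' air-jet protocol. Each frame stacks a dark air gap, a bright thin
#' stratum-corneum (SC) band and deeper layers of decreasing contrast,
#' with exponential depth attenuation and unit-mean multiplicative gamma
#' speckle. During the pressure-on window the whole layer stack is
#' translated downward by the analytic waveform scaled by a Gaussian
#' lateral envelope centred on the jet axis; the central-column plateau
#' displacement equals `F / K_true`. The same config and seed always
#' reproduce the identical series.
#'
#' @param config a [PhantomConfig-class].
#' @param protocol an [AirJetProtocol-class].
#' @param sourceId identifier stored in the returned series.
#' @return a list with elements `series` ([BScanSeries-class]) and
#'   `truth` ([PhantomTruth-class]).
#' @examples
#' cfg <- phantomConfig(imageHeightPx = 64, imageWidthPx = 64, seed = 7)
#' out <- generatePhantomSeries(cfg, airJetProtocol(1, 1, 1, pressurePa = 2e4))
#' out$truth
#' @export
generatePhantomSeries <- function(config, protocol, sourceId = "phantom") {
  stopifnot(is(config, "PhantomConfig"), is(protocol, "AirJetProtocol"))
  H <- config@imageHeightPx
  W <- config@imageWidthPx
  apMm <- config@axialPitchUm / 1000
  lpMm <- config@lateralPitchUm / 1000
  depthMm <- H * apMm
  forceN <- jetForce(protocol)
  deltaMax <- if (config@kTrueNPerMm > 0) forceN / config@kTrueNPerMm else 0
  if (config@scTopDepthMm + config@scThicknessMm + deltaMax >= depthMm) {
    stop(sprintf(
      "configuration error: indentation budget exceeded (sc_top %.3g + sc_thickness %.3g + delta_max %.3g mm >= imaged depth %.3g mm)",
      config@scTopDepthMm, config@scThicknessMm, deltaMax, depthMm
    ))
  }
  total <- protocol@preS + protocol@onS + protocol@postS
  nF <- as.integer(floor(config@fps * total))
  tS <- (seq_len(nF) - 1) / config@fps

  # layer boundaries at rest (mm): air | SC | deeper layers to the bottom
  b0 <- config@scTopDepthMm
  b1 <- b0 + config@scThicknessMm
  bounds <- c(b0, b1)
  if (config@nDeeperLayers > 0L) {
    thick <- (depthMm - b1) / config@nDeeperLayers
    bounds <- c(bounds, b1 + thick * seq_len(config@nDeeperLayers - 1L))
  }
  meanIntensity <- c(config@airIntensity, config@layerContrasts)

  z <- (seq_len(H) - 0.5) * apMm                    # pixel-centre depths
  x <- (seq_len(W) - (W + 1) / 2) * lpMm            # lateral offset from centre
  envelope <- exp(-x^2 / (2 * config@indentSigmaMm^2))
  jc <- (W + 1L) %/% 2L                             # central column

  shape <- if (config@speckleContrast > 0) 1 / config@speckleContrast^2 else Inf
  set.seed(config@seed)

  framesArr <- array(0, dim = c(H, W, nF))
  masksArr <- array(0L, dim = c(H, W, nF))
  boundaryDepth <- numeric(nF)
  delta <- displacementWaveform(tS, protocol, deltaMax)

  for (k in seq_len(nF)) {
    shift <- delta[k] * envelope
    zz <- outer(z, shift, `-`)                      # depth in the resting frame
    lay <- findInterval(zz, bounds)                 # 0 = air, 1 = SC, ...
    img <- matrix(meanIntensity[lay + 1L], H, W)
    att <- exp(-config@attenuationPerMm * pmax(zz - b0, 0))
    img <- img * att
    if (is.finite(shape)) {
      img <- img * matrix(stats::rgamma(H * W, shape = shape, rate = shape), H, W)
    }
    framesArr[, , k] <- pmin(pmax(img, 0), 1)
    masksArr[, , k] <- (lay == 1L) * 1L
    top <- which(masksArr[, jc, k] == 1L)
    boundaryDepth[k] <- if (length(top)) (min(top) - 0.5) * apMm else NA_real_
  }

  series <- new("BScanSeries",
    frames = framesArr, fps = config@fps,
    axialPitchUm = config@axialPitchUm,
    lateralPitchUm = config@lateralPitchUm, sourceId = sourceId
  )
  truth <- new("PhantomTruth",
    boundaryDepthMm = boundaryDepth, masks = masksArr,
    deltaDTrueMm = deltaMax, kTrueNPerMm = config@kTrueNPerMm,
    forceN = forceN
  )
  list(series = series, truth = truth)
}

#' Generate a frame-level phantom segmentation dataset
#'
#' Convenience generator for segmentation experiments: renders `nSeries`
#' phantom series ("patients") with varied layer geometry, contrast,
#' speckle and stiffness, then samples `framesPerSeries` evenly spaced
#' frames from each so the dataset covers the whole deformation range.
#'
#' @param nSeries number of phantom series (treated as patients).
#' @param framesPerSeries frames sampled per series.
#' @param imageSizePx side length of the square frames.
#' @param protocol an [AirJetProtocol-class]; default 5/5/5 s at 50 kPa.
#' @param seed integer seed controlling all per-series parameters.
#' @return a list with `images` (named list of `H x W` matrices), `masks`
#'   (named list of 0/1 matrices), `patientOf` (named character vector
#'   mapping frame id to series id), and `configs` (per-series
#'   [PhantomConfig-class] objects).
#' @examples
#' ds <- generatePhantomDataset(nSeries = 2, framesPerSeries = 3,
#'                              imageSizePx = 64, seed = 1,
#'                              protocol = airJetProtocol(pressurePa = 1e4))
#' length(ds$images)
#' @export
generatePhantomDataset <- function(nSeries = 10L, framesPerSeries = 20L,
                                   imageSizePx = 128L,
                                   protocol = airJetProtocol(pressurePa = 5e4),
                                   seed = 1L) {
  set.seed(seed)
  depthMm <- imageSizePx * 7.5 / 1000
  images <- list()
  masks <- list()
  patientOf <- character()
  configs <- vector("list", nSeries)
  for (s in seq_len(nSeries)) {
    kTrue <- stats::runif(1, 0.5, 2.5)
    cfg <- phantomConfig(
      imageHeightPx = imageSizePx, imageWidthPx = imageSizePx,
      scTopDepthMm = stats::runif(1, 0.10, 0.20) * depthMm / 0.96,
      scThicknessMm = stats::runif(1, 0.08, 0.16) * depthMm / 0.96,
      layerContrasts = c(
        stats::runif(1, 0.7, 0.95),
        stats::runif(1, 0.35, 0.55),
        stats::runif(1, 0.2, 0.35)
      ),
      airIntensity = stats::runif(1, 0.01, 0.05),
      speckleContrast = stats::runif(1, 0.2, 0.4),
      attenuationPerMm = stats::runif(1, 0.5, 1.2),
      indentSigmaMm = stats::runif(1, 0.6, 1.2),
      kTrueNPerMm = kTrue,
      seed = seed + 1000L + s
    )
    configs[[s]] <- cfg
    out <- generatePhantomSeries(cfg, protocol, sourceId = sprintf("ph%02d", s))
    nF <- nFrames(out$series)
    pick <- unique(round(seq(1, nF, length.out = framesPerSeries)))
    for (j in seq_along(pick)) {
      id <- sprintf("ph%02d_f%03d", s, pick[j])
      images[[id]] <- out$series@frames[, , pick[j]]
      masks[[id]] <- out$truth@masks[, , pick[j]]
      patientOf[id] <- sprintf("ph%02d", s)
    }
  }
  list(images = images, masks = masks, patientOf = patientOf, configs = configs)
}
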
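#' @import methods
NULL

## Depth-axis convention, used everywhere in the package:
## row 1 of a frame is the shallowest pixel, depth increases with row
## index, and indentation moves tissue toward larger row indices.

#' BScanSeries: a time-ordered stack of OCT B-scan frames
#'
#' Container for a grayscale OCT B-scan time series together with its
#' acquisition metadata. Frames are stored as an `height x width x n_frames`
#' numeric array with intensities in `[0, 1]`; row 1 is the shallowest
#' (closest to the probe) pixel.
#'
#' @slot frames numeric array, `H x W x T`, intensities in `[0, 1]`.
#' @slot fps frames per second (positive).
#' @slot axialPitchUm axial (depth, row) pixel pitch in micrometres.
#' @slot lateralPitchUm lateral (column) pixel pitch in micrometres.
#' @slot sourceId identifier of the imaged subject or phantom.
#'
#' @seealso [generatePhantomSeries()], [loadSeries()], [saveSeries()]
#' @export
setClass("BScanSeries",
  representation(
    frames = "array",
    fps = "numeric",
    axialPitchUm = "numeric",
    lateralPitchUm = "numeric",
    sourceId = "character"
  )
)

setValidity("BScanSeries", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be an H x W x T array")
  if (length(d) == 3L && any(d < 1L)) msg <- c(msg, "frames must be non-empty")
  rng <- suppressWarnings(range(object@frames))
  if (!all(is.finite(object@frames))) {
    msg <- c(msg, "frame intensities must be finite")
  } else if (rng[1] < 0 || rng[2] > 1) {
    msg <- c(msg, "frame intensities must lie in [0, 1]")
  }
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0) {
    msg <- c(msg, "fps must be a single positive number")
  }
  for (s in c("axialPitchUm", "lateralPitchUm")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      msg <- c(msg, paste(s, "must be a single positive number"))
    }
  }
  if (length(object@sourceId) != 1L) msg <- c(msg, "sourceId must be a single string")
  if (length(msg)) msg else TRUE
})

#' AirJetProtocol: timing and loading of one air-jet indentation run
#'
#' Describes the measurement timeline (baseline, pressure-on, recovery
#' windows) and the pneumatic loading (gauge pressure, nozzle bore) of a
#' non-contact air-jet indentation acquisition. The default 5 s / 5 s / 5 s
#' timeline and 2 mm nozzle reproduce the standard acquisition protocol.
#'
#' @slot preS duration of the pre-pressure baseline window, seconds.
#' @slot onS duration of the pressure-on window, seconds.
#' @slot postS duration of the recovery window, seconds.
#' @slot pressurePa gauge pressure of the air jet, pascals (>= 0).
#' @slot nozzleDiameterMm bore diameter of the air port, millimetres.
#'
#' @seealso [airJetProtocol()], [jetForce()], [displacement()]
#' @export
setClass("AirJetProtocol",
  representation(
    preS = "numeric",
    onS = "numeric",
    postS = "numeric",
    pressurePa = "numeric",
    nozzleDiameterMm = "numeric"
  )
)

setValidity("AirJetProtocol", function(object) {
  msg <- character()
  for (s in c("preS", "onS", "postS", "nozzleDiameterMm")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      msg <- c(msg, paste(s, "must be a single positive number"))
    }
  }
  p <- object@pressurePa
  if (length(p) != 1L || !is.finite(p) || p < 0) {
    msg <- c(msg, "pressurePa must be a single non-negative number")
  }
  if (length(msg)) msg else TRUE
})

#' PhantomConfig: geometry and texture of the synthetic B-scan phantom
#'
#' Parameters of the layered speckle phantom: raster size and pixel pitch,
#' resting depth and thickness of the bright stratum-corneum (SC) band,
#' deeper-layer contrasts, multiplicative speckle contrast, exponential
#' depth attenuation, the lateral width of the pressure dent, and the true
#' structural stiffness used to convert force into indentation depth.
#'
#' @slot imageHeightPx,imageWidthPx raster size in pixels.
#' @slot axialPitchUm,lateralPitchUm pixel pitch, micrometres.
#' @slot fps frame rate, frames per second.
#' @slot scTopDepthMm resting depth of the SC upper boundary, millimetres.
#' @slot scThicknessMm thickness of the SC band, millimetres.
#' @slot nDeeperLayers number of tissue layers below the SC.
#' @slot layerContrasts mean intensity of SC and each deeper layer, in `[0,1]`
#'   (first element is the SC band).
#' @slot airIntensity mean intensity of the air gap above the surface.
#' @slot speckleContrast speckle contrast (SD/mean of the multiplicative
#'   gamma noise), in `[0, 1]`; 0 disables speckle.
#' @slot attenuationPerMm exponential intensity attenuation below the
#'   tissue surface, per millimetre.
#' @slot indentSigmaMm lateral Gaussian width of the pressure dent, mm.
#' @slot kTrueNPerMm ground-truth structural stiffness, N/mm.
#' @slot seed integer seed making the generated series reproducible.
#'
#' @seealso [phantomConfig()], [generatePhantomSeries()]
#' @export
setClass("PhantomConfig",
  representation(
    imageHeightPx = "integer",
    imageWidthPx = "integer",
    axialPitchUm = "numeric",
    lateralPitchUm = "numeric",
    fps = "numeric",
    scTopDepthMm = "numeric",
    scThicknessMm = "numeric",
    nDeeperLayers = "integer",
    layerContrasts = "numeric",
    airIntensity = "numeric",
    speckleContrast = "numeric",
    attenuationPerMm = "numeric",
    indentSigmaMm = "numeric",
    kTrueNPerMm = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@imageHeightPx < 8L || object@imageWidthPx < 8L) {
    msg <- c(msg, "image size must be at least 8 x 8 pixels")
  }
  pos <- c("axialPitchUm", "lateralPitchUm", "fps", "scThicknessMm",
           "indentSigmaMm", "kTrueNPerMm")
  for (s in pos) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      msg <- c(msg, paste(s, "must be a single positive number"))
    }
  }
  if (object@scTopDepthMm < 0) msg <- c(msg, "scTopDepthMm must be >= 0")
  if (object@attenuationPerMm < 0) msg <- c(msg, "attenuationPerMm must be >= 0")
  if (object@speckleContrast < 0 || object@speckleContrast > 1) {
    msg <- c(msg, "speckleContrast must lie in [0, 1]")
  }
  if (object@nDeeperLayers < 0L) msg <- c(msg, "nDeeperLayers must be >= 0")
  if (length(object@layerContrasts) != 1L + object@nDeeperLayers) {
    msg <- c(msg, "layerContrasts must have length 1 + nDeeperLayers")
  }
  if (any(object@layerContrasts < 0 | object@layerContrasts > 1) ||
      object@airIntensity < 0 || object@airIntensity > 1) {
    msg <- c(msg, "all mean intensities must lie in [0, 1]")
  }
  depthMm <- object@imageHeightPx * object@axialPitchUm / 1000
  if (object@scTopDepthMm + object@scThicknessMm >= depthMm) {
    msg <- c(msg, "sc_top + sc_thickness must be smaller than the imaged depth")
  }
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth attached to a generated phantom series
#'
#' @slot boundaryDepthMm per-frame rasterized depth (mm) of the SC upper
#'   boundary at the central lateral position.
#' @slot masks integer `H x W x T` array of \{0,1\} ground-truth SC masks.
#' @slot deltaDTrueMm analytic indentation depth `F / K_true`, millimetres.
#' @slot kTrueNPerMm ground-truth structural stiffness, N/mm.
#' @slot forceN applied force implied by the protocol, newtons.
#'
#' @seealso [generatePhantomSeries()]
#' @export
setClass("PhantomTruth",
  representation(
    boundaryDepthMm = "numeric",
    masks = "array",
    deltaDTrueMm = "numeric",
    kTrueNPerMm = "numeric",
    forceN = "numeric"
  )
)

setValidity("PhantomTruth", function(object) {
  msg <- character()
  d <- dim(object@masks)
  if (length(d) != 3L) msg <- c(msg, "masks must be an H x W x T array")
  if (!all(object@masks %in% c(0L, 1L))) msg <- c(msg, "masks must be 0/1")
  if (length(d) == 3L && length(object@boundaryDepthMm) != d[3]) {
    msg <- c(msg, "boundaryDepthMm must have one entry per frame")
  }
  if (object@deltaDTrueMm < 0) msg <- c(msg, "deltaDTrueMm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DatasetSplit: patient-level train/validation/test partition
#'
#' Item identifiers partitioned into training, validation and test subsets
#' such that no patient contributes items to more than one subset.
#'
#' @slot trainIds,valIds,testIds disjoint character vectors of item ids.
#' @slot patientOf named character vector mapping item id to patient id.
#' @slot ratios numeric triple (train, validation, test), summing to 1.
#' @slot seed integer seed used for the patient shuffle.
#'
#' @seealso [splitDataset()]
#' @export
setClass("DatasetSplit",
  representation(
    trainIds = "character",
    valIds = "character",
    testIds = "character",
    patientOf = "character",
    ratios = "numeric",
    seed = "integer"
  )
)

setValidity("DatasetSplit", function(object) {
  msg <- character()
  all3 <- c(object@trainIds, object@valIds, object@testIds)
  if (anyDuplicated(all3)) msg <- c(msg, "subsets must be pairwise disjoint")
  if (!setequal(all3, names(object@patientOf))) {
    msg <- c(msg, "union of subsets must equal all items")
  }
  if (length(object@ratios) != 3L || abs(sum(object@ratios) - 1) > 1e-9 ||
      any(object@ratios <= 0)) {
    msg <- c(msg, "ratios must be three positive numbers summing to 1")
  }
  pt <- object@patientOf
  sub <- c(
    unique(pt[object@trainIds]), unique(pt[object@valIds]),
    unique(pt[object@testIds])
  )
  if (anyDuplicated(sub)) msg <- c(msg, "a patient appears in two subsets")
  if (length(msg)) msg else TRUE
})

#' TrainConfig: U-Net architecture and optimization settings
#'
#' @slot depth number of encoder levels (resolution halvings).
#' @slot baseChannels channels of the first encoder level; each deeper
#'   level doubles them.
#' @slot loss one of `"bce"`, `"dice"`, `"bce+dice"`.
#' @slot learningRate Adam learning rate.
#' @slot epochs maximum training epochs.
#' @slot batchSize minibatch size, images.
#' @slot patience early-stopping patience on validation loss, epochs.
#' @slot seed integer seed fixing initialization and data order.
#' @slot inputSizePx side length of training rasters; must be divisible by
#'   `2^depth`.
#'
#' @seealso [trainConfig()], [buildUnet()], [trainUnet()]
#' @export
setClass("TrainConfig",
  representation(
    depth = "integer",
    baseChannels = "integer",
    loss = "character",
    learningRate = "numeric",
    epochs = "integer",
    batchSize = "integer",
    patience = "integer",
    seed = "integer",
    inputSizePx = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  for (s in c("depth", "baseChannels", "epochs", "batchSize", "patience",
              "inputSizePx")) {
    if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be positive"))
  }
  if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
  if (!object@loss %in% c("bce", "dice", "bce+dice")) {
    msg <- c(msg, "loss must be one of 'bce', 'dice', 'bce+dice'")
  }
  if (object@inputSizePx %% (2L^object@depth) != 0L) {
    msg <- c(msg, sprintf(
      "inputSizePx (%d) must be divisible by 2^depth (%d)",
      object@inputSizePx, 2L^object@depth
    ))
  }
  if (length(msg)) msg else TRUE
})

#' UNetModel: a (possibly trained) U-Net segmentation model
#'
#' Encoder-decoder with skip concatenations and a single-channel sigmoid
#' output, stored as a flat named list of weight matrices and bias vectors.
#'
#' @slot params named list of parameter arrays.
#' @slot config the [TrainConfig-class] the model was built with.
#' @slot history per-epoch `data.frame(epoch, trainLoss, valLoss)`;
#'   empty before training.
#' @slot bestEpoch epoch of the returned (best-validation) checkpoint;
#'   `NA` before training.
#'
#' @seealso [buildUnet()], [trainUnet()], [predictMask()]
#' @export
setClass("UNetModel",
  representation(
    params = "list",
    config = "TrainConfig",
    history = "data.frame",
    bestEpoch = "integer"
  )
)

#' DepthTrace: tracked depth of the SC landmark over time
#'
#' @slot tS per-frame acquisition times, seconds.
#' @slot depthMm per-frame tracked depth of the landmark, millimetres.
#' @slot landmark `"mask_centroid"` or `"top_boundary"`.
#'
#' @seealso [trackDepth()], [displacement()]
#' @export
setClass("DepthTrace",
  representation(
    tS = "numeric",
    depthMm = "numeric",
    landmark = "character"
  )
)

setValidity("DepthTrace", function(object) {
  msg <- character()
  if (length(object@tS) != length(object@depthMm)) {
    msg <- c(msg, "tS and depthMm must have equal length")
  }
  if (!object@landmark %in% c("mask_centroid", "top_boundary")) {
    msg <- c(msg, "landmark must be 'mask_centroid' or 'top_boundary'")
  }
  if (length(msg)) msg else TRUE
})

#' StiffnessResult: force, displacement and structural stiffness
#'
#' Holds the quantities of the structural stiffness relation K = F / delta-d:
#' applied force F (N), induced displacement delta-d (mm), and their ratio K
#' (N/mm), together with the baseline and maximum tracked depths.
#'
#' @slot forceN applied force, newtons.
#' @slot deltaDMm displacement, millimetres.
#' @slot kNPerMm structural stiffness, newtons per millimetre.
#' @slot baselineDepthMm mean depth over the pre-pressure window, mm.
#' @slot maxDepthMm maximum depth over the pressure-on window, mm.
#'
#' @seealso [stiffness()], [displacement()]
#' @export
setClass("StiffnessResult",
  representation(
    forceN = "numeric",
    deltaDMm = "numeric",
    kNPerMm = "numeric",
    baselineDepthMm = "numeric",
    maxDepthMm = "numeric"
  )
)

setValidity("StiffnessResult", function(object) {
  msg <- character()
  if (object@forceN < 0) msg <- c(msg, "forceN must be >= 0")
  if (object@deltaDMm < 0) msg <- c(msg, "deltaDMm must be >= 0")
  if (object@deltaDMm > 0 &&
      abs(object@kNPerMm - object@forceN / object@deltaDMm) >
        1e-8 * max(1, object@kNPerMm)) {
    msg <- c(msg, "kNPerMm must equal forceN / deltaDMm")
  }
  if (length(msg)) msg else TRUE
})

#' SegMetrics: segmentation quality summary
#'
#' Macro-averaged (per-image mean) pixel accuracy, Dice coefficient and
#' intersection-over-union of predicted against reference masks.
#'
#' @slot pixelAccuracy mean per-image fraction of agreeing pixels.
#' @slot dice mean per-image Dice coefficient.
#' @slot iou mean per-image intersection-over-union.
#' @slot nImages number of evaluated images.
#' @slot perImage per-image `data.frame(id, pixelAccuracy, dice, iou)`.
#'
#' @seealso [evaluateSegmentation()]
#' @export
setClass("SegMetrics",
  representation(
    pixelAccuracy = "numeric",
    dice = "numeric",
    iou = "numeric",
    nImages = "integer",
    perImage = "data.frame"
  )
)

setValidity("SegMetrics", function(object) {
  ok <- c(object@pixelAccuracy, object@dice, object@iou)
  if (any(ok < 0 | ok > 1)) "metrics must lie in [0, 1]" else TRUE
})

#' IccResult: intraclass correlation from a two-way mixed-effects model
#'
#' @slot iccSingle single-measures ICC.
#' @slot iccAverage average-measures ICC over the k conditions.
#' @slot ciSingle,ciAverage 95% confidence intervals `(lo, hi)`.
#' @slot model label of the ICC form, e.g. `"two-way mixed, consistency"`.
#' @slot nSubjects,nConditions dimensions of the analysed matrix.
#'
#' @seealso [iccTwoWayMixed()]
#' @export
setClass("IccResult",
  representation(
    iccSingle = "numeric",
    iccAverage = "numeric",
    ciSingle = "numeric",
    ciAverage = "numeric",
    model = "character",
    nSubjects = "integer",
    nConditions = "integer"
  )
)

#' EffectSize: Cohen's d with confidence intervals
#'
#' Pooled-SD independent-groups Cohen's d, its normal-approximation 95%
#' confidence interval, and the pooled-variance t confidence interval of
#' the raw mean difference.
#'
#' @slot meanDifference `mean(x) - mean(y)`.
#' @slot cohensD standardized mean difference (signed).
#' @slot ci95 95% CI of the mean difference (pooled-variance t).
#' @slot ciD 95% CI of Cohen's d (normal approximation).
#' @slot n1,n2 group sizes.
#'
#' @seealso [cohensD()]
#' @export
setClass("EffectSize",
  representation(
    meanDifference = "numeric",
    cohensD = "numeric",
    ci95 = "numeric",
    ciD = "numeric",
    n1 = "integer",
    n2 = "integer"
  )
)

setValidity("EffectSize", function(object) {
  if (object@ci95[1] > object@meanDifference + 1e-12 ||
      object@ci95[2] < object@meanDifference - 1e-12) {
    "ci95 must bracket the mean difference"
  } else TRUE
})
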
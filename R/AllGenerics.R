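#' Accessor generics
#'
#' Slot accessors for the package's S4 containers. `frames()` returns the
#' `H x W x T` intensity array of a [BScanSeries-class]; `nFrames()` its
#' frame count; `fps()`, `axialPitchUm()`, `lateralPitchUm()` and
#' `sourceId()` its acquisition metadata; `truthMasks()` the mask array of
#' a [PhantomTruth-class]; `trainIds()`, `valIds()` and `testIds()` the
#' subsets of a [DatasetSplit-class]; `history()` the per-epoch loss table
#' of a [UNetModel-class].
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("axialPitchUm", function(x) standardGeneric("axialPitchUm"))

#' @rdname accessors
#' @export
setGeneric("lateralPitchUm", function(x) standardGeneric("lateralPitchUm"))

#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname accessors
#' @export
setGeneric("truthMasks", function(x) standardGeneric("truthMasks"))

#' @rdname accessors
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))

#' @rdname accessors
#' @export
setGeneric("valIds", function(x) standardGeneric("valIds"))

#' @rdname accessors
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))

#' @rdname accessors
#' @export
setGeneric("history", function(x) standardGeneric("history"))

#' @rdname accessors
#' @export
setMethod("frames", "BScanSeries", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("nFrames", "BScanSeries", function(x) dim(x@frames)[3L])

#' @rdname accessors
#' @export
setMethod("fps", "BScanSeries", function(x) x@fps)

#' @rdname accessors
#' @export
setMethod("axialPitchUm", "BScanSeries", function(x) x@axialPitchUm)

#' @rdname accessors
#' @export
setMethod("lateralPitchUm", "BScanSeries", function(x) x@lateralPitchUm)

#' @rdname accessors
#' @export
setMethod("sourceId", "BScanSeries", function(x) x@sourceId)

#' @rdname accessors
#' @export
setMethod("truthMasks", "PhantomTruth", function(x) x@masks)

#' @rdname accessors
#' @export
setMethod("trainIds", "DatasetSplit", function(x) x@trainIds)

#' @rdname accessors
#' @export
setMethod("valIds", "DatasetSplit", function(x) x@valIds)

#' @rdname accessors
#' @export
setMethod("testIds", "DatasetSplit", function(x) x@testIds)

#' @rdname accessors
#' @export
setMethod("history", "UNetModel", function(x) x@history)

setMethod("show", "BScanSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "BScanSeries '%s': %d frames of %d x %d px @ %.3g fps\n",
    object@sourceId, d[3], d[1], d[2], object@fps
  ))
  cat(sprintf(
    "  pixel pitch: %.3g um axial x %.3g um lateral (%.3g x %.3g mm field)\n",
    object@axialPitchUm, object@lateralPitchUm,
    d[1] * object@axialPitchUm / 1000, d[2] * object@lateralPitchUm / 1000
  ))
})

setMethod("show", "AirJetProtocol", function(object) {
  cat(sprintf(
    "AirJetProtocol: %.3g s pre / %.3g s on / %.3g s post, %.5g Pa through %.3g mm nozzle (F = %.4g N)\n",
    object@preS, object@onS, object@postS, object@pressurePa,
    object@nozzleDiameterMm, jetForce(object)
  ))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: K_true = %.4g N/mm, F = %.4g N, delta_d_true = %.4g mm (%d frames)\n",
    object@kTrueNPerMm, object@forceN, object@deltaDTrueMm,
    length(object@boundaryDepthMm)
  ))
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf(
    "DatasetSplit: %d train / %d val / %d test items (%d patients, seed %d)\n",
    length(object@trainIds), length(object@valIds), length(object@testIds),
    length(unique(object@patientOf)), object@seed
  ))
})

setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf(
    "UNetModel: depth %d, base %d channels, %d parameters (%s loss)\n",
    cfg@depth, cfg@baseChannels, np, cfg@loss
  ))
  if (nrow(object@history)) {
    cat(sprintf(
      "  trained %d epochs, best validation loss %.4g at epoch %d\n",
      nrow(object@history), min(object@history$valLoss), object@bestEpoch
    ))
  } else cat("  untrained\n")
})

setMethod("show", "DepthTrace", function(object) {
  cat(sprintf(
    "DepthTrace (%s): %d frames, depth %.4g-%.4g mm\n",
    object@landmark, length(object@tS),
    min(object@depthMm), max(object@depthMm)
  ))
})

setMethod("show", "StiffnessResult", function(object) {
  cat(sprintf(
    "StiffnessResult: K = %.4g N/mm (F = %.4g N, delta_d = %.4g mm; baseline %.4g mm, max %.4g mm)\n",
    object@kNPerMm, object@forceN, object@deltaDMm,
    object@baselineDepthMm, object@maxDepthMm
  ))
})

setMethod("show", "SegMetrics", function(object) {
  cat(sprintf(
    "SegMetrics over %d images: accuracy %.4f, Dice %.4f, IoU %.4f\n",
    object@nImages, object@pixelAccuracy, object@dice, object@iou
  ))
})

setMethod("show", "IccResult", function(object) {
  cat(sprintf(
    "ICC (%s), %d subjects x %d conditions:\n  single  %.3f [%.3f, %.3f]\n  average %.3f [%.3f, %.3f]\n",
    object@model, object@nSubjects, object@nConditions,
    object@iccSingle, object@ciSingle[1], object@ciSingle[2],
    object@iccAverage, object@ciAverage[1], object@ciAverage[2]
  ))
})

setMethod("show", "EffectSize", function(object) {
  cat(sprintf(
    "EffectSize: mean difference %.4g [%.4g, %.4g], Cohen's d %.3f [%.3f, %.3f] (n = %d, %d)\n",
    object@meanDifference, object@ci95[1], object@ci95[2],
    object@cohensD, object@ciD[1], object@ciD[2], object@n1, object@n2
  ))
})
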
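#' Patient-level dataset split
#'
#' Partitions items into training, validation and test subsets at the
#' patient level: patients are shuffled with the seed and assigned
#' greedily, each to the subset with the largest remaining item-count
#' deficit relative to the target ratios. No patient ever contributes to
#' two subsets. When every item is its own patient the subset sizes equal
#' the rounded ratios exactly — 700 items at 60/20/20 give 420/140/140.
#'
#' @param items character vector of item identifiers.
#' @param patientOf patient label per item: a vector aligned with `items`
#'   or a named vector keyed by item id.
#' @param ratios numeric triple (train, validation, test) of positive
#'   values summing to 1.
#' @param seed integer seed for the patient shuffle.
#' @return a [DatasetSplit-class].
#' @examples
#' ids <- sprintf("img%03d", 1:700)
#' sp <- splitDataset(ids, ids, c(0.6, 0.2, 0.2), seed = 1)
#' lengths(list(trainIds(sp), valIds(sp), testIds(sp)))  # 420 140 140
#' @export
splitDataset <- function(items, patientOf, ratios = c(0.6, 0.2, 0.2),
                         seed = 1L) {
  items <- as.character(items)
  if (is.null(names(patientOf))) {
    stopifnot(length(patientOf) == length(items))
    patientOf <- stats::setNames(as.character(patientOf), items)
  } else {
    patientOf <- patientOf[items]
  }
  if (any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be positive and sum to 1")
  }
  patients <- unique(patientOf)
  if (length(patients) < 3L) {
    stop(sprintf(
      "split error: %d patient(s) cannot fill 3 subsets", length(patients)
    ))
  }
  n <- length(items)
  # largest-remainder rounding of the per-subset item targets
  raw <- n * ratios
  target <- floor(raw)
  rem <- n - sum(target)
  if (rem > 0) {
    bump <- order(raw - target, decreasing = TRUE)[seq_len(rem)]
    target[bump] <- target[bump] + 1
  }
  set.seed(as.integer(seed))
  patients <- sample(patients)
  counts <- c(0, 0, 0)
  sets <- list(character(), character(), character())
  for (p in patients) {
    its <- items[patientOf == p]
    s <- which.max(target - counts)   # ties -> first (train, val, test)
    sets[[s]] <- c(sets[[s]], its)
    counts[s] <- counts[s] + length(its)
  }
  new("DatasetSplit",
    trainIds = sets[[1L]], valIds = sets[[2L]], testIds = sets[[3L]],
    patientOf = patientOf, ratios = ratios, seed = as.integer(seed)
  )
}

.asMask <- function(m) {
  if (is.logical(m)) m <- m * 1L
  m
}

.checkCongruent <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop(sprintf(
      "dimension error: mask shapes %s and %s differ",
      paste(dim(pred), collapse = "x"), paste(dim(truth), collapse = "x")
    ))
  }
}

#' Segmentation overlap metrics
#'
#' Dice coefficient `2|A&B| / (|A| + |B|)`, intersection-over-union
#' `|A&B| / (A|B)` and pixel accuracy (fraction of agreeing pixels) between
#' a predicted and a reference binary mask. Two empty masks define Dice
#' and IoU as 1. All three are symmetric in their arguments, and
#' `dice = 2 iou / (1 + iou)` holds for every pair.
#'
#' @param pred,truth congruent 0/1 matrices (or logical matrices).
#' @return a number in `[0, 1]`.
#' @examples
#' a <- matrix(0, 10, 10); a[3:5, ] <- 1
#' diceCoefficient(a, a)  # 1
#' @export
diceCoefficient <- function(pred, truth) {
  pred <- .asMask(pred)
  truth <- .asMask(truth)
  .checkCongruent(pred, truth)
  inter <- sum(pred == 1L & truth == 1L)
  tot <- sum(pred == 1L) + sum(truth == 1L)
  if (tot == 0L) return(1)
  2 * inter / tot
}

#' @rdname diceCoefficient
#' @export
iouScore <- function(pred, truth) {
  pred <- .asMask(pred)
  truth <- .asMask(truth)
  .checkCongruent(pred, truth)
  inter <- sum(pred == 1L & truth == 1L)
  union <- sum(pred == 1L | truth == 1L)
  if (union == 0L) return(1)
  inter / union
}

#' @rdname diceCoefficient
#' @export
pixelAccuracy <- function(pred, truth) {
  pred <- .asMask(pred)
  truth <- .asMask(truth)
  .checkCongruent(pred, truth)
  mean(pred == truth)
}

#' Evaluate a trained U-Net on a set of frames
#'
#' Predicts a mask for every listed frame and macro-averages pixel
#' accuracy, Dice and IoU against the reference masks (per-image means).
#'
#' @param model a trained [UNetModel-class].
#' @param images named list of frames.
#' @param masks named list of congruent reference 0/1 masks.
#' @param ids item ids to evaluate (default: all of `images`).
#' @param threshold probability threshold passed to [predictMask()].
#' @return a [SegMetrics-class].
#' @export
evaluateSegmentation <- function(model, images, masks, ids = names(images),
                                 threshold = 0.5) {
  stopifnot(length(ids) > 0)
  per <- data.frame(id = ids, pixelAccuracy = NA_real_, dice = NA_real_,
                    iou = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    pr <- predictMask(model, images[[ids[i]]], threshold)
    tr <- masks[[ids[i]]]
    per$pixelAccuracy[i] <- pixelAccuracy(pr, tr)
    per$dice[i] <- diceCoefficient(pr, tr)
    per$iou[i] <- iouScore(pr, tr)
  }
  new("SegMetrics",
    pixelAccuracy = mean(per$pixelAccuracy), dice = mean(per$dice),
    iou = mean(per$iou), nImages = length(ids), perImage = per
  )
}
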
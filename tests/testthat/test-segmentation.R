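test_that("patient-level split hits exact rounded sizes for singleton patients", {
  ids <- sprintf("img%03d", 1:700)
  sp <- splitDataset(ids, ids, c(0.6, 0.2, 0.2), seed = 1)
  expect_length(trainIds(sp), 420L)
  expect_length(valIds(sp), 140L)
  expect_length(testIds(sp), 140L)
  expect_setequal(c(trainIds(sp), valIds(sp), testIds(sp)), ids)
})

test_that("no patient ever straddles subsets, across many seeds", {
  set.seed(99)
  items <- sprintf("i%03d", 1:120)
  patients <- sample(sprintf("p%02d", 1:25), 120, replace = TRUE)
  for (seed in c(1:40)) {
    sp <- splitDataset(items, patients, c(0.6, 0.2, 0.2), seed = seed)
    pt <- sp@patientOf
    inTrain <- unique(pt[trainIds(sp)])
    inVal <- unique(pt[valIds(sp)])
    inTest <- unique(pt[testIds(sp)])
    expect_length(intersect(inTrain, inVal), 0L)
    expect_length(intersect(inTrain, inTest), 0L)
    expect_length(intersect(inVal, inTest), 0L)
  }
})

test_that("degenerate splits error out", {
  expect_error(splitDataset(c("a", "b"), c("p1", "p2")), "split error")
  expect_error(splitDataset(letters[1:9], letters[1:9], c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("overlap metrics match their set-arithmetic definitions", {
  a <- matrix(0L, 20, 20); a[5:9, ] <- 1L
  b <- matrix(0L, 20, 20); b[8:12, ] <- 1L
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(iouScore(a, a), 1)
  expect_equal(pixelAccuracy(a, a), 1)

  disjoint <- matrix(0L, 20, 20); disjoint[15:16, ] <- 1L
  expect_equal(diceCoefficient(a, disjoint), 0)
  expect_equal(iouScore(a, disjoint), 0)

  # |A| = |B| = 100, overlap 40 -> dice 0.4, iou 0.25
  expect_equal(diceCoefficient(a, b), 2 * 40 / 200)
  expect_equal(iouScore(a, b), 40 / 160)

  empty <- matrix(0L, 20, 20)
  expect_equal(diceCoefficient(empty, empty), 1)
  expect_equal(iouScore(empty, empty), 1)

  expect_error(diceCoefficient(a, matrix(0L, 10, 10)), "dimension error")
})

test_that("dice = 2 iou / (1 + iou) and symmetry hold on random masks", {
  set.seed(17)
  for (rep in 1:25) {
    a <- matrix(rbinom(400, 1, runif(1, 0.1, 0.6)), 20, 20)
    b <- matrix(rbinom(400, 1, runif(1, 0.1, 0.6)), 20, 20)
    d <- diceCoefficient(a, b)
    i <- iouScore(a, b)
    expect_equal(d, 2 * i / (1 + i), tolerance = 1e-12)
    expect_gte(d, i)
    expect_equal(d, diceCoefficient(b, a))
    expect_equal(i, iouScore(b, a))
    expect_equal(pixelAccuracy(a, b), pixelAccuracy(b, a))
  }
})

test_that("U-Net geometry contract: output shape and divisibility errors", {
  cfg <- trainConfig(depth = 2, baseChannels = 2, inputSizePx = 32, seed = 1)
  m <- buildUnet(cfg)
  pr <- predictProbability(m, matrix(runif(32 * 32), 32, 32))
  expect_identical(dim(pr), c(32L, 32L))
  expect_true(all(pr > 0 & pr < 1))

  expect_error(trainConfig(depth = 4, inputSizePx = 100), "divisible")
  expect_error(predictMask(m, matrix(0, 30, 30)), "configuration error")

  # smallest legal network builds and runs a forward pass
  tiny <- buildUnet(trainConfig(depth = 1, baseChannels = 1, inputSizePx = 2))
  expect_identical(dim(predictProbability(tiny, matrix(0.5, 2, 2))), c(2L, 2L))
})

test_that("zero-weight model predicts all background; threshold near 1 empties mask", {
  cfg <- trainConfig(depth = 1, baseChannels = 2, inputSizePx = 16, seed = 2)
  m <- buildUnet(cfg)
  m@params <- lapply(m@params, function(x) x * 0)
  f <- matrix(runif(256), 16, 16)
  expect_true(all(predictProbability(m, f) == 0.5))
  expect_true(all(predictMask(m, f) == 0L))  # tie at 0.5 -> background

  m2 <- buildUnet(trainConfig(depth = 1, baseChannels = 2, inputSizePx = 16,
                              seed = 3))
  expect_true(all(predictMask(m2, f, threshold = 1 - 1e-12) == 0L))
})

test_that("backpropagation matches numerical gradients on a tiny net", {
  ns <- asNamespace("octstiff")
  set.seed(42)
  depth <- 2L; base <- 2L; H <- 8L; W <- 8L; B <- 2L
  p <- ns$.initUnetParams(depth, base)
  # biases off the ReLU kinks so central differences are valid
  for (nm in grep("\\.b$", names(p), value = TRUE)) {
    p[[nm]] <- rnorm(length(p[[nm]]), sd = 0.1)
  }
  X <- matrix(runif(B * H * W), ncol = 1)
  Tg <- matrix(rbinom(B * H * W, 1, 0.3), ncol = 1)
  lossOf <- function(pp) {
    fw <- ns$.unetForward(pp, X, H, W, B, depth, keep = FALSE)
    ns$.segLoss(fw$Z, Tg, "bce+dice")$loss
  }
  fw <- ns$.unetForward(p, X, H, W, B, depth, keep = TRUE)
  ls <- ns$.segLoss(fw$Z, Tg, "bce+dice")
  g <- ns$.unetBackward(p, fw$cache, ls$dZ, H, W, B, depth)
  eps <- 1e-6
  for (nm in names(p)) {
    for (ix in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      p2 <- p; p2[[nm]][ix] <- p2[[nm]][ix] + eps
      p3 <- p; p3[[nm]][ix] <- p3[[nm]][ix] - eps
      num <- (lossOf(p2) - lossOf(p3)) / (2 * eps)
      expect_equal(g[[nm]][ix], num, tolerance = 1e-3,
                   label = sprintf("analytic grad %s[%d]", nm, ix))
    }
  }
})

test_that("training reduces loss on separable frames, deterministically", {
  ds <- generatePhantomDataset(nSeries = 4, framesPerSeries = 5,
                               imageSizePx = 32, seed = 21,
                               protocol = testProtocol(pressurePa = 5e3))
  ids <- names(ds$images)
  trainSet <- ids[ds$patientOf %in% c("ph01", "ph02", "ph03")]
  valSet <- ids[ds$patientOf == "ph04"]
  cfg <- trainConfig(depth = 2, baseChannels = 4, epochs = 6, batchSize = 4,
                     learningRate = 2e-3, seed = 31, inputSizePx = 32)
  m <- trainUnet(buildUnet(cfg), ds$images, ds$masks,
                 trainIdsChr = trainSet, valIdsChr = valSet)
  h <- history(m)
  expect_lt(h$trainLoss[nrow(h)], h$trainLoss[1])

  m2 <- trainUnet(buildUnet(cfg), ds$images, ds$masks,
                  trainIdsChr = trainSet, valIdsChr = valSet)
  expect_identical(history(m), history(m2))

  # zero learning rate: parameters frozen, flat loss history
  cfg0 <- trainConfig(depth = 2, baseChannels = 4, epochs = 3, batchSize = 4,
                      learningRate = 0, seed = 31, inputSizePx = 32)
  m0 <- buildUnet(cfg0)
  t0 <- trainUnet(m0, ds$images, ds$masks,
                  trainIdsChr = trainSet, valIdsChr = valSet)
  expect_equal(t0@params, m0@params)
  expect_equal(diff(range(history(t0)$valLoss)), 0, tolerance = 1e-12)

  expect_error(
    trainUnet(m0, ds$images, ds$masks, trainIdsChr = character(),
              valIdsChr = valSet),
    "training error"
  )
})
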
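test_that("centerline extraction picks the middle column", {
  f <- matrix(rnorm(10 * 997), 10, 997)
  expect_identical(extractCenterline(f), f[, 499])  # odd width

  even <- matrix(rnorm(10 * 100), 10, 100)
  expect_identical(extractCenterline(even), even[, 50])

  one <- matrix(1:5, 5, 1)
  expect_identical(extractCenterline(one), one[, 1])

  # frame whose every column j is the constant j: centre profile constant
  cols <- matrix(rep(1:9, each = 6), 6, 9)
  expect_equal(extractCenterline(cols), rep(5, 6))
})

test_that("composite profile is the element-wise mean of centerlines", {
  H <- 12; W <- 7; nF <- 4
  p <- rnorm(H)
  fr <- array(0, c(H, W, nF))
  for (k in 1:nF) fr[, , k] <- matrix(p, H, W)   # identical frames
  s <- new("BScanSeries", frames = (fr - min(fr)) / diff(range(fr)),
           fps = 10, axialPitchUm = 7.5, lateralPitchUm = 10, sourceId = "t")
  expect_equal(compositeProfile(s), extractCenterline(frames(s)[, , 1]))
  expect_equal(compositeProfile(s, 2L), extractCenterline(frames(s)[, , 2]))

  # linearity: profiles p and -p + c average to c/2
  fr2 <- array(0.2, c(H, W, 2))
  fr2[, , 1] <- 0.1
  fr2[, , 2] <- 0.5
  s2 <- new("BScanSeries", frames = fr2, fps = 10, axialPitchUm = 7.5,
            lateralPitchUm = 10, sourceId = "t")
  expect_equal(compositeProfile(s2), rep(0.3, H))

  expect_error(compositeProfile(s, integer()), "empty frame window")
})

test_that("depth tracking follows the phantom truth within one axial pixel", {
  cfg <- testPhantomConfig(k = 1, seed = 14)
  proto <- testProtocol(pressurePa = 2e4)
  out <- generatePhantomSeries(cfg, proto)
  tb <- trackDepth(out$series, truthMasks(out$truth), "top_boundary")
  expect_lt(max(abs(tb@depthMm - out$truth@boundaryDepthMm)),
            cfg@axialPitchUm / 1000 + 1e-12)

  # centroid trace moves with the boundary up to a constant offset
  tc <- trackDepth(out$series, truthMasks(out$truth), "mask_centroid")
  off <- tc@depthMm - out$truth@boundaryDepthMm
  expect_lt(diff(range(off)), 2 * cfg@axialPitchUm / 1000)

  # identical masks give a constant trace
  mk <- truthMasks(out$truth)
  for (k in seq_len(dim(mk)[3])) mk[, , k] <- mk[, , 1]
  expect_equal(length(unique(trackDepth(out$series, mk)@depthMm)), 1L)

  # an empty central band is a tracking error naming the frame
  mk[, , 3] <- 0L
  expect_error(trackDepth(out$series, mk), "frame 3")
})

test_that("displacement = on-window max minus pre-window baseline", {
  proto <- airJetProtocol()  # 5/5/5
  n <- 150
  t <- (seq_len(n) - 1) / 10
  d <- rep(0.5, n)
  d[t >= 5 & t < 10] <- 0.8
  tr <- new("DepthTrace", tS = t, depthMm = d, landmark = "mask_centroid")
  disp <- displacement(tr, proto)
  expect_equal(disp$baselineMm, 0.5)
  expect_equal(disp$maxMm, 0.8)
  expect_equal(disp$deltaDMm, 0.3)

  flat <- new("DepthTrace", tS = t, depthMm = rep(0.5, n),
              landmark = "mask_centroid")
  expect_equal(displacement(flat, proto)$deltaDMm, 0)

  short <- new("DepthTrace", tS = t[1:30], depthMm = d[1:30],
               landmark = "mask_centroid")
  expect_error(displacement(short, proto), "domain error")
})

test_that("max-of-window noise inflation stays within 3 px on a 50 px plateau", {
  # 1000 simulated traces with 1 px noise: the on-window max overshoots the
  # plateau by the expected extreme-value bias, but delta-d stays within 3 px
  proto <- airJetProtocol()
  n <- 150
  t <- (seq_len(n) - 1) / 10
  px <- 7.5e-3
  set.seed(77)
  errs <- replicate(1000, {
    d <- ifelse(t >= 5 & t < 10, 50 * px, 0) + rnorm(n, 0, px)
    tr <- new("DepthTrace", tS = t, depthMm = d + 1, landmark = "mask_centroid")
    displacement(tr, proto)$deltaDMm / px - 50
  })
  expect_lt(mean(abs(errs)), 3)
  expect_lt(abs(mean(errs)), 3)
  # the optional 3-frame median reduces the inflation
  errsMed <- replicate(200, {
    d <- ifelse(t >= 5 & t < 10, 50 * px, 0) + rnorm(n, 0, px)
    tr <- new("DepthTrace", tS = t, depthMm = d + 1, landmark = "mask_centroid")
    displacement(tr, proto, smooth = "median3")$deltaDMm / px - 50
  })
  expect_lt(mean(errsMed), mean(errs))
})

test_that("stiffness is F over delta-d and refuses zero displacement", {
  expect_equal(stiffness(0.5, 0.5)@kNPerMm, 1)
  expect_equal(stiffness(1, 0.25)@kNPerMm, 4)
  expect_error(stiffness(1, 0), "undefined-stiffness")
  expect_error(stiffness(-1, 0.5), "domain error")
})

test_that("scale equivariance: pressure scales force but not recovered K", {
  cfg <- testPhantomConfig(k = 1.5, seed = 23)
  k1 <- quantifyStiffness(
    generatePhantomSeries(cfg, testProtocol(pressurePa = 1.5e4))$series,
    generatePhantomSeries(cfg, testProtocol(pressurePa = 1.5e4))$truth@masks,
    testProtocol(pressurePa = 1.5e4)
  )
  k2 <- quantifyStiffness(
    generatePhantomSeries(cfg, testProtocol(pressurePa = 3e4))$series,
    generatePhantomSeries(cfg, testProtocol(pressurePa = 3e4))$truth@masks,
    testProtocol(pressurePa = 3e4)
  )
  expect_equal(k2@forceN, 2 * k1@forceN, tolerance = 1e-12)
  expect_equal(k2@kNPerMm, k1@kNPerMm, tolerance = 0.1)
})
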
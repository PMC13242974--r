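test_that("displacement waveform follows the pre/on/post protocol", {
  p <- airJetProtocol()  # 5/5/5 s
  expect_equal(displacementWaveform(2.0, p, 0.5), 0)
  expect_equal(displacementWaveform(7.5, p, 0.5), 0.5)
  expect_equal(displacementWaveform(14.9, p, 0.5), 0)
  # smooth rise inside the ramp
  mid <- displacementWaveform(5.25, p, 0.5)
  expect_gt(mid, 0)
  expect_lt(mid, 0.5)
  expect_error(displacementWaveform(-0.1, p, 0.5), "out of protocol range")
  expect_error(displacementWaveform(15.1, p, 0.5), "out of protocol range")
  expect_error(displacementWaveform(1, p, -1), ">= 0")
})

test_that("force arithmetic is pressure times nozzle area", {
  expect_equal(jetForce(1e5, 2), 1e5 * pi * 1e-6, tolerance = 1e-12)  # 0.3142 N
  expect_equal(jetForce(0, 2), 0)
  expect_equal(jetForce(2e5, 2), 2 * jetForce(1e5, 2))
  expect_equal(jetForce(airJetProtocol(pressurePa = 1e5)), jetForce(1e5, 2))
  expect_error(jetForce(-1, 2), ">= 0")
})

test_that("generated series has the protocol-implied geometry and truth", {
  cfg <- testPhantomConfig(k = 1, seed = 5)
  proto <- testProtocol(pressurePa = 2e4)  # F = 0.0628 N
  out <- generatePhantomSeries(cfg, proto)

  # frame count = floor(fps * total duration)
  expect_equal(nFrames(out$series), floor(10 * 3))
  # delta_d_true = F / K
  expect_equal(out$truth@deltaDTrueMm, jetForce(proto) / 1, tolerance = 1e-12)
  expect_equal(out$truth@kTrueNPerMm * out$truth@deltaDTrueMm,
               out$truth@forceN, tolerance = 1e-12)

  # rasterized boundary within one axial pixel of the analytic waveform
  tS <- (seq_len(nFrames(out$series)) - 1) / 10
  analytic <- cfg@scTopDepthMm +
    displacementWaveform(tS, proto, out$truth@deltaDTrueMm)
  expect_lt(max(abs(out$truth@boundaryDepthMm - analytic)),
            cfg@axialPitchUm / 1000 + 1e-12)

  # intensities valid, masks binary and congruent
  expect_true(all(frames(out$series) >= 0 & frames(out$series) <= 1))
  expect_true(all(truthMasks(out$truth) %in% c(0L, 1L)))
  expect_identical(dim(truthMasks(out$truth)), dim(frames(out$series)))
})

test_that("zero pressure keeps the boundary static", {
  cfg <- testPhantomConfig(seed = 6)
  out <- generatePhantomSeries(cfg, testProtocol(pressurePa = 0))
  expect_equal(out$truth@deltaDTrueMm, 0)
  expect_equal(length(unique(out$truth@boundaryDepthMm)), 1L)
})

test_that("generation is deterministic and stiffer phantoms deform less", {
  cfg <- testPhantomConfig(seed = 9)
  proto <- testProtocol()
  a <- generatePhantomSeries(cfg, proto)
  b <- generatePhantomSeries(cfg, proto)
  expect_identical(frames(a$series), frames(b$series))
  expect_identical(truthMasks(a$truth), truthMasks(b$truth))

  deltas <- vapply(c(0.5, 1, 1.5, 2, 2.5), function(k) {
    generatePhantomSeries(testPhantomConfig(k = k), proto)$truth@deltaDTrueMm
  }, 0)
  expect_true(all(diff(deltas) < 0))  # delta_d = F/K strictly decreasing
})

test_that("the SC band outshines the air gap in every frame", {
  cfg <- testPhantomConfig(seed = 12, speckleContrast = 0.4)
  out <- generatePhantomSeries(cfg, testProtocol())
  fr <- frames(out$series)
  mk <- truthMasks(out$truth)
  for (k in seq_len(dim(fr)[3])) {
    inside <- mean(fr[, , k][mk[, , k] == 1L])
    # air region: everything above the top mask row per column
    topRows <- apply(mk[, , k], 2, function(col) min(which(col == 1L)))
    air <- unlist(lapply(seq_along(topRows), function(j) {
      if (topRows[j] > 1) fr[seq_len(topRows[j] - 1L), j, k] else numeric()
    }))
    expect_gt(inside, mean(air))
  }
})

test_that("an indentation exceeding the depth budget is a configuration error", {
  cfg <- testPhantomConfig(k = 0.05)  # delta_max = F/K huge
  expect_error(
    generatePhantomSeries(cfg, testProtocol(pressurePa = 5e4)),
    "configuration error"
  )
})

test_that("the frame dataset is patient-labelled and reproducible", {
  ds <- generatePhantomDataset(nSeries = 3, framesPerSeries = 4,
                               imageSizePx = 64, seed = 3,
                               protocol = testProtocol(pressurePa = 1e4))
  expect_length(ds$images, 12L)
  expect_setequal(unique(ds$patientOf), c("ph01", "ph02", "ph03"))
  expect_identical(dim(ds$images[[1]]), c(64L, 64L))
  ds2 <- generatePhantomDataset(nSeries = 3, framesPerSeries = 4,
                                imageSizePx = 64, seed = 3,
                                protocol = testProtocol(pressurePa = 1e4))
  expect_identical(ds$images, ds2$images)
})
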
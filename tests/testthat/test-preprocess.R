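test_that("grayscale conversion uses luminance weights and preserves range", {
  g <- matrix(runif(24), 4, 6)
  expect_identical(toGrayscale(g), g)

  rgb <- array(0.5, c(4, 6, 3))
  expect_equal(toGrayscale(rgb), matrix(0.5, 4, 6))

  green <- array(0, c(4, 6, 3))
  green[, , 2] <- 1
  expect_equal(toGrayscale(green), matrix(0.587, 4, 6))

  expect_error(toGrayscale(array(0, c(4, 6, 2))), "format error")
})

test_that("centre crop drops odd remainders from the bottom/right", {
  big <- matrix(seq_len(1200 * 1100), 1200, 1100)
  cr <- cropCenter(big, 997)
  expect_identical(dim(cr), c(997L, 997L))
  # 1200 -> margins 101 (top) + 102 (bottom); 1100 -> 51 + 52
  expect_identical(cr[1, 1], big[102, 52])

  same <- matrix(rnorm(997 * 997), 997, 997)
  expect_identical(cropCenter(same, 997), same)

  expect_error(cropCenter(matrix(0, 500, 500), 997), "dimension error")
})

test_that("Gaussian denoise: identity cases and offset commutation", {
  f <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(gaussianDenoise(f, 0), f)

  const <- matrix(0.7, 20, 20)
  expect_equal(gaussianDenoise(const, 2), const, tolerance = 1e-12)

  # commutes with constant offsets: g(f + c) = g(f) + c
  expect_equal(gaussianDenoise(f + 3, 1.5), gaussianDenoise(f, 1.5) + 3,
               tolerance = 1e-12)

  expect_error(gaussianDenoise(f, -1), ">= 0")
})

test_that("Gaussian denoise shrinks white-noise variance by ~1/(4 pi sigma^2)", {
  set.seed(8)
  sigma <- 2
  f <- matrix(rnorm(256 * 256), 256, 256)
  sm <- gaussianDenoise(f, sigma)
  ratio <- var(as.vector(sm)) / var(as.vector(f))
  expect_lt(ratio, 1)
  expect_equal(ratio, 1 / (4 * pi * sigma^2), tolerance = 0.2)
})

test_that("the conditioning chain is deterministic and shape-contracting", {
  set.seed(9)
  fr <- array(runif(1000 * 1000 * 2), c(1000, 1000, 2))
  s <- new("BScanSeries", frames = fr, fps = 10, axialPitchUm = 7.5,
           lateralPitchUm = 10, sourceId = "t")
  a <- preprocessSeries(s, cropPx = 997, sigmaPx = 1)
  b <- preprocessSeries(s, cropPx = 997, sigmaPx = 1)
  expect_identical(dim(frames(a)), c(997L, 997L, 2L))
  expect_identical(frames(a), frames(b))
})
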
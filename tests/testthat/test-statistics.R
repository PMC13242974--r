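test_that("one-way ANOVA matches the hand-expanded decomposition", {
  # frozen toy case: groups {1,2},{3,4},{5,6} -> MSB = 8, MSW = 0.5, F = 16
  toy <- list(c(1, 2), c(3, 4), c(5, 6))
  av <- onewayAnova(toy)
  expect_equal(av$msBetween, 8)
  expect_equal(av$msError, 0.5)
  expect_equal(av$F, 16)
  expect_equal(av$dfError, 3)

  set.seed(101)
  for (rep in 1:20) {
    ng <- sample(2:5, 1)
    groups <- lapply(seq_len(ng), function(i) rnorm(sample(5:20, 1)))
    got <- onewayAnova(groups)
    want <- oracleAnova(groups)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$msError, want$msError, tolerance = 1e-10)
    expect_equal(got$dfError, want$dfError)
  }
})

test_that("identical groups give F = 0, p = 1, and tiny groups error", {
  av <- onewayAnova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(av$F, 0)
  expect_equal(av$p, 1)
  expect_error(onewayAnova(list(1, c(2, 3))), "n >= 2")
  expect_error(onewayAnova(list(c(1, 2))), "2 groups")
})

test_that("LSD contrasts reuse the pooled error term correctly", {
  # hand computation: groups {1,2},{3,4}, MSW = 0.5, df = 4:
  # t = (1.5 - 3.5) / sqrt(0.5 * (1/2 + 1/2)) = -2/sqrt(0.5) = -2.828
  lsd <- lsdPostHoc(list(c(1, 2), c(3, 4)), msError = 0.5, dfError = 4)
  expect_equal(lsd$t[1], -2 / sqrt(0.5), tolerance = 1e-12)

  # identical pair -> zero difference, p = 1
  lsd0 <- lsdPostHoc(list(c(1, 2, 3), c(1, 2, 3)), msError = 1, dfError = 4)
  expect_equal(lsd0$meanDiff[1], 0)
  expect_equal(lsd0$p[1], 1)

  # with 2 groups, LSD p equals the pooled t-test p (same error term)
  set.seed(7)
  x <- rnorm(8)
  y <- rnorm(9, 0.5)
  av <- onewayAnova(list(x, y))
  lsd2 <- lsdPostHoc(list(x, y), av$msError, av$dfError)
  expect_equal(lsd2$p[1], oraclePooledT(x, y)$p, tolerance = 1e-10)
})

test_that("pooled t-test matches the hand oracle and F = t^2 for 2 groups", {
  got <- studentsT(c(1, 2, 3), c(2, 3, 4))
  expect_equal(got$t, -sqrt(3 / 2), tolerance = 1e-10)  # -1.225

  set.seed(11)
  for (rep in 1:20) {
    x <- rnorm(sample(5:15, 1))
    y <- rnorm(sample(5:15, 1), 0.3)
    got <- studentsT(x, y)
    want <- oraclePooledT(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    av <- onewayAnova(list(x, y))
    expect_equal(av$F, want$t^2, tolerance = 1e-10)
    expect_equal(av$p, want$p, tolerance = 1e-10)
  }
  same <- c(1.2, 3.4, 5.6)
  tt <- studentsT(same, same)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
})

test_that("ICC matches the explicit two-way decomposition and its identities", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    k <- sample(2:6, 1)
    m <- matrix(rnorm(n * k), n, k) + rnorm(n)  # subject effect
    got <- iccTwoWayMixed(m)
    want <- oracleIcc(m)
    expect_equal(got@iccSingle, want$single, tolerance = 1e-10)
    expect_equal(got@iccAverage, want$average, tolerance = 1e-10)
    # Spearman-Brown step-up: ICC(3,k) = k r / (1 + (k-1) r)
    r <- got@iccSingle
    expect_equal(got@iccAverage, k * r / (1 + (k - 1) * r), tolerance = 1e-10)
    if (r >= 0) expect_gte(got@iccAverage, got@iccSingle)
    expect_lte(got@ciSingle[1], got@iccSingle)
    expect_gte(got@ciSingle[2], got@iccSingle)
  }
})

test_that("ICC edge behaviour: perfect agreement, pure noise, missing cells", {
  v <- c(1, 3, 5, 9, 2)
  m <- cbind(v, v, v)
  got <- iccTwoWayMixed(m)
  expect_equal(got@iccSingle, 1)
  expect_equal(got@iccAverage, 1)

  set.seed(33)
  noise <- matrix(rnorm(200 * 4), 200, 4)
  got <- iccTwoWayMixed(noise)
  expect_lt(abs(got@iccSingle), 0.05)

  bad <- matrix(c(1, 2, NA, 4), 2, 2)
  expect_error(iccTwoWayMixed(bad), "missing cells")
})

test_that("Cohen's d matches the pooled-SD oracle with sane intervals", {
  # hand case: x = {0,2}, y = {1,3}: s_pooled = sqrt(2), d = -1/sqrt(2)
  es <- cohensD(c(0, 2), c(1, 3))
  expect_equal(es@cohensD, -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(es@meanDifference, -1)

  set.seed(41)
  for (rep in 1:15) {
    x <- rnorm(sample(5:20, 1))
    y <- rnorm(sample(5:20, 1), 1)
    es <- cohensD(x, y)
    expect_equal(es@cohensD, oracleCohensD(x, y), tolerance = 1e-10)
    expect_lte(es@ci95[1], es@meanDifference)
    expect_gte(es@ci95[2], es@meanDifference)
    expect_lte(es@ciD[1], es@cohensD)
    expect_gte(es@ciD[2], es@cohensD)
  }

  # large-sample recovery of a one-SD true shift
  set.seed(43)
  x <- rnorm(10000, 1)
  y <- rnorm(10000, 0)
  expect_lt(abs(cohensD(x, y)@cohensD - 1), 0.05)

  expect_error(cohensD(c(1, 1), c(2, 2)), "undefined-d")
  expect_equal(cohensD(c(3, 3), c(3, 3))@cohensD, 0)
})

test_that("Pearson correlation matches the product-moment oracle", {
  expect_equal(pearsonCorrelation(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearsonCorrelation(1:5, -(1:5))$r, -1)
  expect_equal(pearsonCorrelation(1:4, c(1, 3, 2, 4))$r, 0.8, tolerance = 1e-12)

  set.seed(51)
  for (rep in 1:15) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    got <- pearsonCorrelation(x, y)
    r <- oraclePearson(x, y)
    expect_equal(got$r, r, tolerance = 1e-10)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(got$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-10)
  }
  expect_error(pearsonCorrelation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearsonCorrelation(1:2, 1:2), "n >= 3")
})
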
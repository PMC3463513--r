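# Error-weighted line fits, parameter tests and fold-change curves.

test_that("collinear points are recovered exactly with zero chi-square", {
  x <- 0:4
  y <- 1.5 + 0.3 * x
  f <- weightedLineFit(x, y, rep(1, 5))
  expect_equal(slope(f), 0.3, tolerance = 1e-12)
  expect_equal(intercept(f), 1.5, tolerance = 1e-12)
  expect_equal(f@chisq, 0, tolerance = 1e-12)
})

test_that("the three-point worked example matches the closed-form sums", {
  x <- c(0, 1, 2); y <- c(1, 2, 2); s <- c(1, 1, 2)
  f <- weightedLineFit(x, y, s)
  # evaluate the normal-equation sums independently
  w <- 1 / s^2
  S <- sum(w); Sx <- sum(w * x); Sy <- sum(w * y)
  Sxx <- sum(w * x^2); Sxy <- sum(w * x * y)
  D <- S * Sxx - Sx^2
  expect_equal(slope(f), (S * Sxy - Sx * Sy) / D)
  expect_equal(intercept(f), (Sxx * Sy - Sx * Sxy) / D)
  expect_equal(f@seSlope, sqrt(S / D))
  expect_equal(f@seIntercept, sqrt(Sxx / D))
})

test_that("rescaling all sigmas leaves the line and scales the errors", {
  set.seed(2)
  x <- runif(6, 0, 100); y <- 0.1 + 0.002 * x + rnorm(6, 0, 0.01)
  s <- runif(6, 0.005, 0.02)
  f1 <- weightedLineFit(x, y, s)
  f2 <- weightedLineFit(x, y, 3 * s)
  expect_equal(slope(f2), slope(f1))
  expect_equal(intercept(f2), intercept(f1))
  expect_equal(f2@seSlope, 3 * f1@seSlope)
  expect_equal(f2@seIntercept, 3 * f1@seIntercept)
})

test_that("the fit matches an independent chi-square minimiser", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    x <- runif(n, 0, 100)
    y <- rnorm(n, 0.5 + 0.01 * x, 0.1)
    s <- runif(n, 0.02, 0.3)
    f <- weightedLineFit(x, y, s)
    o <- gridLineFitOracle(x, y, s)
    expect_equal(slope(f), o$slope, tolerance = 1e-6)
    expect_equal(intercept(f), o$intercept, tolerance = 1e-6)
    expect_equal(f@seSlope, o$seSlope, tolerance = 1e-4)
    expect_equal(f@seIntercept, o$seIntercept, tolerance = 1e-4)
  }
})

test_that("degenerate fit inputs are rejected", {
  expect_error(weightedLineFit(1:2, 1:2, c(1, 1)), "3 points")
  expect_error(weightedLineFit(rep(1, 4), 1:4, rep(1, 4)), "identical")
  expect_message(f <- weightedLineFit(c(1:4, 5), c(1:4, 99),
                                      c(rep(1, 4), NA)), "dropped")
  expect_equal(f@n, 4L)
})

test_that("two-line comparisons use t = diff/sqrt(se^2+se^2) and df = n1+n2-4", {
  fA <- new("LineFit", slope = 2, intercept = 0.5, seSlope = 0.1,
            seIntercept = 0.2, n = 10L, chisq = 5)
  fB <- new("LineFit", slope = 1, intercept = 0.5, seSlope = 0.1,
            seIntercept = 0.2, n = 10L, chisq = 7)
  r <- compareLineParams(fA, fB, "slope")
  expect_equal(r$df, 16)
  expect_equal(r$t, 1 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-1 / sqrt(0.02), 16))

  same <- compareLineParams(fA, fA, "slope")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # antisymmetry: swapping the lines flips t, keeps p
  r2 <- compareLineParams(fB, fA, "slope")
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
})

test_that("null tests use df = n - 2 and the stated t", {
  f <- new("LineFit", slope = 0.004, intercept = 1.5, seSlope = 0.002,
           seIntercept = 0.25, n = 10L, chisq = 3)
  r <- testParamNull(f, "intercept", nullValue = 1)
  expect_equal(r$df, 8)
  expect_equal(r$t, 2)
  expect_equal(r$p, 2 * pt(-2, 8))

  z <- new("LineFit", slope = 0, intercept = 1, seSlope = 0.01,
           seIntercept = 0.01, n = 5L, chisq = 0)
  r0 <- testParamNull(z, "slope", 0)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
})

test_that("fold-change curves follow the delta method and drop bad bins", {
  a <- data.frame(x = c(10, 30, 50), y = c(0.4, 0.4, 0.4),
                  sigma = c(0.04, 0.04, 0.04))
  b <- data.frame(x = c(10, 30, 50), y = c(0.2, 0.2, 0),
                  sigma = c(0.02, 0.02, 0.02))
  fc <- suppressMessages(foldChangeCurve(a, b))
  expect_equal(nrow(fc), 2L)   # zero-denominator bin dropped
  expect_equal(fc$ratio, c(2, 2))
  expect_equal(fc$se, rep(2 * sqrt(0.01 + 0.01), 2), tolerance = 1e-12)

  # identical series: all ratios exactly 1
  fcI <- foldChangeCurve(a, a)
  expect_equal(fcI$ratio, rep(1, 3))

  expect_error(foldChangeCurve(a, transform(a, x = x + 5)), "identical bins")
  allBad <- transform(b, y = 0)
  expect_error(suppressMessages(foldChangeCurve(a, allBad)), "no common")
})
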
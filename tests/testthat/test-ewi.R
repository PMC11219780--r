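test_that("row standardization yields exact population moments", {
  y <- standardizeRows(matrix(c(1, 2, 3), 1))
  expect_equal(as.vector(y), c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
  set.seed(4)
  x <- matrix(rnorm(50), 5, 10)
  y2 <- standardizeRows(x)
  expect_equal(unname(rowMeans(y2)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(sqrt(rowMeans(y2^2))), rep(1, 5), tolerance = 1e-10)
  # idempotence and affine invariance (positive scale)
  expect_equal(standardizeRows(y2), y2, tolerance = 1e-10)
  expect_equal(standardizeRows(3.7 * x + 11), y2, tolerance = 1e-10)
  expect_error(standardizeRows(matrix(c(5, 5, 5), 1,
                                      dimnames = list("HB", NULL))), "HB")
})

test_that("column skewness matches the population-moment definition", {
  expect_equal(columnSkewness(matrix(c(-1, 0, 1), 3)), 0)
  expect_equal(columnSkewness(matrix(c(0, 0, 1), 3)), 1 / sqrt(2))
  set.seed(6)
  col <- rnorm(9)
  expect_equal(columnSkewness(matrix(-col, 9)),
               -columnSkewness(matrix(col, 9)), tolerance = 1e-12)
  # moment oracle
  m3 <- mean((col - mean(col))^3)
  m2 <- mean((col - mean(col))^2)
  expect_equal(unname(columnSkewness(matrix(col, 9))), m3 / m2^1.5,
               tolerance = 1e-12)
  expect_error(columnSkewness(matrix(1:2, 2)), "at least 3")
})

test_that("the EWI is zero when the standardized column mean is zero", {
  # every row standardizes to (-a, 0, a) or (a, 0, -a): column 2 of the
  # score matrix is exactly zero, so ybar = 0 and EWI = 0 whatever the
  # skewness guard does
  x <- rbind(m1 = c(1, 2, 3), m2 = c(3, 2, 1), m3 = c(10, 20, 30))
  s <- computeEWI(x)
  expect_equal(s@ybar[2], 0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(s@ewi[2], 0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the EWI is invariant to positive-scale affine marker transforms", {
  set.seed(10)
  for (trial in 1:10) {
    x <- matrix(rnorm(7 * 40), 7, 40)
    a <- runif(7, 0.5, 4)
    b <- rnorm(7, 0, 10)
    e1 <- computeEWI(x)
    e2 <- computeEWI(x * a + b)
    expect_equal(e2@ewi, e1@ewi, tolerance = 1e-8)
  }
})

test_that("permuting samples permutes the EWI identically", {
  set.seed(11)
  x <- matrix(rnorm(7 * 25), 7, 25,
              dimnames = list(paste0("m", 1:7), paste0("s", 1:25)))
  perm <- sample(25)
  expect_equal(unname(computeEWI(x[, perm])@ewi),
               unname(computeEWI(x)@ewi[perm]), tolerance = 1e-10)
})

test_that("near-zero skewness saturates under the division guard", {
  x <- rbind(c(-1, 5), c(0, 6), c(1, 7), c(-1, 5), c(0, 6), c(1, 7))
  # column 1 of the standardized scores is symmetric: skewness ~ 0
  s <- computeEWI(x, epsilon = 1e-8)
  expect_true(any(s@saturated))
  expect_true(all(is.finite(s@ewi)))
})

test_that("warning flags follow the robust median/MAD rule", {
  base <- rep(c(-1, 1), 20)               # constant spread, median 0, MAD 1
  series <- new("EWISeries", sampleIDs = sprintf("s%02d", 1:41),
                ybar = numeric(41), skew = numeric(41),
                ewi = c(base, 25), saturated = logical(41),
                epsilon = 1e-8, flagged = integer(0), flagK = NA_real_,
                flagMethod = "none")
  out <- flagWarnings(series, k = 3)
  expect_identical(flaggedSamples(out), 41L)
  expect_identical(out@flagMethod, "mad")

  none <- flagWarnings(series, k = Inf)
  expect_length(flaggedSamples(none), 0)

  const <- series; const@ewi <- rep(2, 41)
  expect_length(flaggedSamples(flagWarnings(const, 3)), 0)
})

test_that("a single strong spike in unit noise is the only flag", {
  set.seed(12)
  e <- rnorm(60)
  med <- stats::median(e); MAD <- stats::mad(e)
  e[17] <- med + 10 * MAD
  series <- new("EWISeries", sampleIDs = sprintf("s%02d", 1:60),
                ybar = numeric(60), skew = numeric(60), ewi = e,
                saturated = logical(60), epsilon = 1e-8,
                flagged = integer(0), flagK = NA_real_, flagMethod = "none")
  fl <- flaggedSamples(flagWarnings(series, k = 3))
  expect_true(17L %in% fl)
  expect_lte(length(fl), 3)   # unit normal noise rarely crosses 3 MAD
})

test_that("the outcome curve has one value per sample and zero CV when
           constant", {
  ie <- tiny_cohort()
  glu <- outcomeCurve(ie)
  expect_length(glu, 6)
  expect_identical(names(glu), sampleIDs(ie))
  fc <- fluctuationContrast(rep(1, 6), rep(4.2, 6))
  expect_equal(fc$cvOutcome, 0)
})
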
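test_that("initialisation is seed-deterministic with the contracted shapes", {
  a <- initNetwork(28, 10, 1, seed = 7)
  b <- initNetwork(28, 10, 1, seed = 7)
  expect_identical(a, b)
  expect_identical(dim(a@W), c(10L, 28L))
  expect_identical(dim(a@Wout), c(1L, 10L))
  z <- initNetwork(3, 2, 1, seed = 1, initScale = 0)
  expect_true(all(z@W == 0) && all(z@theta == 0) && all(z@Wout == 0) &&
                all(z@alpha == 0))
  expect_error(initNetwork(0, 2, 1), ">= 1")
})

test_that("the forward pass reproduces the layer equations", {
  # all-zero logistic network: every activation is phi(0) = 0.5
  z <- initNetwork(3, 4, 1, seed = 1, initScale = 0,
                   hiddenTransfer = "logistic")
  fw <- forwardPass(z, c(1, 2, 3))
  expect_equal(unname(fw$HO[1, ]), rep(0.5, 4))
  expect_equal(unname(fw$O[1, 1]), 0.5)

  # single hidden node, W = 1, theta = 0, x = 0
  m1 <- new("BPNetwork", W = matrix(1, 1, 1), theta = 0,
            Wout = matrix(0, 1, 1), alpha = 0,
            hiddenTransfer = "logistic", outputTransfer = "logistic")
  fw1 <- forwardPass(m1, 0)
  expect_equal(unname(fw1$HI[1, 1]), 0)
  expect_equal(unname(fw1$HO[1, 1]), 0.5)

  expect_error(forwardPass(z, c(1, 2)), "expects")
})

test_that("forward pass agrees with a straight-line oracle to 1e-12", {
  for (seed in 1:5) {
    m <- initNetwork(3, 4, 1, seed = seed, initScale = 0.8)
    set.seed(seed + 100)
    x <- rnorm(3)
    got <- forwardPass(m, x)
    want <- oracle_forward(m@W, m@theta, m@Wout, m@alpha, x)
    expect_equal(unname(got$HI[1, ]), want$HI, tolerance = 1e-12)
    expect_equal(unname(got$HO[1, ]), want$HO, tolerance = 1e-12)
    expect_equal(unname(got$O[1, ]), want$O, tolerance = 1e-12)
  }
})

test_that("logistic transfers keep every node activation inside (0, 1)", {
  m <- initNetwork(5, 6, 1, seed = 3, initScale = 1,
                   hiddenTransfer = "logistic")
  set.seed(4)
  X <- matrix(rnorm(50, sd = 2), 10, 5)
  fw <- forwardPass(m, X)
  expect_true(all(fw$HO > 0 & fw$HO < 1))
  expect_true(all(fw$O > 0 & fw$O < 1))
})

test_that("the half-squared error matches its definition and scales
           quadratically", {
  expect_equal(geError(c(1, 2), c(1, 2))$aggregate, 0)
  expect_equal(geError(1, 0)$perSample, 0.5)
  # two samples: GE = mean(0.5*0.2^2, 0.5*0.4^2) = 0.05
  ge <- geError(c(0.2, 0.9), c(0.4, 0.5))
  expect_equal(ge$aggregate, 0.05)
  set.seed(1)
  O <- runif(5); D <- runif(5)
  expect_equal(geError(3 * O, 3 * D)$aggregate,
               9 * geError(O, D)$aggregate, tolerance = 1e-12)
  expect_error(geError(numeric(0), numeric(0)), "empty")
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:5) {
    m <- initNetwork(5, 4, 1, seed = seed, initScale = 0.5)
    set.seed(seed + 50)
    X <- matrix(runif(40), 8, 5)
    y <- runif(8)
    ana <- geGradient(m, X, y)
    num <- numeric_gradient(m, X, y)
    for (part in names(ana)) {
      denom <- pmax(abs(num[[part]]), 1e-8)
      expect_lt(max(abs(ana[[part]] - num[[part]]) / denom), 1e-5)
    }
  }
})

test_that("training with zero epochs returns the initial network", {
  set.seed(2)
  X <- matrix(runif(30), 10, 3)
  y <- runif(10)
  cfg <- bpnnControl(maxEpochs = 0, seed = 5)
  fit <- trainNetwork(X, cfg, y = y)
  expect_identical(networkModel(fit)@W,
                   `colnames<-`(initNetwork(3, 10, 1, seed = 5,
                                            initScale = 0.05)@W,
                                colnames(networkModel(fit)@W)))
  expect_length(geTrace(fit), 0)
})

test_that("a constant target is learned to GE below 1e-4", {
  set.seed(3)
  X <- matrix(runif(60), 30, 2)
  y <- rep(0.3, 30)
  fit <- trainNetwork(X, bpnnControl(maxEpochs = 2000, seed = 1), y = y)
  expect_lt(fit@finalGE, 1e-4)
})

test_that("training is seed-deterministic and longer training never raises
           the best error", {
  set.seed(6)
  X <- matrix(runif(80), 20, 4)
  y <- plogis(X[, 1] - 0.5 * X[, 3])
  f1 <- trainNetwork(X, bpnnControl(maxEpochs = 300, seed = 9), y = y)
  f2 <- trainNetwork(X, bpnnControl(maxEpochs = 300, seed = 9), y = y)
  expect_identical(networkModel(f1), networkModel(f2))
  f4 <- trainNetwork(X, bpnnControl(maxEpochs = 600, seed = 9), y = y)
  expect_lte(min(geTrace(f4)), min(geTrace(f1)))
  expect_lte(f1@finalGE, geTrace(f1)[1])     # improves on the initial error
})

test_that("unscaled targets are rejected with a logistic output", {
  X <- matrix(runif(20), 10, 2)
  expect_error(trainNetwork(X, bpnnControl(), y = rnorm(10, 5)), "\\[0, 1\\]")
})

test_that("the Levenberg-Marquardt optimizer minimises the same objective", {
  set.seed(8)
  X <- matrix(runif(120), 60, 2)
  y <- plogis(2 * X[, 1] - X[, 2])
  gdm <- trainNetwork(X, bpnnControl(hiddenDim = 3, maxEpochs = 200,
                                     seed = 2), y = y)
  lm <- trainNetwork(X, bpnnControl(hiddenDim = 3, maxEpochs = 200, seed = 2,
                                    optimizer = "lm"), y = y)
  expect_lt(lm@finalGE, geTrace(gdm)[1])   # improves on the initial error
  expect_lte(lm@finalGE, gdm@finalGE + 1e-6)
  # too few samples for the parameter count is rejected with advice
  expect_error(trainNetwork(X[1:10, ], bpnnControl(optimizer = "lm"),
                            y = y[1:10]), "gdm")
})

test_that("predictions agree with the forward pass and respect the
           zero-weight degenerate case", {
  ie <- minMaxScale(tiny_cohort())
  fit <- trainNetwork(ie, bpnnControl(maxEpochs = 50, seed = 1))
  pred <- predictNetwork(fit, ie)
  fw <- forwardPass(networkModel(fit), inputMatrix(ie))
  expect_equal(unname(pred$predictions), as.vector(fw$O), tolerance = 1e-12)
  expect_length(pred$relativeErrors, 6)

  m0 <- networkModel(fit)
  m0@Wout[] <- 0
  p0 <- predictNetwork(m0, inputMatrix(ie))
  expect_equal(unname(diff(range(p0$predictions))), 0)
})

test_that("relative errors near a converged constant fit are about zero", {
  set.seed(3)
  X <- matrix(runif(40), 20, 2)
  y <- rep(0.4, 20)
  fit <- trainNetwork(X, bpnnControl(maxEpochs = 2000, seed = 1), y = y)
  pred <- predictNetwork(fit, X, targets = y)
  expect_lt(max(abs(pred$relativeErrors)), 0.05)
})

test_that("importance scores are the column-wise absolute weight sums", {
  m <- initNetwork(3, 3, 1, seed = 1, initScale = 0)
  m@W <- diag(3)
  expect_equal(unname(inputWeightProfile(m)$importance), rep(1, 3))
  m@W[, 2] <- 0
  expect_equal(unname(inputWeightProfile(m)$importance)[2], 0)

  set.seed(9)
  W <- matrix(rnorm(12), 4, 3)
  m2 <- as_network(W)
  expect_equal(unname(inputWeightProfile(m2)$importance),
               apply(W, 2, function(col) sum(abs(col))))
  g <- inputWeightProfile(m2, method = "garson")$importance
  expect_equal(sum(g), 1)
  expect_true(all(g >= 0))
})
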
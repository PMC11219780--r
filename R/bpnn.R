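#' @include AllClasses.R AllGenerics.R
NULL

.transfer <- function(name) {
  switch(name,
    logistic = list(f = function(z) 1 / (1 + exp(-z)),
                    # derivative expressed in the activation a = f(z)
                    df = function(a) a * (1 - a)),
    tanh = list(f = tanh, df = function(a) 1 - a^2),
    stop("unknown transfer function: ", name))
}

#' Training configuration for the backpropagation network
#'
#' Defaults: 10 hidden nodes, batch gradient descent with momentum 0.9 and
#' learning rate 0.1, at most 750 epochs or until the aggregate half-squared
#' error falls below `targetError`, parameters initialised uniformly in
#' `[-initScale, initScale]`. These defaults target prediction accuracy
#' (regression use). When the goal is marker detection, gentler
#' early-stopped settings are preferable -- early stopping acts as implicit
#' ridge-like regularisation that keeps the weights of mutually correlated
#' (redundant) indicators even, which the downstream weight-profile
#' clustering relies on; [runPipeline()] therefore uses
#' `bpnnControl(hiddenDim = 15, maxEpochs = 1500, learningRate = 0.02,
#' initScale = 0.03)` by default. See the package vignette.
#'
#' @param hiddenDim number of hidden nodes.
#' @param maxEpochs maximum training epochs (0 returns the initial network).
#' @param learningRate gradient-descent step size.
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param targetError stop when aggregate GE falls to this value.
#' @param initScale half-width of the uniform initialisation interval.
#' @param seed RNG seed for initialisation (reproducibility).
#' @param hiddenTransfer,outputTransfer `"tanh"` or `"logistic"`.
#' @param optimizer `"gdm"` (gradient descent with momentum, default) or
#'   `"lm"` (Levenberg-Marquardt via \pkg{minpack.lm}).
#' @return a list of class `bpnnControl`.
#' @export
bpnnControl <- function(hiddenDim = 10L, maxEpochs = 750L, learningRate = 0.1,
                        momentum = 0.9, targetError = 1e-4, initScale = 0.05,
                        seed = 1L, hiddenTransfer = "tanh",
                        outputTransfer = "logistic",
                        optimizer = c("gdm", "lm")) {
  stopifnot(hiddenDim >= 1L, maxEpochs >= 0L, learningRate > 0,
            momentum >= 0, momentum < 1, targetError > 0, initScale >= 0)
  structure(list(hiddenDim = as.integer(hiddenDim),
                 maxEpochs = as.integer(maxEpochs),
                 learningRate = learningRate, momentum = momentum,
                 targetError = targetError, initScale = initScale,
                 seed = as.integer(seed), hiddenTransfer = hiddenTransfer,
                 outputTransfer = outputTransfer,
                 optimizer = match.arg(optimizer)),
            class = "bpnnControl")
}

#' Initialise a three-layer network
#'
#' Weights and thresholds are drawn uniformly in `[-initScale, initScale]`
#' from the seeded generator, in the fixed order W, theta, Wout, alpha, so a
#' given seed yields a bitwise-identical model.
#'
#' @param inputDim,hiddenDim,outputDim layer sizes (all `>= 1`).
#' @param seed RNG seed.
#' @param initScale half-width of the initialisation interval; 0 gives an
#'   all-zero network.
#' @param hiddenTransfer,outputTransfer transfer selections.
#' @return a [BPNetwork-class].
#' @examples
#' m <- initNetwork(28, 10, 1, seed = 1)
#' dim(m@W)  # 10 x 28
#' @export
initNetwork <- function(inputDim, hiddenDim, outputDim = 1L, seed = 1L,
                        initScale = 0.05, hiddenTransfer = "tanh",
                        outputTransfer = "logistic") {
  if (inputDim < 1L || hiddenDim < 1L || outputDim < 1L)
    stop("all layer dimensions must be >= 1")
  set.seed(seed)
  W <- matrix(stats::runif(hiddenDim * inputDim, -initScale, initScale),
              hiddenDim, inputDim)
  theta <- stats::runif(hiddenDim, -initScale, initScale)
  Wout <- matrix(stats::runif(outputDim * hiddenDim, -initScale, initScale),
                 outputDim, hiddenDim)
  alpha <- stats::runif(outputDim, -initScale, initScale)
  new("BPNetwork", W = W, theta = theta, Wout = Wout, alpha = alpha,
      hiddenTransfer = hiddenTransfer, outputTransfer = outputTransfer)
}

#' Forward pass through the network
#'
#' Computes, for each sample, the hidden pre-activations
#' `HI_i = sum_j W_ij x_j + theta_i`, the hidden outputs `HO_i = phi(HI_i)`,
#' and the network output `O_k = phi(sum_i Wout_ki HO_i + alpha_k)`, where
#' `phi` is the logistic function `1 / (1 + exp(-x))` or `tanh` per layer.
#'
#' @param model a [BPNetwork-class].
#' @param x input vector of length `inputDim`, or a samples x inputDim
#'   matrix.
#' @return a list with elements `HI`, `HO` (samples x hidden) and `O`
#'   (samples x outputs); for a single vector input, one-row matrices.
#' @export
forwardPass <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model@W))
    stop("input has ", ncol(x), " columns but the network expects ",
         ncol(model@W))
  if (!all(is.finite(x))) stop("inputs must be finite")
  h <- .transfer(model@hiddenTransfer)
  o <- .transfer(model@outputTransfer)
  HI <- x %*% t(model@W) + matrix(model@theta, nrow(x), nrow(model@W),
                                  byrow = TRUE)
  HO <- h$f(HI)
  O <- o$f(HO %*% t(model@Wout) + matrix(model@alpha, nrow(x),
                                         nrow(model@Wout), byrow = TRUE))
  list(HI = HI, HO = HO, O = O)
}

#' Half-squared prediction error, per sample and aggregate
#'
#' `GE_p = 0.5 * sum_k (O_k(x_p) - D_k(x_p))^2` per sample, and the
#' aggregate `GE` is the mean of `GE_p` over the evaluated samples.
#'
#' @param predictions,targets numeric vectors, or samples x outputs matrices.
#' @return list with `perSample` and `aggregate`.
#' @examples
#' geError(1, 0)$perSample  # 0.5
#' @export
geError <- function(predictions, targets) {
  O <- if (is.null(dim(predictions))) matrix(predictions, ncol = 1) else predictions
  D <- if (is.null(dim(targets))) matrix(targets, ncol = 1) else targets
  if (!identical(dim(O), dim(D))) stop("predictions/targets shape mismatch")
  if (nrow(O) == 0L) stop("empty prediction set")
  if (!all(is.finite(O)) || !all(is.finite(D))) stop("values must be finite")
  gep <- 0.5 * rowSums((O - D)^2)
  list(perSample = gep, aggregate = mean(gep))
}

## Analytic gradient of the aggregate GE w.r.t. all parameters (batch).
## Exposed for finite-difference verification.

#' Analytic backpropagation gradient of the aggregate error
#'
#' Returns the gradient of `GE = mean_p GE_p` with respect to every
#' parameter of the network, computed by backpropagation. Used internally by
#' [trainNetwork()]; exported so the gradient can be verified against
#' central finite differences.
#'
#' @param model a [BPNetwork-class].
#' @param x samples x inputDim matrix.
#' @param y targets (vector or samples x outputs matrix).
#' @return list with elements `W`, `theta`, `Wout`, `alpha`.
#' @export
geGradient <- function(model, x, y) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  n <- nrow(x)
  h <- .transfer(model@hiddenTransfer)
  o <- .transfer(model@outputTransfer)
  fw <- forwardPass(model, x)
  err <- fw$O - y                       # n x K
  dOut <- err * o$df(fw$O) / n          # n x K : dGE/d(output pre-activation)
  gWout <- t(dOut) %*% fw$HO            # K x H
  galpha <- colSums(dOut)
  dHid <- (dOut %*% model@Wout) * h$df(fw$HO)   # n x H
  gW <- t(dHid) %*% x                   # H x p
  gtheta <- colSums(dHid)
  list(W = gW, theta = gtheta, Wout = gWout, alpha = galpha)
}

.train_gdm <- function(model, X, y, cfg) {
  vW <- model@W * 0; vth <- model@theta * 0
  vV <- model@Wout * 0; val <- model@alpha * 0
  trace <- numeric(0)
  for (e in seq_len(cfg$maxEpochs)) {
    fw <- forwardPass(model, X)
    ge <- geError(fw$O, y)$aggregate
    if (!is.finite(ge))
      stop("training diverged (non-finite loss) at epoch ", e)
    trace[e] <- ge
    if (ge <= cfg$targetError) break
    g <- geGradient(model, X, y)
    vW <- cfg$momentum * vW - cfg$learningRate * g$W
    vth <- cfg$momentum * vth - cfg$learningRate * g$theta
    vV <- cfg$momentum * vV - cfg$learningRate * g$Wout
    val <- cfg$momentum * val - cfg$learningRate * g$alpha
    model@W <- model@W + vW
    model@theta <- model@theta + vth
    model@Wout <- model@Wout + vV
    model@alpha <- model@alpha + val
  }
  list(model = model, trace = trace)
}

.train_lm <- function(model, X, y, cfg) {
  if (nrow(model@Wout) != 1L)
    stop("the Levenberg-Marquardt optimizer supports a single output node")
  H <- nrow(model@W); p <- ncol(model@W); n <- nrow(X)
  npar <- H * p + 2L * H + 1L
  if (n < npar)
    stop("Levenberg-Marquardt needs at least as many samples as parameters (",
         npar, "); reduce hiddenDim or use optimizer = 'gdm'")
  hT <- .transfer(model@hiddenTransfer); oT <- .transfer(model@outputTransfer)
  pack <- function(m) c(as.vector(m@W), m@theta, as.vector(m@Wout), m@alpha)
  unpack <- function(par) {
    model@W <- matrix(par[seq_len(H * p)], H, p)
    model@theta <- par[H * p + seq_len(H)]
    model@Wout <- matrix(par[H * p + H + seq_len(H)], 1, H)
    model@alpha <- par[H * p + 2 * H + 1L]
    model
  }
  resid <- function(par) {
    fw <- forwardPass(unpack(par), X)
    as.vector(fw$O) - y
  }
  jacf <- function(par) {
    m <- unpack(par)
    fw <- forwardPass(m, X)
    dphi <- oT$df(as.vector(fw$O))
    J <- matrix(0, n, length(par))
    dHO <- hT$df(fw$HO)
    for (i in seq_len(H)) {
      J[, (i - 1L) * p + seq_len(p)] <- dphi * m@Wout[1, i] * dHO[, i] * X
      J[, H * p + i] <- dphi * m@Wout[1, i] * dHO[, i]
      J[, H * p + H + i] <- dphi * fw$HO[, i]
    }
    J[, length(par)] <- dphi
    J
  }
  fit <- minpack.lm::nls.lm(pack(model), fn = resid, jac = jacf,
                            control = minpack.lm::nls.lm.control(
                              maxiter = min(cfg$maxEpochs, 1024L),
                              ftol = 2 * cfg$targetError))
  list(model = unpack(fit$par), trace = fit$rsstrace / (2 * n))
}

#' Train the network by backpropagation
#'
#' Batch gradient descent with momentum (default) minimising the aggregate
#' half-squared error GE; stops at `maxEpochs` or when GE reaches
#' `targetError`. A Levenberg-Marquardt optimizer is available via
#' `bpnnControl(optimizer = "lm")`. Training is fully reproducible for a
#' fixed configuration (the seed drives initialisation; the optimisation is
#' deterministic).
#'
#' @param x an [IndicatorExperiment-class] (scaled; its non-outcome
#'   indicators are the inputs and the outcome column the target) or a
#'   samples x inputs numeric matrix.
#' @param config a [bpnnControl()] list.
#' @param y targets in `[0, 1]` when `x` is a matrix; ignored otherwise.
#' @return a [BPNetworkFit-class].
#' @examples
#' X <- matrix(runif(60), 20, 3)
#' y <- plogis(X[, 1] - X[, 2])
#' fit <- trainNetwork(X, bpnnControl(maxEpochs = 50), y = y)
#' @export
trainNetwork <- function(x, config = bpnnControl(), y = NULL) {
  if (is(x, "IndicatorExperiment")) {
    if (any(missingMask(x))) stop("impute missing values before training")
    X <- inputMatrix(x)
    y <- outcomeVector(x)
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop("targets 'y' required when x is a matrix")
  }
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(x)")
  if (config$outputTransfer == "logistic" && (min(y) < 0 || max(y) > 1))
    stop("logistic output requires targets in [0, 1]; scale the data first")
  model <- initNetwork(ncol(X), config$hiddenDim, 1L, seed = config$seed,
                       initScale = config$initScale,
                       hiddenTransfer = config$hiddenTransfer,
                       outputTransfer = config$outputTransfer)
  colnames(model@W) <- colnames(X)
  res <- if (config$maxEpochs == 0L) list(model = model, trace = numeric(0))
         else if (config$optimizer == "lm") .train_lm(model, X, y, config)
         else .train_gdm(model, X, y, config)
  fw <- forwardPass(res$model, X)
  ge <- geError(fw$O, y)
  new("BPNetworkFit", model = res$model, geTrace = res$trace,
      finalGE = ge$aggregate, perSampleGE = ge$perSample,
      predictions = as.vector(fw$O), config = unclass(config))
}

#' Predict with a trained network and report per-sample relative errors
#'
#' @param model a [BPNetwork-class] or [BPNetworkFit-class].
#' @param newdata an [IndicatorExperiment-class] or samples x inputs matrix.
#' @param targets optional true outcome values; taken from the outcome
#'   column when `newdata` is an `IndicatorExperiment`.
#' @return list with `predictions` and, when targets are available,
#'   `relativeErrors` (`(O - D) / D`; the absolute error is reported where
#'   `|D| < 1e-8`).
#' @export
predictNetwork <- function(model, newdata, targets = NULL) {
  if (is(model, "BPNetworkFit")) model <- model@model
  if (is(newdata, "IndicatorExperiment")) {
    X <- inputMatrix(newdata)
    if (is.null(targets)) targets <- outcomeVector(newdata)
  } else X <- as.matrix(newdata)
  O <- as.vector(forwardPass(model, X)$O)
  out <- list(predictions = stats::setNames(O, rownames(X)))
  if (!is.null(targets)) {
    small <- abs(targets) < 1e-8
    re <- (O - targets) / ifelse(small, 1, targets)
    out$relativeErrors <- stats::setNames(re, rownames(X))
  }
  out
}

#' @describeIn predictNetwork S4 `predict` method for a fitted network.
#' @param object a [BPNetworkFit-class].
#' @param ... passed on to [predictNetwork()].
#' @export
setMethod("predict", "BPNetworkFit", function(object, newdata, ...) {
  predictNetwork(object, newdata, ...)
})

#' Per-indicator input-to-hidden weight profiles and importance scores
#'
#' For indicator `j`, the profile is column `j` of the input-to-hidden
#' weight matrix `W`, and the default importance scalar is the sum of the
#' absolute weights in that column. Garson's algorithm (which additionally
#' weighs each hidden node by its absolute output weight and normalises) is
#' available as an alternative.
#'
#' @param model a [BPNetwork-class] or [BPNetworkFit-class].
#' @param method `"abssum"` (default) or `"garson"`.
#' @return list with `profiles` (hidden x indicators matrix, columns named
#'   by indicator) and `importance` (named numeric).
#' @export
inputWeightProfile <- function(model, method = c("abssum", "garson")) {
  method <- match.arg(method)
  if (is(model, "BPNetworkFit")) model <- model@model
  W <- model@W
  if (is.null(colnames(W)))
    colnames(W) <- sprintf("I%02d", seq_len(ncol(W)))
  imp <- if (method == "abssum") {
    colSums(abs(W))
  } else {
    # Garson: contribution of input j through hidden i, scaled by |Wout_i|
    Q <- abs(W) / pmax(rowSums(abs(W)), .Machine$double.eps)
    contrib <- colSums(Q * abs(as.vector(model@Wout[1, ])))
    contrib / sum(contrib)
  }
  list(profiles = W, importance = imp)
}
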
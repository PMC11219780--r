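# small fixture builders and independent oracles shared across test files

make_ie <- function(values, outcome = "GLU") {
  IndicatorExperiment(values, outcomeName = outcome)
}

# a tiny complete cohort: 6 samples x 3 indicators (incl. outcome)
tiny_cohort <- function() {
  m <- matrix(c(1, 2, 5,
                2, 4, 6,
                3, 6, 7,
                4, 8, 8,
                5, 10, 9,
                6, 12, 10), 6, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:6), c("A", "B", "GLU")))
  make_ie(m)
}

# straight-line forward oracle, written independently of forwardPass()
oracle_forward <- function(W, theta, Wout, alpha, x,
                           hidden = "tanh", output = "logistic") {
  phi <- function(z, kind) if (kind == "logistic") 1 / (1 + exp(-z)) else tanh(z)
  HI <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) HI[i] <- sum(W[i, ] * x) + theta[i]
  HO <- phi(HI, hidden)
  O <- numeric(nrow(Wout))
  for (k in seq_len(nrow(Wout))) O[k] <- phi(sum(Wout[k, ] * HO) + alpha[k],
                                             output)
  list(HI = HI, HO = HO, O = O)
}

# numeric central-difference gradient of the aggregate GE
numeric_gradient <- function(model, X, y, h = 1e-6) {
  ge_of <- function(m) geError(forwardPass(m, X)$O, y)$aggregate
  grad_mat <- function(get, set) {
    g <- get(model) * 0
    for (i in seq_along(g)) {
      mp <- model; mm <- model
      vp <- get(mp); vp[i] <- vp[i] + h; mp <- set(mp, vp)
      vm <- get(mm); vm[i] <- vm[i] - h; mm <- set(mm, vm)
      g[i] <- (ge_of(mp) - ge_of(mm)) / (2 * h)
    }
    g
  }
  list(
    W = grad_mat(function(m) m@W, function(m, v) { m@W <- v; m }),
    theta = grad_mat(function(m) m@theta, function(m, v) { m@theta <- v; m }),
    Wout = grad_mat(function(m) m@Wout, function(m, v) { m@Wout <- v; m }),
    alpha = grad_mat(function(m) m@alpha, function(m, v) { m@alpha <- v; m }))
}

# synthetic hidden x input weight matrix with a planted high-importance block
planted_weight_matrix <- function(seed, p = 28, q = 7, hidden = 10,
                                  separation = 3) {
  set.seed(seed)
  module <- sort(sample.int(p, q))
  W <- matrix(runif(hidden * p, -0.1, 0.1), hidden, p)
  base_imp <- mean(colSums(abs(W)))
  direction <- rnorm(hidden)
  direction <- direction / sum(abs(direction))
  for (j in module)
    W[, j] <- separation * base_imp * direction +
      matrix(runif(hidden, -0.02, 0.02), hidden)
  colnames(W) <- sprintf("I%02d", seq_len(p))
  list(W = W, module = colnames(W)[module])
}

as_network <- function(W) {
  new("BPNetwork", W = W, theta = rep(0, nrow(W)),
      Wout = matrix(1, 1, nrow(W)), alpha = 0,
      hiddenTransfer = "tanh", outputTransfer = "logistic")
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
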
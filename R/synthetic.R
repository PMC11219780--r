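#' @include AllClasses.R AllGenerics.R
NULL

#' Specify a synthetic clinical cohort
#'
#' The generator emulates the statistical structure the early-warning
#' method assumes: a block of `moduleSize` mutually correlated "key marker"
#' indicators sharing one latent factor per sample (loading `lambda`, so the
#' expected within-module Pearson correlation is `lambda^2`), independent
#' standard-normal noise indicators, a continuous outcome linked to the
#' latent factor through a logistic function, a handful of planted
#' "pre-onset" anomaly samples whose marker block is jointly elevated while
#' the outcome stays normal, and completely-at-random missing cells.
#'
#' Anomalies are created by shifting the marker block of a sample by
#' `anomalyShift` marker SDs with per-marker multipliers
#' `1 + anomalyStrength * pattern`, where `pattern` is an exactly
#' standardized, randomly permuted dispersion pattern with skewness
#' `anomalySkewness`; the elevation drives the warning index's numerator
#' while keeping its skewness denominator moderate and controlled.
#'
#' @param nSamples,nIndicators cohort dimensions (inputs, excluding the
#'   outcome); defaults 200 x 28.
#' @param moduleSize planted module size (default 7).
#' @param lambda latent-factor loading in (0, 1); default 0.8.
#' @param outcomeBeta slope of the latent factor in the outcome link.
#' @param outcomeNoiseSD Gaussian noise SD added on the logit scale.
#' @param nAnomalies number of planted anomaly samples (default 6).
#' @param anomalyShift block shift in per-marker SD units (default 3).
#' @param anomalySkewness target skewness of the dispersion pattern.
#' @param anomalyStrength multiplier strength of the dispersion pattern.
#' @param missingRate MCAR missingness rate over input cells (default 0.02).
#' @param seed RNG seed; a fixed seed yields byte-identical cohorts.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nSamples = 200L, nIndicators = 28L, moduleSize = 7L,
                          lambda = 0.8, outcomeBeta = 2, outcomeNoiseSD = 0.05,
                          nAnomalies = 6L, anomalyShift = 3,
                          anomalySkewness = 0.25, anomalyStrength = 1,
                          missingRate = 0.02, seed = 1L) {
  new("SyntheticSpec", nSamples = as.integer(nSamples),
      nIndicators = as.integer(nIndicators),
      moduleSize = as.integer(moduleSize), lambda = lambda,
      outcomeBeta = outcomeBeta, outcomeNoiseSD = outcomeNoiseSD,
      nAnomalies = as.integer(nAnomalies), anomalyShift = anomalyShift,
      anomalySkewness = anomalySkewness, anomalyStrength = anomalyStrength,
      missingRate = missingRate, seed = as.integer(seed))
}

## exactly standardized dispersion pattern with a target skewness:
## gamma-quantile probe points, affinely standardized; the gamma shape is
## solved so the (population) skewness of the standardized vector hits the
## target.
.skewPattern <- function(q, target) {
  std <- function(p) (p - mean(p)) / sqrt(mean((p - mean(p))^2))
  if (target == 0) return(std(stats::qnorm(stats::ppoints(q))))
  f <- function(k) mean(std(stats::qgamma(stats::ppoints(q), shape = k))^3) -
    abs(target)
  k <- stats::uniroot(f, c(0.05, 5000))$root
  sign(target) * std(stats::qgamma(stats::ppoints(q), shape = k))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws the cohort described by a [syntheticSpec()]. All randomness flows
#' from `spec@seed` in a fixed draw order, so the output is reproducible
#' byte for byte.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `data` (an [IndicatorExperiment-class], outcome column
#'   `"GLU"`, missing cells masked) and `truth` (list with `module`, the
#'   planted member names, and `anomalies`, the planted sample indices).
#' @examples
#' cohort <- generateIndicatorData(syntheticSpec(nSamples = 50, seed = 7))
#' dim(indicatorValues(cohort$data))  # 50 x 29
#' @export
generateIndicatorData <- function(spec) {
  validObject(spec)
  n <- spec@nSamples; p <- spec@nIndicators; q <- spec@moduleSize
  set.seed(spec@seed)
  ind_names <- sprintf("I%02d", seq_len(p))
  module_idx <- sort(sample.int(p, q))
  f <- stats::rnorm(n)
  X <- matrix(stats::rnorm(n * p), n, p, dimnames =
                list(sprintf("S%03d", seq_len(n)), ind_names))
  X[, module_idx] <- spec@lambda * f +
    sqrt(1 - spec@lambda^2) * matrix(stats::rnorm(n * q), n, q)
  y <- stats::plogis(spec@outcomeBeta * f +
                       stats::rnorm(n, 0, spec@outcomeNoiseSD))

  anomalies <- integer(0)
  if (spec@nAnomalies > 0L) {
    anomalies <- sort(sample.int(n, spec@nAnomalies))
    pat <- .skewPattern(q, spec@anomalySkewness)
    sd_mod <- apply(X[, module_idx, drop = FALSE], 2, stats::sd)
    for (j in anomalies) {
      mult <- 1 + spec@anomalyStrength * sample(pat)
      X[j, module_idx] <- X[j, module_idx] + spec@anomalyShift * sd_mod * mult
    }
  }

  if (spec@missingRate > 0) {
    holes <- matrix(stats::runif(n * p) < spec@missingRate, n, p)
    # keep every sample partially observed and every indicator well observed
    X[holes] <- NA_real_
  }
  values <- cbind(X, GLU = y)
  data <- IndicatorExperiment(values, outcomeName = "GLU")
  list(data = data,
       truth = list(module = ind_names[module_idx], anomalies = anomalies))
}

#' Default synthetic cohort (study shape)
#'
#' Convenience wrapper: `generateIndicatorData(syntheticSpec(seed = seed))`,
#' i.e. 200 samples, 28 inputs plus outcome, a planted 7-member module with
#' loading 0.8, six planted anomalies and 2\% missingness.
#'
#' @param seed RNG seed.
#' @return as [generateIndicatorData()].
#' @export
syntheticCohort <- function(seed = 1L) {
  generateIndicatorData(syntheticSpec(seed = seed))
}
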
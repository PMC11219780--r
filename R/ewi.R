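#' @include AllClasses.R AllGenerics.R
NULL

#' Row-standardize a marker score matrix
#'
#' Each marker row is centred by its mean and divided by its population
#' standard deviation across samples, removing the dimensional differences
#' between indicators. Rows are exactly mean-0 / SD-1 afterwards (population
#' moments), which makes the downstream warning index invariant to any
#' positive-scale affine transform of the raw marker units.
#'
#' @param x numeric matrix, markers as rows and samples as columns.
#' @return matrix of the same shape with standardized rows.
#' @examples
#' standardizeRows(matrix(c(1, 2, 3), 1))  # -1.2247 0 1.2247
#' @export
standardizeRows <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  sdp <- sqrt(rowMeans((x - mu)^2))
  if (any(sdp == 0))
    stop("constant marker row(s): ",
         paste(if (is.null(rownames(x))) which(sdp == 0)
               else rownames(x)[sdp == 0], collapse = ", "))
  (x - mu) / sdp
}

#' Per-sample skewness of standardized marker scores
#'
#' Population-moment (biased) skewness over the markers within each sample
#' column: `s_j = m3_j / m2_j^{3/2}` with `m_r = mean((y_ij - ybar_j)^r)`
#' taken over the `m` markers. Returns `NaN` for a column with zero spread;
#' such columns are handled by the division guard in [computeEWI()].
#'
#' @param y markers x samples matrix (typically from [standardizeRows()]).
#' @return numeric vector of length `ncol(y)`.
#' @examples
#' columnSkewness(matrix(c(0, 0, 1), 3))  # 1/sqrt(2)
#' @export
columnSkewness <- function(y) {
  y <- as.matrix(y)
  if (nrow(y) < 3L) stop("need at least 3 markers for skewness")
  apply(y, 2, function(col) {
    cm <- mean(col)
    m2 <- mean((col - cm)^2)
    m3 <- mean((col - cm)^3)
    if (m2 == 0) NaN else m3 / m2^1.5
  })
}

#' Compute the composite early-warning index
#'
#' For the key-marker submatrix (markers x samples), row-standardizes the
#' scores, then for every sample `j` forms the column mean `ybar_j`, the
#' column skewness `s_j`, and the index `EWI_j = ybar_j / s_j`. Where
#' `|s_j|` falls below the guard `epsilon` (or is undefined), the index is
#' reported as `sign(ybar_j) * |ybar_j| / epsilon` and marked saturated.
#'
#' @param x markers x samples numeric matrix, or an
#'   [IndicatorExperiment-class] together with `module`.
#' @param module a [MarkerModule-class] or character vector of marker names
#'   (required when `x` is an `IndicatorExperiment`).
#' @param epsilon division guard for near-zero skewness (default `1e-8`).
#' @return an [EWISeries-class] (not yet flagged; see [flagWarnings()]).
#' @export
computeEWI <- function(x, module = NULL, epsilon = 1e-8) {
  if (is(x, "IndicatorExperiment")) {
    if (is.null(module))
      stop("a marker module is required with an IndicatorExperiment")
    members <- if (is(module, "MarkerModule")) moduleMembers(module) else module
    if (any(missingMask(x))) stop("impute missing values first")
    xm <- t(indicatorValues(x)[, members, drop = FALSE])
  } else xm <- as.matrix(x)
  if (nrow(xm) < 3L) stop("need at least 3 markers")
  if (ncol(xm) < 1L) stop("need at least 1 sample")
  y <- standardizeRows(xm)
  ybar <- colMeans(y)
  s <- columnSkewness(y)
  saturated <- !is.finite(s) | abs(s) < epsilon
  ewi <- ifelse(saturated, sign(ybar) * abs(ybar) / epsilon, ybar / s)
  ids <- colnames(xm)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(ncol(xm)))
  new("EWISeries", sampleIDs = ids, ybar = ybar, skew = s, ewi = ewi,
      saturated = saturated, epsilon = epsilon, flagged = integer(0),
      flagK = NA_real_, flagMethod = "none")
}

#' Flag strong warning signals in an EWI series
#'
#' A sample is flagged when its index deviates from the series median by
#' more than `k` times the (consistency-scaled) median absolute deviation.
#' When the MAD is zero the rule falls back to mean +/- k SD; when both
#' scales are zero nothing is flagged.
#'
#' @param series an [EWISeries-class].
#' @param k robust-z threshold (default 3).
#' @return the series with `flaggedSamples()` filled in and the rule
#'   parameters recorded.
#' @export
flagWarnings <- function(series, k = 3) {
  e <- series@ewi
  if (length(e) < 3L) stop("need at least 3 samples to flag")
  md <- stats::median(e)
  MAD <- stats::mad(e)
  if (MAD > 0) {
    flags <- which(abs(e - md) > k * MAD)
    method <- "mad"
  } else {
    s <- stats::sd(e)
    if (s > 0) {
      flags <- which(abs(e - mean(e)) > k * s)
      method <- "sd"
    } else {
      flags <- integer(0)
      method <- "none"
    }
  }
  series@flagged <- as.integer(flags)
  series@flagK <- k
  series@flagMethod <- method
  validObject(series)
  series
}

#' Raw outcome series for side-by-side comparison with the EWI
#'
#' @param data an [IndicatorExperiment-class].
#' @param outcome outcome indicator name; defaults to the designated one.
#' @return named numeric vector, one value per sample.
#' @export
outcomeCurve <- function(data, outcome = NULL) {
  if (is.null(outcome)) outcome <- outcomeName(data)
  stats::setNames(indicatorValues(data)[, outcome], sampleIDs(data))
}

#' Fluctuation contrast between the warning index and the raw outcome
#'
#' Compares the coefficient of variation (SD over absolute mean) of the EWI
#' series with that of the raw outcome curve. A working composite index
#' fluctuates far more strongly at abnormal samples than the outcome
#' itself, so the ratio exceeds 1.
#'
#' @param series an [EWISeries-class] (or numeric vector).
#' @param outcome numeric outcome series (e.g. from [outcomeCurve()]).
#' @return list with `cvEWI`, `cvOutcome` and their `ratio`.
#' @export
fluctuationContrast <- function(series, outcome) {
  e <- if (is(series, "EWISeries")) series@ewi else as.numeric(series)
  cv <- function(v) {
    m <- abs(mean(v))
    if (m == 0) Inf else stats::sd(v) / m
  }
  out <- list(cvEWI = cv(e), cvOutcome = cv(outcome))
  out$ratio <- if (is.finite(out$cvOutcome) && out$cvOutcome > 0)
    out$cvEWI / out$cvOutcome else Inf
  out
}
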
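#' @include AllClasses.R AllGenerics.R
NULL

#' Spearman rank correlation coefficient
#'
#' For tie-free data this evaluates the classical formula
#' `rho = 1 - 6 * sum(d_i^2) / (n * (n^2 - 1))` on the rank differences
#' `d_i`; with ties, ranks are assigned by averaging and the coefficient is
#' computed as the Pearson correlation of the ranks (the two agree exactly
#' in the tie-free case).
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return a number in `[-1, 1]`.
#' @examples
#' spearmanRho(1:3, c(10, 20, 30))  #  1
#' spearmanRho(1:3, 3:1)            # -1
#' @export
spearmanRho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("undefined correlation: an argument is constant (zero rank variance)")
  if (!anyDuplicated(rx) && !anyDuplicated(ry)) {
    d <- rx - ry
    return(1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

#' Within- versus cross-module Spearman correlation report
#'
#' Computes the Spearman correlation matrix among the module members
#' (`within`) and between module members and all non-module input
#' indicators (`cross`), together with summary statistics of `|rho|` per
#' block and the coherence contrast
#' `delta = mean|rho|_within - mean|rho|_cross`. A coherent key-marker
#' module shows `delta > 0`: its members are systematically correlated
#' while their association with the remaining indicators is weak.
#'
#' @param data a complete [IndicatorExperiment-class].
#' @param module a [MarkerModule-class] or character vector of member
#'   indicator names.
#' @return a [CorrelationReport-class].
#' @export
moduleCorrelationReport <- function(data, module) {
  members <- if (is(module, "MarkerModule")) moduleMembers(module) else module
  if (length(members) < 2L) stop("module must have at least 2 members")
  v <- indicatorValues(data)
  if (any(missingMask(data))) stop("impute missing values first")
  if (!all(members %in% colnames(v)))
    stop("module members absent from the data: ",
         paste(setdiff(members, colnames(v)), collapse = ", "))
  if (nrow(v) < 3L) stop("need at least 3 samples")
  others <- setdiff(colnames(v), c(members, outcomeName(data)))

  within <- matrix(1, length(members), length(members),
                   dimnames = list(members, members))
  for (i in seq_along(members)) for (j in seq_along(members)) {
    if (i < j)
      within[i, j] <- within[j, i] <- spearmanRho(v[, members[i]],
                                                  v[, members[j]])
  }
  cross <- matrix(NA_real_, length(members), length(others),
                  dimnames = list(members, others))
  for (i in seq_along(members)) for (j in seq_along(others))
    cross[i, j] <- spearmanRho(v[, members[i]], v[, others[j]])

  wvals <- abs(within[upper.tri(within)])
  cvals <- abs(as.vector(cross))
  blockStats <- data.frame(
    block = c("within", "cross"),
    mean = c(mean(wvals), mean(cvals)),
    median = c(stats::median(wvals), stats::median(cvals)),
    min = c(min(wvals), min(cvals)),
    max = c(max(wvals), max(cvals)))
  new("CorrelationReport", within = within, cross = cross,
      blockStats = blockStats, delta = mean(wvals) - mean(cvals),
      nSamples = nrow(v))
}
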
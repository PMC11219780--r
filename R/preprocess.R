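#' @include AllClasses.R AllGenerics.R
NULL

#' K-nearest-neighbour imputation of missing indicator values
#'
#' Each missing cell is replaced by the unweighted mean of that indicator
#' over the `k` nearest samples among those observing it. The distance
#' between two samples is the Euclidean distance over the indicators
#' observed in both, divided by the number of shared observed indicators
#' (the partial-distance convention), so samples with different missingness
#' patterns remain comparable.
#'
#' Imputation operates on raw indicator values; observed cells are never
#' changed, and imputing an already-complete table is the identity.
#'
#' @param x an [IndicatorExperiment-class], possibly with missing cells.
#' @param k neighbour count; must satisfy `1 <= k <` number of samples.
#' @return an [IndicatorExperiment-class] with an all-`FALSE` mask.
#' @examples
#' m <- matrix(c(1, 2, 1, 2, NA, 4, 1, 2, 3), 3, 3, byrow = TRUE,
#'             dimnames = list(paste0("s", 1:3), c("A", "B", "GLU")))
#' ie <- knnImpute(IndicatorExperiment(m, "GLU"), k = 1)
#' sum(missingMask(ie))  # 0
#' @export
knnImpute <- function(x, k = 5L) {
  v <- indicatorValues(x)          # samples x indicators
  mask <- t(missingMask(x))
  n <- nrow(v)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < number of samples")
  if (!any(mask)) return(x)
  obs_per_row <- rowSums(!mask)
  if (any(obs_per_row == 0L))
    stop("fully missing sample(s): ",
         paste(rownames(v)[obs_per_row == 0L], collapse = ", "))
  obs_per_col <- colSums(!mask)
  short <- which(obs_per_col < k)
  if (length(short))
    stop("indicator(s) observed in fewer than k = ", k, " samples: ",
         paste(colnames(v)[short], collapse = ", "))

  O <- !mask
  vz <- v; vz[mask] <- 0
  # pairwise partial distances: sqrt(sum over shared coords) / n_shared
  shared <- O %*% t(O)                                  # co-observation counts
  sq <- vz^2
  cross <- vz %*% t(vz)
  ssq_shared <- sq %*% t(O)                             # sum_i x_ai^2 over shared
  d2 <- ssq_shared + t(ssq_shared) - 2 * cross
  d2[d2 < 0] <- 0
  D <- sqrt(d2) / pmax(shared, 1L)
  D[shared == 0L] <- Inf
  diag(D) <- Inf

  out <- v
  for (i in which(rowSums(mask) > 0L)) {
    ord <- order(D[i, ], seq_len(n))                    # stable tie-break
    for (j in which(mask[i, ])) {
      cand <- ord[O[ord, j]]
      nb <- cand[seq_len(k)]
      out[i, j] <- mean(v[nb, j])
    }
  }
  res <- IndicatorExperiment(out, outcomeName = outcomeName(x),
                             scaled = isScaled(x),
                             scaleTable = metadata(x)$scaleTable)
  res
}

#' Min-max standardization of every indicator to [0, 1]
#'
#' Maps each indicator column by `(x - min) / (max - min)` and records the
#' per-indicator `(min, max)` table in the metadata so that [inverseScale()]
#' is an exact inverse. A constant indicator cannot be scaled; by default it
#' is mapped to 0.5 with a warning (`constantPolicy = "midpoint"`), or
#' dropped (`constantPolicy = "drop"`).
#'
#' @param x a complete (imputed) [IndicatorExperiment-class].
#' @param constantPolicy `"midpoint"` or `"drop"`.
#' @return an [IndicatorExperiment-class] with `isScaled()` `TRUE` and a
#'   `scaleTable` in its metadata.
#' @export
minMaxScale <- function(x, constantPolicy = c("midpoint", "drop")) {
  constantPolicy <- match.arg(constantPolicy)
  if (any(missingMask(x))) stop("impute missing values before scaling")
  v <- indicatorValues(x)
  mins <- apply(v, 2, min)
  maxs <- apply(v, 2, max)
  const <- maxs == mins
  if (any(const)) {
    if (constantPolicy == "drop") {
      if (outcomeName(x) %in% colnames(v)[const])
        stop("outcome indicator is constant; cannot drop it")
      warning("dropping constant indicator(s): ",
              paste(colnames(v)[const], collapse = ", "))
      v <- v[, !const, drop = FALSE]
      mins <- mins[!const]; maxs <- maxs[!const]; const <- const[!const]
    } else {
      warning("constant indicator(s) mapped to 0.5: ",
              paste(colnames(v)[which(const)], collapse = ", "))
    }
  }
  rng <- ifelse(maxs > mins, maxs - mins, 1)
  sc <- sweep(sweep(v, 2, mins), 2, rng, "/")
  if (any(const)) sc[, const] <- 0.5
  tab <- data.frame(indicator = colnames(v), min = unname(mins),
                    max = unname(maxs), stringsAsFactors = FALSE)
  IndicatorExperiment(sc, outcomeName = outcomeName(x), scaled = TRUE,
                      scaleTable = tab)
}

#' Invert min-max scaling
#'
#' Applies `x * (max - min) + min` per indicator using the table stored by
#' [minMaxScale()] (or an explicitly supplied one). A constant indicator
#' (recorded with `min == max`) maps back to the constant.
#'
#' @param x a scaled [IndicatorExperiment-class].
#' @param scaleTable optional data.frame with columns `indicator`, `min`,
#'   `max`; defaults to the table stored in the metadata.
#' @return an [IndicatorExperiment-class] on the original scale.
#' @export
inverseScale <- function(x, scaleTable = NULL) {
  tab <- if (is.null(scaleTable)) metadata(x)$scaleTable else scaleTable
  if (is.null(tab)) stop("no scale table available; was the data scaled?")
  v <- indicatorValues(x)
  if (!setequal(tab$indicator, colnames(v)))
    stop("scale table does not match the indicator columns")
  tab <- tab[match(colnames(v), tab$indicator), ]
  rng <- ifelse(tab$max > tab$min, tab$max - tab$min, 0)
  out <- sweep(sweep(v, 2, rng, "*"), 2, tab$min, "+")
  const <- tab$max == tab$min
  if (any(const)) out[, const] <- rep(tab$min[const], each = nrow(out))
  IndicatorExperiment(out, outcomeName = outcomeName(x), scaled = FALSE)
}
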
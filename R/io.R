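#' @include AllClasses.R AllGenerics.R
NULL

.delim_for <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a samples x indicators table from a delimited text file
#'
#' Expects one header row of indicator names plus a sample-ID column
#' (the first column by default). All other columns must be numeric; empty
#' cells and the tokens `NA` / `NaN` are read as missing and recorded in the
#' missingness mask.
#'
#' @param path file to read.
#' @param outcomeName name of the outcome indicator column; must be present.
#' @param delimiter field separator; by default inferred from the file
#'   extension (`,` for `.csv`, tab otherwise).
#' @param idColumn name or index of the sample-ID column (default: first).
#' @param naTokens character vector of tokens treated as missing.
#' @return an [IndicatorExperiment-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tA\tGLU", "s1\t1\t5", "s2\t\t6"), tf)
#' ie <- readIndicatorTable(tf, outcomeName = "GLU")
#' sum(missingMask(ie))  # 1
#' @export
readIndicatorTable <- function(path, outcomeName, delimiter = NULL,
                               idColumn = 1L, naTokens = c("", "NA", "NaN")) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .delim_for(path, delimiter)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (is.character(idColumn)) {
    idx <- match(idColumn, colnames(raw))
    if (is.na(idx)) stop("sample-ID column '", idColumn, "' not found")
  } else idx <- as.integer(idColumn)
  ids <- raw[[idx]]
  if (anyDuplicated(ids))
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dat <- raw[, -idx, drop = FALSE]
  if (!outcomeName %in% colnames(dat))
    stop("outcome column '", outcomeName, "' is absent from ", path)
  vals <- matrix(NA_real_, nrow(dat), ncol(dat),
                 dimnames = list(ids, colnames(dat)))
  for (j in seq_len(ncol(dat))) {
    cell <- dat[[j]]
    missing <- cell %in% naTokens | is.na(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!missing & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                   cell[bad[1]], ids[bad[1]], colnames(dat)[j]))
    num[missing] <- NA_real_
    vals[, j] <- num
  }
  IndicatorExperiment(vals, outcomeName = outcomeName)
}

#' Write an IndicatorExperiment to a delimited text file
#'
#' Writes a header row and one row per sample, with the sample ID in the
#' first column and masked cells written as `NA`. [readIndicatorTable()] on
#' the result reproduces values, mask and label orders exactly.
#'
#' @param x an [IndicatorExperiment-class].
#' @param path output file; the extension selects the delimiter as in
#'   [readIndicatorTable()].
#' @param delimiter optional explicit field separator.
#' @return `path`, invisibly.
#' @export
writeIndicatorTable <- function(x, path, delimiter = NULL) {
  sep <- .delim_for(path, delimiter)
  v <- indicatorValues(x)
  df <- data.frame(id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Partition samples into training and test sets
#'
#' `"sequential"` mode takes the first `floor(fraction * n)` samples as the
#' training set (the convention for an ordered patient cohort); `"random"`
#' mode permutes the samples with the given seed first.
#'
#' @param x an [IndicatorExperiment-class].
#' @param fraction training share in (0, 1); default 0.75.
#' @param mode `"sequential"` or `"random"`.
#' @param seed RNG seed for random mode.
#' @return a [SplitIndex-class].
#' @examples
#' ie <- IndicatorExperiment(matrix(1:8, 4, 2,
#'   dimnames = list(paste0("s", 1:4), c("A", "GLU"))), "GLU")
#' splitSamples(ie, 0.75)
#' @export
splitSamples <- function(x, fraction = 0.75,
                         mode = c("sequential", "random"), seed = 1L) {
  mode <- match.arg(mode)
  ids <- sampleIDs(x)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 samples to split")
  ntrain <- floor(fraction * n)
  if (ntrain < 1L || ntrain >= n)
    stop("fraction ", fraction, " leaves an empty train or test set for n = ", n)
  if (mode == "random") {
    set.seed(seed)
    ids <- ids[sample.int(n)]
  }
  new("SplitIndex", train = ids[seq_len(ntrain)],
      test = ids[(ntrain + 1L):n], fraction = fraction, mode = mode)
}

#' Subset an IndicatorExperiment to a set of samples
#'
#' @param x an [IndicatorExperiment-class].
#' @param ids sample IDs to keep (order preserved as given).
#' @return an [IndicatorExperiment-class] with those samples.
#' @export
selectSamples <- function(x, ids) {
  stopifnot(all(ids %in% sampleIDs(x)))
  x[, ids]
}
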
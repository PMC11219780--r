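#' @include AllClasses.R AllGenerics.R
NULL

#' Pairwise Euclidean distances between indicator profiles
#'
#' @param profiles either a matrix whose columns are indicator profiles
#'   (e.g. hidden-weight vectors), or a named numeric vector of scalar
#'   importances.
#' @return a symmetric distance matrix with zero diagonal, labelled by
#'   indicator.
#' @examples
#' pairwiseEuclidean(c(a = 1, b = 4))["a", "b"]  # 3
#' @export
pairwiseEuclidean <- function(profiles) {
  m <- if (is.null(dim(profiles))) rbind(profiles) else as.matrix(profiles)
  if (!all(is.finite(m))) stop("profiles must be finite")
  D <- as.matrix(stats::dist(t(m), method = "euclidean"))
  dimnames(D) <- list(colnames(m), colnames(m))
  D
}

#' Single-linkage (shortest distance) agglomerative clustering
#'
#' Repeatedly merges the two clusters with the smallest minimum inter-point
#' distance. Ties in the minimum distance are broken deterministically by
#' the lexicographically smallest pair of cluster representative labels
#' (each cluster is represented by its smallest member label). Merge heights
#' are non-decreasing.
#'
#' @param d a symmetric non-negative distance matrix with zero diagonal
#'   (e.g. from [pairwiseEuclidean()]), or a [stats::dist] object.
#' @param labels leaf labels; defaults to the dimnames of `d`.
#' @return an object of class `hclust` (method `"single"`), usable with
#'   [stats::cutree()], [plot()], and convertible to Newick via
#'   [treeToNewick()].
#' @export
singleLinkage <- function(d, labels = NULL) {
  D <- as.matrix(d)
  if (any(is.na(D))) stop("distance matrix contains NA/NaN")
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items to cluster")
  if (is.null(labels)) labels <- rownames(D)
  if (is.null(labels)) labels <- sprintf("L%02d", seq_len(n))

  active <- seq_len(n)
  id <- -seq_len(n)                       # hclust coding: leaves negative
  rep_lab <- labels                       # cluster representative labels
  Dc <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      dab <- Dc[a, b]
      if (is.null(best) || dab < best$d - 0) {
        take <- TRUE
      } else if (dab == best$d) {
        # lexicographic tie-break on sorted representative label pairs
        cand <- sort(c(rep_lab[a], rep_lab[b]))
        cur <- sort(c(rep_lab[best$a], rep_lab[best$b]))
        take <- cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])
      } else take <- FALSE
      if (take) best <- list(a = a, b = b, d = dab)
    }
    a <- best$a; b <- best$b
    merge[step, ] <- sort(c(id[a], id[b]))
    height[step] <- best$d
    # merge b into a
    newd <- pmin(Dc[a, ], Dc[b, ])
    Dc[a, ] <- newd; Dc[, a] <- newd; Dc[a, a] <- 0
    members[[a]] <- c(members[[a]], members[[b]])
    rep_lab[a] <- min(rep_lab[a], rep_lab[b])
    id[a] <- step
    keep <- setdiff(seq_len(k), b)
    Dc <- Dc[keep, keep, drop = FALSE]
    id <- id[keep]; rep_lab <- rep_lab[keep]
    members <- members[keep]; active <- active[keep]
  }

  order <- .leaf_order(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "single",
                 dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

.leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(n - 1L)
}

#' Detect the key-marker module from a merge tree
#'
#' Implements the uppermost-tail rule: merges whose height strictly exceeds
#' the empirical (type-1) `percentile`-th percentile of all merge heights
#' are undone -- for the default 95th percentile this removes the top 5\% of
#' merges by count, and the largest merge always counts as part of the
#' uppermost tail -- and, among the resulting flat clusters with at least
#' `minSize` members, the cluster with the greatest mean importance is the
#' key-marker module.
#'
#' @param tree an `hclust` object (from [singleLinkage()]).
#' @param importances named numeric importance per indicator.
#' @param percentile cut percentile in (0, 100); default 95.
#' @param minSize minimum module size considered (default 2).
#' @return a [MarkerModule-class]; members are sorted by importance,
#'   descending.
#' @export
detectModule <- function(tree, importances, percentile = 95, minSize = 2L) {
  stopifnot(percentile > 0, percentile < 100, minSize >= 1L)
  labels <- tree$labels
  if (!all(labels %in% names(importances)))
    stop("importances must be named for every leaf of the tree")
  importances <- importances[labels]
  nm <- length(tree$height)
  hs <- sort(tree$height)
  # empirical (type-1) percentile, capped so the largest merge is always in
  # the uppermost tail: merges strictly above the cut are undone
  idx <- min(ceiling(percentile / 100 * nm), nm - 1L)
  cutHeight <- if (idx >= 1L) hs[idx] else 0
  cl <- stats::cutree(tree, h = cutHeight)
  sizes <- table(cl)
  if (length(sizes) < 2L)
    stop("module detection failed: no separable module at percentile ",
         percentile, " (all ", length(labels), " indicators in one cluster)")
  cand <- names(sizes)[sizes >= minSize]
  if (!length(cand)) {
    tab <- paste(sprintf("cluster %s: %d", names(sizes), as.integer(sizes)),
                 collapse = "; ")
    stop("module detection failed: no cluster of size >= ", minSize,
         " survives the cut (", tab, ")")
  }
  meanImp <- vapply(cand, function(g) mean(importances[cl == as.integer(g)]),
                    numeric(1))
  best <- as.integer(cand[which.max(meanImp)])
  members <- labels[cl == best]
  members <- members[order(-importances[members])]
  complement <- setdiff(labels, members)
  new("MarkerModule", members = members, complement = complement,
      importance = sort(importances, decreasing = TRUE),
      cutHeight = cutHeight, percentile = percentile,
      minSize = as.integer(minSize), mode = "unspecified", tree = tree)
}

#' Run the full marker-detection stage on a trained network
#'
#' Composes [inputWeightProfile()] -> [pairwiseEuclidean()] ->
#' [singleLinkage()] -> [detectModule()]. In `"vector"` mode (default) the
#' clustered objects are the per-indicator columns of the input-to-hidden
#' weight matrix; in `"scalar"` mode they are the importance scalars.
#' Importance scores always drive the selection among flat clusters.
#'
#' @param model a [BPNetwork-class] or [BPNetworkFit-class].
#' @param mode `"vector"` or `"scalar"`.
#' @param percentile,minSize passed to [detectModule()].
#' @param importanceMethod passed to [inputWeightProfile()].
#' @return a [MarkerModule-class] with `mode` recorded.
#' @export
runMarkerDetection <- function(model, mode = c("vector", "scalar"),
                               percentile = 95, minSize = 2L,
                               importanceMethod = "abssum") {
  mode <- match.arg(mode)
  prof <- inputWeightProfile(model, method = importanceMethod)
  obj <- if (mode == "vector") prof$profiles else prof$importance
  D <- pairwiseEuclidean(obj)
  tree <- singleLinkage(D)
  mod <- detectModule(tree, prof$importance, percentile = percentile,
                      minSize = minSize)
  mod@mode <- mode
  mod
}

#' Export a merge tree as a Newick string
#'
#' @param tree an `hclust` object.
#' @return a single Newick string with branch lengths.
#' @export
treeToNewick <- function(tree) {
  ape::write.tree(ape::as.phylo(tree))
}

#' Merge tree as a linkage table
#'
#' @param tree an `hclust` object.
#' @return data.frame with columns `left`, `right` (negative = leaf index),
#'   `height`, and `size` of the resulting cluster.
#' @export
mergeTable <- function(tree) {
  n <- length(tree$labels)
  size <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    s <- function(x) if (x < 0L) 1L else size[x]
    size[i] <- s(tree$merge[i, 1L]) + s(tree$merge[i, 2L])
  }
  data.frame(left = tree$merge[, 1L], right = tree$merge[, 2L],
             height = tree$height, size = size)
}
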
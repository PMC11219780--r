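test_that("pairwise Euclidean distances match hand values", {
  D <- pairwiseEuclidean(c(a = 1, b = 4))
  expect_equal(D["a", "b"], 3)
  expect_equal(diag(D), c(a = 0, b = 0))
  m <- cbind(p = c(0, 0), q = c(3, 4), r = c(0, 0))
  D2 <- pairwiseEuclidean(m)
  expect_equal(D2["p", "q"], 5)
  expect_equal(D2["p", "r"], 0)
  expect_true(isSymmetric(D2))
})

test_that("single linkage reproduces small dendrograms exactly", {
  D <- pairwiseEuclidean(c(a = 0, b = 7))
  t2 <- singleLinkage(D)
  expect_equal(t2$height, 7)

  # collinear scalars 0, 1, 3: merges at heights 1 then 2
  t3 <- singleLinkage(pairwiseEuclidean(c(a = 0, b = 1, c = 3)))
  expect_equal(t3$height, c(1, 2))
})

test_that("single linkage matches the stats::hclust oracle on random
           matrices up to n = 8", {
  set.seed(99)
  for (trial in 1:120) {
    n <- sample(3:8, 1)
    pts <- matrix(rnorm(n * 3), 3, n,
                  dimnames = list(NULL, sprintf("L%02d", seq_len(n))))
    D <- pairwiseEuclidean(pts)
    mine <- singleLinkage(D)
    ref <- stats::hclust(stats::as.dist(D), method = "single")
    expect_equal(mine$height, ref$height, tolerance = 1e-12)
    # identical topology: cophenetic distances agree
    expect_equal(as.matrix(stats::cophenetic(mine))[colnames(D), colnames(D)],
                 as.matrix(stats::cophenetic(ref))[colnames(D), colnames(D)],
                 tolerance = 1e-12)
  }
})

test_that("tied distances are broken deterministically and heights are
           label-permutation invariant", {
  # four points forming two tied pairs
  x <- c(d = 10, c = 0, b = 10.5, a = 0.5)
  t1 <- singleLinkage(pairwiseEuclidean(x))
  t2 <- singleLinkage(pairwiseEuclidean(x))
  expect_identical(t1$merge, t2$merge)
  perm <- sample(length(x))
  t3 <- singleLinkage(pairwiseEuclidean(x[perm]))
  expect_equal(sort(t1$height), sort(t3$height), tolerance = 1e-12)
})

test_that("merge heights are non-decreasing and the tree has n-1 merges", {
  set.seed(12)
  for (trial in 1:20) {
    n <- sample(4:12, 1)
    D <- pairwiseEuclidean(rnorm(n) * 5)
    tr <- singleLinkage(D, labels = sprintf("x%02d", seq_len(n)))
    expect_identical(nrow(tr$merge), n - 1L)
    expect_true(all(diff(tr$height) >= -1e-12))
    expect_setequal(tr$order, seq_len(n))
  }
})

test_that("the uppermost-tail cut isolates a planted high-importance module", {
  set.seed(21)
  for (trial in 1:20) {
    imp <- c(rnorm(7, 10, 0.05), rnorm(21, 2, 0.3))
    names(imp) <- sprintf("I%02d", 1:28)
    tree <- singleLinkage(pairwiseEuclidean(imp))
    mod <- detectModule(tree, imp)
    expect_setequal(moduleMembers(mod), names(imp)[1:7])
    # members come out sorted by importance, descending
    expect_identical(moduleMembers(mod),
                     names(sort(imp[moduleMembers(mod)], decreasing = TRUE)))
  }
})

test_that("equal importances yield no separable module", {
  imp <- rep(1, 10)
  names(imp) <- sprintf("I%02d", 1:10)
  tree <- singleLinkage(pairwiseEuclidean(imp))
  expect_error(detectModule(tree, imp), "no separable module")
})

test_that("between two separated clusters the higher-importance one wins", {
  imp <- c(a = 1.0, b = 1.1, c = 1.05, x = 5.0, y = 5.1, z = 5.05)
  tree <- singleLinkage(pairwiseEuclidean(imp))
  mod <- detectModule(tree, imp)
  expect_setequal(moduleMembers(mod), c("x", "y", "z"))
  expect_setequal(moduleComplement(mod), c("a", "b", "c"))
})

test_that("the number of flat clusters is non-increasing in the cut height", {
  set.seed(31)
  D <- pairwiseEuclidean(rnorm(15))
  tree <- singleLinkage(D, labels = sprintf("x%02d", 1:15))
  hs <- sort(unique(c(0, tree$height, max(tree$height) * 1.1)))
  counts <- vapply(hs, function(h) length(unique(stats::cutree(tree, h = h))),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("marker detection on a network with a planted weight block
           recovers the block", {
  for (seed in 1:10) {
    pw <- planted_weight_matrix(seed)
    mod <- runMarkerDetection(as_network(pw$W))
    expect_setequal(moduleMembers(mod), pw$module)
  }
})

test_that("with one hidden node, vector and scalar modes agree", {
  set.seed(77)
  W <- matrix(rnorm(8), 1, 8, dimnames = list(NULL, sprintf("I%02d", 1:8)))
  W[, 1:3] <- W[, 1:3] + 6     # high-weight block
  net <- as_network(W)
  mv <- runMarkerDetection(net, mode = "vector")
  ms <- runMarkerDetection(net, mode = "scalar")
  expect_setequal(moduleMembers(mv), moduleMembers(ms))
})

test_that("marker detection is deterministic for a fixed model", {
  pw <- planted_weight_matrix(5)
  m1 <- runMarkerDetection(as_network(pw$W))
  m2 <- runMarkerDetection(as_network(pw$W))
  expect_identical(moduleMembers(m1), moduleMembers(m2))
  expect_identical(m1@cutHeight, m2@cutHeight)
})

test_that("merge trees export to Newick and to a linkage table", {
  tree <- singleLinkage(pairwiseEuclidean(c(a = 0, b = 1, c = 3)))
  nwk <- treeToNewick(tree)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "a")
  tab <- mergeTable(tree)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$height, c(1, 2))
  expect_equal(tab$size, c(2L, 3L))
})
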
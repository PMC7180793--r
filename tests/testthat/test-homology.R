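unitSquare <- function() {
  PointCloud(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), tau = 1L)
}

test_that("pairwise distances are Euclidean, symmetric, zero-diagonal", {
  pc <- PointCloud(rbind(c(0, 0), c(3, 4)), tau = 1L)
  d <- pairwiseDistances(pc)
  expect_equal(d, matrix(c(0, 5, 5, 0), 2), ignore_attr = TRUE)

  one <- PointCloud(matrix(c(0, 0), 1), tau = 1L)
  expect_equal(pairwiseDistances(one), matrix(0, 1, 1), ignore_attr = TRUE)

  dup <- PointCloud(rbind(c(1, 2), c(1, 2)), tau = 1L)
  expect_equal(pairwiseDistances(dup)[1, 2], 0)
})

test_that("the Rips filtration enumerates simplices at their diameters", {
  eq <- matrix(1, 3, 3) - diag(3)   # 3 points pairwise distance 1
  filt <- ripsFiltration(eq, threshold = 2)
  expect_equal(nrow(filt), 7L)
  expect_equal(as.vector(table(filt$dim)), c(3L, 3L, 1L))
  expect_equal(filt$value[filt$dim == 0L], rep(0, 3))
  expect_equal(filt$value[filt$dim == 1L], rep(1, 3))
  expect_equal(filt$value[filt$dim == 2L], 1)

  expect_equal(nrow(ripsFiltration(eq, threshold = 0.5)), 3L)
})

test_that("unit-square filtration has the enumerated diameters", {
  filt <- ripsFiltration(pairwiseDistances(unitSquare()),
                         threshold = sqrt(2))
  expect_equal(sum(filt$dim == 0L), 4L)
  edges <- sort(filt$value[filt$dim == 1L])
  expect_equal(edges, c(1, 1, 1, 1, sqrt(2), sqrt(2)))
  expect_equal(filt$value[filt$dim == 2L], rep(sqrt(2), 4))
})

test_that("filtration order is by value then dimension, faces first", {
  withr::local_seed(10)
  filt <- ripsFiltration(pairwiseDistances(randomCloud(8)))
  expect_true(!is.unsorted(filt$value))
  # any simplex's faces appear earlier
  key <- paste(filt$v1, filt$v2, filt$v3)
  for (j in which(filt$dim == 2L)) {
    for (face in list(c(filt$v1[j], filt$v2[j]), c(filt$v1[j], filt$v3[j]),
                      c(filt$v2[j], filt$v3[j]))) {
      pos <- which(filt$dim == 1L & filt$v1 == face[1] & filt$v2 == face[2])
      expect_true(pos < j)
    }
  }
})

test_that("a single point has one essential component and no loops", {
  dg <- ripsDiagram(PointCloud(matrix(c(0, 0), 1), tau = 1L))
  p <- persistencePairs(dg)
  expect_equal(nrow(p), 1L)
  expect_equal(p$dimension, 0L)
  expect_equal(p$birth, 0)
  expect_equal(p$death, Inf)
})

test_that("the unit square has one loop born at 1, dying at sqrt(2)", {
  dg <- ripsDiagram(unitSquare())
  h0 <- persistencePairs(dg, dimension = 0L)
  expect_equal(sort(h0$death), c(1, 1, 1, Inf))
  expect_equal(h0$birth, rep(0, 4))
  h1 <- persistencePairs(dg, dimension = 1L)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))
})

test_that("an equilateral triangle's cycle has zero persistence", {
  pts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  dg <- ripsDiagram(PointCloud(pts, tau = 1L))
  expect_equal(nrow(persistencePairs(dg, dimension = 1L)), 0L)
  h0 <- persistencePairs(dg, dimension = 0L)
  expect_equal(sum(is.infinite(h0$death)), 1L)
  expect_equal(sort(h0$death[is.finite(h0$death)]), rep(1, 2),
               tolerance = 1e-12)
})

test_that("diagrams reproduce brute-force Betti numbers on random clouds", {
  withr::local_seed(12)
  for (rep in 1:25) {
    pc <- randomCloud(sample(3:8, 1))
    dmat <- pairwiseDistances(pc)
    thr <- enclosingRadius(dmat) * runif(1, 0.5, 1)
    dg <- computePersistence(ripsFiltration(dmat, threshold = thr),
                             maxScale = thr)
    for (eps in unique(c(0, dmat[dmat <= thr], thr))) {
      expect_equal(diagramBetti(dg, eps), bruteBetti(dmat, eps),
                   label = sprintf("betti at eps=%g", eps))
    }
  }
})

test_that("finite H0 deaths count n minus the threshold graph's components", {
  withr::local_seed(13)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    pc <- randomCloud(n)
    dmat <- pairwiseDistances(pc)
    thr <- quantile(dmat[upper.tri(dmat)], 0.4)
    dg <- computePersistence(ripsFiltration(dmat, threshold = thr),
                             maxScale = thr)
    g <- igraph::graph_from_adjacency_matrix(dmat <= thr & upper.tri(dmat),
                                             mode = "upper")
    ncomp <- igraph::components(g)$no
    h0 <- persistencePairs(dg, dimension = 0L)
    expect_equal(sum(is.finite(h0$death)), n - ncomp)
    expect_equal(sum(is.infinite(h0$death)), ncomp)
  }
})

test_that("H0 pairs account for every point on tie-free clouds", {
  withr::local_seed(14)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    dg <- ripsDiagram(randomCloud(n))
    expect_equal(nrow(persistencePairs(dg, dimension = 0L)), n)
  }
})

test_that("an invalidly ordered filtration is rejected", {
  filt <- ripsFiltration(pairwiseDistances(unitSquare()))
  expect_error(computePersistence(filt[rev(seq_len(nrow(filt))), ]),
               "filtration")
})

test_that("barcodes re-view pairs, capping essential classes for display", {
  dg <- PersistenceDiagram(c(0L, 1L), c(0, 1), c(Inf, sqrt(2)),
                           maxScale = 2)
  bc <- diagramToBarcode(dg)
  expect_equal(bc$end[bc$dimension == 1L], sqrt(2))
  expect_equal(bc$end[bc$dimension == 0L], 2)
  expect_true(bc$essential[bc$dimension == 0L])

  empty <- PersistenceDiagram(maxScale = 1)
  expect_equal(nrow(diagramToBarcode(empty)), 0L)
})

test_that("diagrams survive a text export round trip", {
  dg <- ripsDiagram(unitSquare())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDiagram(dg, f)
  back <- readDiagram(f, maxScale = dg@maxScale)
  expect_equal(persistencePairs(back), persistencePairs(dg))
})
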
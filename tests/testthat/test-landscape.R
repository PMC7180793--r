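test_that("the tent function has the right rise, apex and support", {
  expect_equal(tentValue(1, sqrt(2), (1 + sqrt(2)) / 2), (sqrt(2) - 1) / 2)
  expect_equal(tentValue(0, 2, 3), 0)
  expect_equal(tentValue(0, 2, -1), 0)
  expect_equal(tentValue(0, 2, 0.5), 0.5)
  expect_equal(tentValue(0, 2, 1.5), 0.5)
  expect_error(tentValue(0, Inf, 1), "finite")
})

test_that("an empty H1 diagram gives an all-zero landscape", {
  dg <- PersistenceDiagram(maxScale = 2)
  ls <- computeLandscape(dg, kMax = 3, xMin = 0, xMax = 2, G = 11)
  expect_equal(landscapeLevels(ls), matrix(0, 3, 11))
})

test_that("a single pair peaks at half its persistence; level 2 is zero", {
  dg <- PersistenceDiagram(1L, 1, sqrt(2), maxScale = 2)
  ls <- computeLandscape(dg, kMax = 2, xMin = 0, xMax = 2, G = 201)
  lv <- landscapeLevels(ls)
  x <- landscapeGrid(ls)
  # the sampled peak is within one grid step of the true apex height
  expect_lt(abs(max(lv[1, ]) - (sqrt(2) - 1) / 2), 2 / 200)
  expect_equal(x[which.max(lv[1, ])], (1 + sqrt(2)) / 2, tolerance = 1e-2)
  expect_equal(lv[2, ], rep(0, 201))
})

test_that("two overlapping pairs produce the first and second max", {
  dg <- PersistenceDiagram(c(1L, 1L), c(0, 1), c(2, 3), maxScale = 4)
  ls <- computeLandscape(dg, kMax = 2, xMin = 0, xMax = 4, G = 9)
  lv <- landscapeLevels(ls)
  x <- landscapeGrid(ls)
  expect_equal(lv[1, x == 1], 1)
  expect_equal(lv[2, x == 1], 0)
  expect_equal(lv[1, x == 1.5], 0.5)
  expect_equal(lv[2, x == 1.5], 0.5)
})

test_that("landscape levels are ordered, 1-Lipschitz and order-invariant", {
  withr::local_seed(21)
  for (rep in 1:100) {
    np <- sample(0:8, 1)
    dg <- randomH1Diagram(np)
    G <- 80
    ls <- computeLandscape(dg, kMax = 4, xMin = 0, xMax = 4.2, G = G)
    lv <- landscapeLevels(ls)
    spacing <- 4.2 / (G - 1)
    expect_true(all(lv >= 0))
    expect_true(all(diff(lv) <= 1e-12))          # lambda_k >= lambda_{k+1}
    expect_true(all(abs(t(diff(t(lv)))) <= spacing + 1e-12))
    if (np > 1) {
      perm <- sample(np)
      p <- persistencePairs(dg, 1L)
      dg2 <- PersistenceDiagram(rep(1L, np), p$birth[perm], p$death[perm],
                                maxScale = dg@maxScale)
      ls2 <- computeLandscape(dg2, kMax = 4, xMin = 0, xMax = 4.2, G = G)
      expect_equal(landscapeLevels(ls2), lv)
    }
  }
})

test_that("adding a pair never lowers any landscape level", {
  withr::local_seed(22)
  for (rep in 1:25) {
    dg <- randomH1Diagram(sample(1:6, 1))
    p <- persistencePairs(dg, 1L)
    b <- runif(1, 0, 2); d <- b + runif(1, 0.1, 2)
    dg2 <- PersistenceDiagram(rep(1L, nrow(p) + 1L), c(p$birth, b),
                              c(p$death, d), maxScale = dg@maxScale)
    l1 <- landscapeLevels(computeLandscape(dg, kMax = 4, xMax = 4.2, G = 60))
    l2 <- landscapeLevels(computeLandscape(dg2, kMax = 4, xMax = 4.2, G = 60))
    expect_true(all(l2 >= l1 - 1e-12))
  }
})

test_that("cohort vectorization has the K*G shape contract", {
  dgs <- list(PersistenceDiagram(1L, 0.2, 1.2, maxScale = 2),
              PersistenceDiagram(1L, 0.3, 1.5, maxScale = 2))
  fm <- vectorizeCohort(dgs, labels = c("HC", "PD"), kMax = 2, G = 50)
  expect_equal(dim(featureValues(fm)), c(2L, 100L))
  # level-major flattening: the first G entries are lambda_1
  ls1 <- computeLandscape(dgs[[1]], kMax = 2, xMin = 0, xMax = 1.5, G = 50)
  expect_equal(featureValues(fm)[1, 1:50],
               landscapeLevels(ls1)[1, ], ignore_attr = TRUE)
})

test_that("subjects with empty H1 become zero rows", {
  dgs <- list(PersistenceDiagram(1L, 0.2, 1.2, maxScale = 2),
              PersistenceDiagram(maxScale = 2))
  fm <- vectorizeCohort(dgs, labels = c("HC", "PD"), kMax = 2, G = 20)
  expect_equal(unname(featureValues(fm)[2, ]), rep(0, 40))
})

test_that("identical diagrams get identical rows; all-empty cohorts warn", {
  dg <- PersistenceDiagram(1L, 0.1, 0.9, maxScale = 1)
  fm <- vectorizeCohort(list(dg, dg), labels = c("a", "b"), kMax = 3, G = 30)
  expect_equal(unname(featureValues(fm)[1, ]), unname(featureValues(fm)[2, ]))

  empties <- list(PersistenceDiagram(maxScale = 1),
                  PersistenceDiagram(maxScale = 1))
  expect_warning(fm0 <- vectorizeCohort(empties, labels = c("a", "b"),
                                        kMax = 2, G = 10), "zero")
  expect_true(all(featureValues(fm0) == 0))
})
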
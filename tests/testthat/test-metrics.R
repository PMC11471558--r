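test_that("kNN graph matches the brute-force oracle and excludes self", {
  # collinear geometry
  pts <- matrix(c(0, 0, 1, 0, 5, 0), 3, 2, byrow = TRUE)
  g <- buildKnnGraph(pts, k = 1)
  expect_equal(g$indices[2, 1], 1L)
  # duplicates: zero distance, self excluded
  gd <- buildKnnGraph(rbind(c(1, 1), c(1, 1), c(4, 4)), k = 1)
  expect_equal(gd$indices[1, 1], 2L)
  expect_equal(gd$distances[1, 1], 0)
  # random matrix vs O(N^2) oracle
  set.seed(3)
  X <- matrix(rnorm(250), 50, 5)
  g5 <- buildKnnGraph(X, k = 4)
  D <- as.matrix(dist(X)); diag(D) <- Inf
  for (i in 1:50) {
    o <- order(D[i, ])[1:4]
    expect_equal(sort(g5$indices[i, ]), sort(o))
    expect_equal(g5$distances[i, ], unname(D[i, g5$indices[i, ]]))
    expect_true(all(diff(g5$distances[i, ]) >= 0))
    expect_false(i %in% g5$indices[i, ])
  }
  expect_error(buildKnnGraph(X, k = 50), "smaller")
})

test_that("graph LISI scores hit their extremes and the hand formula", {
  cl <- clusteredPoints(n = 40, centers = rbind(c(0, 0), c(50, 50)))
  g <- buildKnnGraph(cl$points, k = 5)
  # fully separated batches: no mixing
  expect_equal(graphIlisi(g, cl$labels), 0, tolerance = 1e-9)
  expect_equal(graphClisi(g, cl$labels), 1, tolerance = 1e-9)
  # perfect mixing: alternate labels on one tight clump
  set.seed(2)
  pts <- matrix(rnorm(80, sd = 0.01), 40, 2)
  lab2 <- rep(1:2, 20)
  gm <- buildKnnGraph(pts, k = 15)
  ilisiMixed <- graphIlisi(gm, lab2)
  expect_gt(ilisiMixed, 0.75)  # finite neighbourhoods sit just below 1
  # hand-computed inverse Simpson on a small fixed graph
  gsmall <- list(indices = rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)),
                 distances = matrix(1, 3, 2), k = 2L)
  class(gsmall) <- "neighborGraph"
  labs <- c(1, 1, 2)
  handLisi <- mean(c(1 / (0.5^2 + 0.5^2), 1 / (0.5^2 + 0.5^2), 1 / 1))
  expect_equal(graphIlisi(gsmall, labs), (handLisi - 1) / (2 - 1))
  # relabeling invariance
  expect_equal(graphIlisi(gm, lab2), graphIlisi(gm, 3 - lab2))
  expect_warning(v <- graphIlisi(gm, rep(1, 40)), "single label")
  expect_equal(v, 1)
})

test_that("graph connectivity counts largest components per label", {
  cl <- clusteredPoints(n = 40, centers = rbind(c(0, 0), c(50, 50)))
  g <- buildKnnGraph(cl$points, k = 4)
  expect_equal(graphConnectivity(g, cl$labels), 1)
  # one label split into two distant halves scores 0.5 for that label
  pts <- rbind(matrix(rnorm(20, sd = 0.1), 10, 2),
               matrix(rnorm(20, sd = 0.1) + 100, 10, 2),
               matrix(rnorm(20, sd = 0.1) + 500, 10, 2))
  labs <- c(rep("a", 20), rep("b", 10))
  gs <- buildKnnGraph(pts, k = 3)
  expect_equal(graphConnectivity(gs, labs), mean(c(0.5, 1)))
})

test_that("kBET scores random mixing near 1 and segregation near 0", {
  set.seed(14)
  pts <- matrix(rnorm(400), 200, 2)
  batchesMixed <- sample(rep(1:2, 100))
  g <- buildKnnGraph(pts, k = 50)
  expect_gt(kbet(g, batchesMixed, seed = 2), 0.8)
  # batch-segregated clumps
  pts2 <- rbind(matrix(rnorm(200), 100, 2),
                matrix(rnorm(200) + 50, 100, 2))
  g2 <- buildKnnGraph(pts2, k = 50)
  expect_lt(kbet(g2, rep(1:2, each = 100), seed = 2), 0.05)
  # chi-square statistic equals the hand computation on one neighbourhood
  nb <- g2$indices[1, ]
  obs <- table(factor(rep(1:2, each = 100)[nb], levels = 1:2))
  expd <- 0.5 * length(nb)
  stat <- sum((as.numeric(obs) - expd)^2 / expd)
  expect_equal(unname(stat), (obs[[1]] - expd)^2 / expd +
                 (obs[[2]] - expd)^2 / expd)
  expect_error(kbet(g2, rep(1, 200)), "2 batches")
})

test_that("modality ASW rewards aligned modalities", {
  cl <- clusteredPoints(n = 60)
  embA <- cl$points
  # identical embeddings: silhouette of the modality grouping ~ 0
  expect_gt(modalityAsw(list(A = embA, B = embA), cl$labels), 0.95)
  embFar <- embA + 1000
  expect_lt(modalityAsw(list(A = embA, B = embFar), cl$labels), 0.05)
  # matches a direct silhouette computation within one label
  set.seed(8)
  e1 <- matrix(rnorm(20), 10, 2); e2 <- matrix(rnorm(20), 10, 2)
  labs <- rep("x", 10)
  got <- modalityAsw(list(m1 = e1, m2 = e2), labs)
  sil <- cluster::silhouette(rep(1:2, each = 10), dist(rbind(e1, e2)))
  expect_equal(got, mean(1 - abs(sil[, "sil_width"])))
})

test_that("FOSCTTM equals its extremes and a brute-force double loop", {
  set.seed(21)
  E <- matrix(rnorm(30), 10, 3)
  expect_equal(foscttm(E, E), 1)
  # worst case at N = 2: both true matches are the farther point, and the
  # fraction-of-closer-samples tops out at (N - 1)/N
  E2 <- matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE)
  expect_equal(foscttm(E2, E2[2:1, ]), 1 - 1 / 2)
  # brute force on a random pair
  F1 <- matrix(rnorm(30), 10, 3); F2 <- matrix(rnorm(30), 10, 3)
  n1 <- n2 <- 0
  for (i in 1:10) {
    ti <- sqrt(sum((F1[i, ] - F2[i, ])^2))
    for (j in 1:10) {
      if (sqrt(sum((F1[i, ] - F2[j, ])^2)) < ti) n1 <- n1 + 1
      if (sqrt(sum((F1[j, ] - F2[i, ])^2)) < ti) n2 <- n2 + 1
    }
  }
  want <- 1 - (n1 / 10 + n2 / 10) / 20
  expect_equal(foscttm(F1, F2), want)
  # symmetric under swapping the modalities
  expect_equal(foscttm(F1, F2), foscttm(F2, F1))
  expect_error(foscttm(F1[1, , drop = FALSE], F2[1, , drop = FALSE]),
               "N >= 2")
})

test_that("label transfer F1 matches nearest-neighbour oracles", {
  cl <- clusteredPoints(n = 40)
  expect_equal(labelTransferF1(list(a = cl$points, b = cl$points),
                               cl$labels), 1)
  # random labels over well-mixed embeddings with 4 types: ~1/4
  set.seed(33)
  e1 <- matrix(rnorm(2000), 1000, 2)
  e2 <- matrix(rnorm(2000), 1000, 2)
  labs <- sample(1:4, 1000, replace = TRUE)
  expect_lt(abs(labelTransferF1(list(e1, e2), labs) - 0.25), 0.06)
  # tiny fixture with hand-computable neighbours
  r1 <- rbind(c(0, 0), c(10, 0), c(0, 10))
  r2 <- rbind(c(0, 1), c(10, 1), c(0, 11))
  labs3 <- c("x", "y", "z")
  expect_equal(labelTransferF1(list(r1, r2), labs3), 1)
})

test_that("bio-conservation metrics recover planted structure", {
  cl <- clusteredPoints(n = 80, centers = rbind(c(0, 0), c(30, 0),
                                                c(0, 30), c(30, 30)))
  g <- buildKnnGraph(cl$points, k = 10)
  bc <- bioConservation(g, cl$labels, seed = 1)
  expect_gt(bc[["NMI"]], 0.95)
  expect_gt(bc[["ARI"]], 0.95)
  expect_gt(bc[["isolated_F1"]], 0.95)
  expect_gt(bc[["cLISI"]], 0.95)
  expect_true(all(bc >= 0 & bc <= 1))
})

test_that("NMI and ARI extremes behave per textbook formulas", {
  # identical labelings
  labs <- rep(1:4, each = 10)
  expect_equal(igraph::compare(labs, labs, method = "nmi"), 1)
  expect_equal(igraph::compare(labs, labs, method = "adjusted.rand"), 1)
  # one-cluster prediction vs balanced types: ARI 0
  one <- rep(1, 40)
  expect_equal(igraph::compare(one, labs, method = "adjusted.rand"), 0)
  # fixed contingency table vs hand-computed NMI
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  expect_equal(igraph::compare(a, b, method = "nmi"), 0)
})

test_that("overall scores are the stated convex combinations", {
  expect_equal(overallScores(rep(1, 3), rep(1, 4))$scib, 1)
  expect_equal(overallScores(rep(0.5, 3), rep(1, 4))$scib, 0.8)
  expect_equal(overallScores(rep(1, 6), rep(1, 8), rep(1, 6))$scmib, 1)
  set.seed(6)
  b <- runif(3); bio <- runif(4)
  expect_equal(overallScores(b, bio)$scib, 0.4 * mean(b) + 0.6 * mean(bio))
  b6 <- runif(6); bio8 <- runif(8); m6 <- runif(6)
  expect_equal(overallScores(b6, bio8, m6)$scmib,
               0.3 * mean(b6) + 0.3 * mean(m6) + 0.4 * mean(bio8))
  expect_error(overallScores(c(0.5, NA, 1), bio), "missing")
  expect_error(overallScores(c(2, 0, 0), bio), "\\[0,1\\]")
})

test_that("modality contributions are normalized neighbourhood overlaps", {
  set.seed(10)
  X <- matrix(rnorm(100), 20, 5)
  g <- buildKnnGraph(X, k = 4)
  gOther <- buildKnnGraph(matrix(rnorm(100), 20, 5), k = 4)
  mc <- modalityContribution(list(m1 = g, m2 = gOther), g)
  expect_equal(rowSums(mc), rep(1, 20))
  expect_true(all(mc[, "m1"] >= mc[, "m2"] - 1e-12))
  # identical graphs share the contribution equally
  mcEq <- modalityContribution(list(a = g, b = g, c = g), g)
  expect_equal(unname(mcEq), matrix(1 / 3, 20, 3))
  # matches the set-intersection oracle
  for (i in 1:5) {
    o1 <- length(intersect(g$indices[i, ], g$indices[i, ])) / 4
    o2 <- length(intersect(gOther$indices[i, ], g$indices[i, ])) / 4
    expect_equal(unname(mc[i, ]), c(o1, o2) / (o1 + o2))
  }
})

test_that("feature-space graphs are scale invariant and match a PCA
          oracle for one modality", {
  set.seed(19)
  X <- matrix(rpois(600, 5), 30, 20)
  g1 <- featureSpaceGraph(list(RNA = X), nComponents = 5, k = 4)
  pc <- prcomp(scale(X), rank. = 5, center = FALSE)$x
  gOracle <- buildKnnGraph(pc, k = 4)
  expect_equal(g1$indices, gOracle$indices)
  # multiplying one modality by 10 leaves the standardized graph unchanged
  Y <- matrix(rnorm(30 * 6), 30, 6)
  gA <- featureSpaceGraph(list(RNA = X, ADT = exp(Y)), nComponents = 4,
                          k = 4)
  gB <- featureSpaceGraph(list(RNA = X, ADT = exp(Y) * 10),
                          nComponents = 4, k = 4)
  expect_equal(gA$indices, gB$indices)
  # duplicated cells are mutual nearest neighbours
  Z <- rbind(X[1, ], X)
  gDup <- featureSpaceGraph(list(RNA = Z), nComponents = 5, k = 4)
  expect_true(2L %in% gDup$indices[1, 1] || 1L %in% gDup$indices[2, 1])
})
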
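test_that("DBSCAN separates distant blobs and labels sparse points as noise", {
  blob <- function(cx, cy) cbind(cx + rep(c(-10, 0, 10), 4)[1:10],
                                 cy + rep(c(-10, 0, 10), each = 4)[1:10])
  pts <- rbind(blob(200, 200), blob(1200, 200))
  lab <- dbscanCluster(pts, eps = 50, minPts = 4)
  expect_equal(sort(unique(lab)), c(1L, 2L))
  expect_equal(unname(table(lab)), c(10L, 10L), ignore_attr = TRUE)

  sparse <- cbind(seq(0, 900, by = 100), seq(0, 900, by = 100))
  expect_true(all(dbscanCluster(sparse, eps = 50, minPts = 2) == -1L))
})

test_that("DBSCAN equals the brute-force transitive-closure oracle on random patterns", {
  for (s in 1:10) {
    n <- c(30, 50, 80, 100)[(s %% 4) + 1]
    pts <- withr::with_seed(s, cbind(runif(n, 0, 600), runif(n, 0, 600)))
    got <- dbscanCluster(pts, eps = 60, minPts = 4)
    want <- oracleDbscan(pts, eps = 60, minPts = 4)
    expect_identical(got, want)
  }
})

test_that("DBSCAN labels are invariant to translation and rotation", {
  pts <- withr::with_seed(7, cbind(runif(60, 0, 500), runif(60, 0, 500)))
  lab <- dbscanCluster(pts, eps = 60, minPts = 4)
  shifted <- pts + matrix(c(1000, -400), 60, 2, byrow = TRUE)
  expect_identical(dbscanCluster(shifted, eps = 60, minPts = 4), lab)
  th <- 0.7
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_identical(dbscanCluster(rot, eps = 60, minPts = 4), lab)
})

test_that("cluster centroids are arithmetic means and translate with the points", {
  pts <- rbind(c(0, 0), c(2, 0))
  expect_equal(clusterCenter(pts, c(1, 1), 1), c(1, 0), ignore_attr = TRUE)
  expect_equal(clusterCenter(rbind(c(5, 7)), 1L, 1), c(5, 7),
               ignore_attr = TRUE)
  expect_error(clusterCenter(pts, c(1, 1), 2), "empty")
  pp <- generatePointPattern(3, 15, 10, 0, field = c(2000, 2000), seed = 2)
  lab <- dbscanCluster(pp, eps = 50, minPts = 4)
  ctr <- clusterCenters(pp, lab)
  shifted <- pp@points + 100
  expect_equal(clusterCenters(shifted, lab), ctr + 100, tolerance = 1e-12)
})

test_that("pair correlation matches the closed form for a single centered point", {
  pp <- PointPattern(points = matrix(c(500, 500), ncol = 2),
                     field = c(1000, 1000))
  pc <- pairCorrelation(pp, matrix(c(500, 500), ncol = 2), binEdges = c(0, 10))
  expect_equal(pc$g, 1e6 / (pi * 100), tolerance = 1e-9)
  expect_equal(pc$count, 1L, ignore_attr = TRUE)
})

test_that("CSR has unit pair correlation in every interior bin", {
  centers <- as.matrix(expand.grid(x = c(600, 1000, 1400),
                                   y = c(600, 1000, 1400)))
  gMat <- t(vapply(1:60, function(s) {
    pp <- generatePointPattern(0, 0, 0, 2000, field = c(2000, 2000), seed = s)
    pairCorrelation(pp, centers, binEdges = seq(0, 200, by = 40))$g
  }, numeric(5)))
  gBar <- colMeans(gMat)
  se <- apply(gMat, 2, sd) / sqrt(nrow(gMat))
  expect_true(all(abs(gBar - 1) < 3 * se + 1e-9))
})

test_that("CSR pair-correlation variance shrinks with pattern size", {
  centers <- matrix(c(1000, 1000), ncol = 2)
  gAt <- function(n, seeds) vapply(seeds, function(s) {
    pp <- generatePointPattern(0, 0, 0, n, field = c(2000, 2000), seed = s)
    pairCorrelation(pp, centers, binEdges = c(0, 200))$g
  }, numeric(1))
  vSmall <- var(gAt(250, 1:40))
  vBig <- var(gAt(2000, 1:40))
  expect_gt(vSmall / vBig, 3)  # expected factor 8
})

test_that("clustered patterns show g > 1 near cluster centers, decaying outward", {
  gMat <- t(vapply(1:100, function(s) {
    pp <- generatePointPattern(5, 40, 25, 100, field = c(4000, 4000),
                               seed = s)
    ctrs <- t(vapply(1:5, function(k)
      colMeans(pp@points[pp@marks == k, , drop = FALSE]), numeric(2)))
    pairCorrelation(pp, ctrs, binEdges = seq(0, 300, by = 50))$g
  }, numeric(6)))
  gBar <- colMeans(gMat)
  expect_gt(gBar[1], 1)
  expect_gt(gBar[1], gBar[2])
  expect_gt(gBar[2], gBar[3])
  expect_lt(abs(gBar[6] - 1), 0.3)
})

test_that("end-to-end cluster analysis restates near-center enrichment", {
  pp <- generatePointPattern(4, 60, 20, 80, field = c(3000, 3000), seed = 12)
  lab <- dbscanCluster(pp, eps = 60, minPts = 5)
  expect_gte(max(lab), 4L)
  ctrs <- clusterCenters(pp, lab)
  pc <- pairCorrelation(pp, ctrs, binEdges = seq(0, 400, by = 80))
  expect_gt(pc$g[1], pc$g[5])
  expect_gt(pc$g[1], 1)
})

test_that("degenerate spatial inputs are rejected or exact", {
  pp0 <- generatePointPattern(2, 10, 0, 0, field = c(1000, 1000), seed = 1)
  # sigma 0: offspring coincide with parents
  expect_equal(nrow(unique(pp0@points)), 2L)
  ppN <- generatePointPattern(0, 0, 0, 55, field = c(1000, 1000), seed = 1)
  expect_equal(length(ppN), 55L)
  expect_error(generatePointPattern(-1, 5, 10, 0), "counts")
  expect_error(pairCorrelation(ppN, matrix(c(2000, 0), ncol = 2), c(0, 10)),
               "within the field")
  expect_error(pairCorrelation(ppN, matrix(c(500, 500), ncol = 2), c(10, 10)),
               "increasing")
})
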
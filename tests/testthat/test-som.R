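test_that("toroidal grid distance wraps around", {
  expect_equal(toroidalGridDistance(c(0, 0), c(9, 0), 10, 10), 1)
  expect_equal(toroidalGridDistance(c(0, 0), c(0, 0), 5, 5), 0)
  expect_equal(toroidalGridDistance(c(0, 0), c(2, 2), 10, 10), sqrt(8))
  expect_equal(toroidalGridDistance(c(1, 1), c(3, 9), 4, 10), sqrt(4 + 4))
  expect_error(toroidalGridDistance(c(0, 0), c(5, 0), 5, 5), "outside")
})

test_that("SOM recovers planted orthogonal patterns across seeds", {
  m <- rbind(matrix(rep(c(1, 1, 1, 1, 0, 0, 0, 0), 12), 12, byrow = TRUE),
             matrix(rep(c(0, 0, 0, 0, 1, 1, 1, 1), 12), 12, byrow = TRUE))
  rownames(m) <- paste0("g", 1:24)
  colnames(m) <- paste0("t", 1:8)
  truth <- rep(1:2, each = 12)
  aris <- vapply(1:10, function(s) {
    g <- trainSOM(m, rows = 2, cols = 2, epochs = 20, seed = s)
    cl <- clusterSomCells(binarizePrototypes(g), 2)
    adjRandIndex(promoterClusters(g, cl$cellCluster), truth)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("identical rows collapse to one cell with the common codebook", {
  m <- matrix(rep(c(1, 0, 1, 0, 0), 20), 20, byrow = TRUE,
              dimnames = list(paste0("g", 1:20), paste0("t", 1:5)))
  g <- trainSOM(m, rows = 2, cols = 2, epochs = 10, seed = 3)
  expect_equal(length(unique(somAssignment(g))), 1L)
  cell <- unique(somAssignment(g))
  expect_equal(unname(somCodebook(g)[cell, ]), c(1, 0, 1, 0, 0))
  expect_true(all(somCodebook(g) >= 0 & somCodebook(g) <= 1))
  # prototype at threshold 0.5 equals the common row
  expect_equal(unname(binarizePrototypes(g)[cell, ]), c(1L, 0L, 1L, 0L, 0L))
})

test_that("training is reproducible and stable under row shuffling", {
  cfg <- tinyConfig(nTfs = 12, nPromoters = 60, nBindingClusters = 3,
                    bindingNoise = 0.05)
  m <- generateCistromes(cfg)$membership
  g1 <- trainSOM(m, rows = 3, cols = 3, epochs = 15, seed = 5)
  g2 <- trainSOM(m, rows = 3, cols = 3, epochs = 15, seed = 5)
  expect_identical(somCodebook(g1), somCodebook(g2))
  perm <- withr::with_seed(1, sample(nrow(m)))
  g3 <- trainSOM(m[perm, ], rows = 3, cols = 3, epochs = 15, seed = 5)
  c1 <- promoterClusters(g1, clusterSomCells(binarizePrototypes(g1),
                                             3)$cellCluster)
  c3 <- promoterClusters(g3, clusterSomCells(binarizePrototypes(g3),
                                             3)$cellCluster)
  expect_gte(adjRandIndex(c1[rownames(m)], c3[rownames(m)]), 0.8)
})

test_that("planted clusters are topologically compact on the torus", {
  cfg <- tinyConfig(nTfs = 12, nPromoters = 80, nBindingClusters = 2)
  cis <- generateCistromes(cfg)
  g <- trainSOM(cis$membership, rows = 4, cols = 4, epochs = 15, seed = 2)
  co <- cbind(rep(0:3, each = 4), rep(0:3, 4))
  a <- somAssignment(g)
  cl <- cis$truth$promoterCluster[names(a)]
  pairDist <- function(i, j)
    toroidalGridDistance(co[a[i], ], co[a[j], ], 4, 4)
  idx <- t(combn(length(a), 2))
  d <- vapply(seq_len(nrow(idx)), function(r)
    pairDist(idx[r, 1], idx[r, 2]), numeric(1))
  same <- cl[idx[, 1]] == cl[idx[, 2]]
  expect_lt(mean(d[same]), mean(d[!same]))
})

test_that("Ward cut matches the brute-force objective and labeling rule", {
  # two blocks of identical prototypes: exact partition
  prot <- rbind(matrix(rep(c(1, 1, 0, 0, 0, 0), 3), 3, byrow = TRUE),
                matrix(rep(c(1, 1, 1, 1, 1, 0), 3), 3, byrow = TRUE))
  cl <- clusterSomCells(prot, 2)
  expect_equal(as.character(cl$cellCluster), rep(c("A", "B"), each = 3))
  # larger mean prototype sum gets the later letter
  expect_lt(cl$complexity[["A"]], cl$complexity[["B"]])
  # toy 8-cell case: Ward partitions equal greedy ESS minimization
  # (continuous coordinates: generic position, no merge-cost ties)
  set.seed(12)
  x <- matrix(runif(8 * 6), 8, 6)
  tree <- hclust(dist(x), method = "ward.D2")
  oracle <- bruteForceWardPartitions(x)
  for (k in 2:(nrow(x) - 1))
    expect_equal(adjRandIndex(cutree(tree, k), oracle[[k]]), 1,
                 info = paste("k =", k))
  expect_error(clusterSomCells(prot, 5), "distinct prototypes")
})

test_that("homogeneity curve is monotone, reaches 1, and finds the elbow", {
  prot <- rbind(matrix(rep(c(1, 1, 0, 0, 0, 0), 4), 4, byrow = TRUE),
                matrix(rep(c(0, 0, 1, 1, 0, 0), 4), 4, byrow = TRUE),
                matrix(rep(c(0, 0, 0, 0, 1, 1), 4), 4, byrow = TRUE))
  hom <- homogeneityAnalysis(prot, kRange = 2:11)
  expect_true(all(diff(hom$homogeneity) >= -1e-12))
  expect_equal(hom$suggestedK, 3L)
  expect_equal(unname(hom$homogeneity[as.character(3:11)]),
               rep(1, 9))
  full <- homogeneityAnalysis(prot, kRange = c(2, nrow(prot)))
  expect_equal(unname(full$homogeneity[as.character(nrow(prot))]), 1)
})

test_that("cell summaries average gene values and conserve the total", {
  m <- matrix(c(1, 1, 0, 1, 1, 0, 0, 1, 1, 0, 1, 1), 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), c("a", "b", "c")))
  g <- trainSOM(m, rows = 2, cols = 2, epochs = 5, seed = 1)
  vals <- c(g1 = 2, g2 = 4, g3 = 1, g4 = 3)
  cm <- cellSummaryMap(g, vals)
  a <- somAssignment(g)
  sizes <- tabulate(a, 4)
  expect_true(all(is.na(cm[matrix(c(1 + (which(sizes == 0) - 1) %/% 2,
                                    1 + (which(sizes == 0) - 1) %% 2),
                                  ncol = 2)])))
  expect_equal(sum(cm * matrix(sizes, 2, byrow = TRUE), na.rm = TRUE),
               sum(vals))
  # direct check: one cell valued {2,4} averages to 3
  cm2 <- cellSummaryMap(g, c(g1 = 2, g2 = 2, g3 = 4, g4 = 4))
  expect_equal(sum(cm2 * matrix(sizes, 2, byrow = TRUE), na.rm = TRUE), 12)
})
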
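test_that("activity strata recover planted levels and order by activity", {
  set.seed(1)
  lv <- rep(1:4, each = 25)
  feats <- cbind(acc = 2^lv, ace = 2^lv, expr = 2^lv)
  rownames(feats) <- paste0("g", seq_along(lv))
  st <- activityStrata(feats, k = 4)
  expect_equal(adjRandIndex(st, lv), 1)
  expect_equal(unname(tapply(rowMeans(feats), st, mean)),
               sort(unname(tapply(rowMeans(feats), st, mean))))
  # strict planted recovery maps stratum i to level i (ascending activity)
  expect_equal(unname(st), lv)
  same <- feats; same[] <- 3
  expect_error(activityStrata(same, k = 2), "degenerate")
  featsNA <- feats; featsNA[3, 2] <- NA
  expect_error(activityStrata(featsNA, k = 4), "g3")
})

test_that("matched control sets preserve per-stratum counts exactly", {
  strata <- setNames(rep(1:4, times = c(30, 25, 20, 15)), paste0("g", 1:90))
  identity_ <- c(paste0("g", 1:3), paste0("g", 31:32), "g56")  # (3,2,1,0)
  pool <- setdiff(names(strata), identity_)
  ens <- sampleMatchedControls(identity_, pool, strata, nIter = 50,
                               seed = 4)
  need <- table(strata[identity_])
  for (s in controlSets(ens)) {
    expect_equal(as.vector(table(factor(strata[s], 1:4))[1:3]),
                 as.vector(need))
    expect_length(intersect(s, identity_), 0)
    expect_false(anyDuplicated(s) > 0)
  }
  # insufficient stratum errors by name
  tiny <- setNames(c(1, 1, 2), c("a", "b", "c"))
  expect_error(sampleMatchedControls(c("a", "b"), "c", tiny, 5, 1),
               "stratum 1")
})

test_that("inclusion frequencies are uniform within binomial bounds", {
  strata <- setNames(rep(1:2, times = c(14, 12)), paste0("g", 1:26))
  identity_ <- c("g1", "g2", "g3", "g15", "g16")       # needs (3, 2)
  pool <- setdiff(names(strata), identity_)
  nIter <- 1000
  ens <- sampleMatchedControls(identity_, pool, strata, nIter = nIter,
                               seed = 9)
  counts <- table(factor(unlist(controlSets(ens)), levels = pool))
  pr <- ifelse(strata[pool] == 1, 3 / 11, 2 / 10)
  # family-wise 99% binomial bounds (Bonferroni across candidates)
  alpha <- 0.01 / length(pool)
  lo <- qbinom(alpha / 2, nIter, pr)
  hi <- qbinom(1 - alpha / 2, nIter, pr)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("representative set sits at the p-value mode", {
  ens <- new("ControlSetEnsemble", identity = c("i1", "i2"),
             sets = list(c("a", "b"), c("c", "d"), c("e", "f"),
                         c("g", "h")),
             pvalues = rep(NA_real_, 4), representative = NA_integer_)
  fakeP <- c(0.011, 0.012, 0.013, 0.5)
  values <- setNames(seq_len(10) / 10,
                     c("i1", "i2", letters[1:8]))
  i <- 0
  statFn <- function(a, b) { i <<- i + 1; fakeP[i] }
  ens <- selectRepresentativeSet(ens, values, statFn)
  expect_lte(representativeIndex(ens), 3L)     # among the modal-bin sets
  expect_equal(setPvalues(ens), fakeP)
  # all p equal: first set selected
  j <- 0
  statEq <- function(a, b) { j <<- j + 1; 0.3 }
  ens2 <- selectRepresentativeSet(ens, values, statEq)
  expect_equal(representativeIndex(ens2), 1L)
})

test_that("modal selection recovers the most frequent discrete p-value", {
  set.seed(123)
  genes <- paste0("g", 1:120)
  strata <- setNames(rep(1:2, length.out = 120), genes)
  identity_ <- genes[1:10]
  vals <- setNames(c(rnorm(10, -1.5), rnorm(110)), genes)
  ens <- sampleMatchedControls(identity_, genes[-(1:10)], strata,
                               nIter = 300, seed = 1)
  ens <- selectRepresentativeSet(ens, vals)
  p <- setPvalues(ens)
  tab <- table(p)
  modal <- min(as.numeric(names(tab)[tab == max(tab)]))
  expect_equal(p[representativeIndex(ens)], unname(modal))
  # binned variant remains available and picks near the modal bin center
  ensB <- selectRepresentativeSet(ens, vals, binWidth = 0.25)
  counts <- tabulate(pmin(floor(p / 0.25) + 1, 4), 4)
  ctr <- (which.max(counts) - 0.5) * 0.25
  expect_equal(setPvalues(ensB)[representativeIndex(ensB)],
               p[which.min(abs(p - ctr))])
})

test_that("rank-sum test is exact for small ties-free samples", {
  expect_equal(groupShiftTest(c(1, 2, 3), c(4, 5, 6), "less"), 0.05)
  expect_equal(groupShiftTest(c(1, 2, 3), c(1, 2, 3), "two.sided"), 1)
  expect_warning(p1 <- groupShiftTest(rep(2, 5), rep(2, 4)), "degenerate")
  expect_equal(p1, 1)
  # one-sided p-values overlap at the observed statistic
  set.seed(6)
  for (rep_ in 1:10) {
    a <- rnorm(8); b <- rnorm(12)
    expect_gte(groupShiftTest(a, b, "less") +
                 groupShiftTest(a, b, "greater"), 1)
  }
})

test_that("null p-values are uniform and the test has power", {
  set.seed(99)
  ps <- vapply(1:500, function(i)
    groupShiftTest(rnorm(20), rnorm(20), "two.sided"), numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, punif))$p.value, 0.01)
  set.seed(100)
  rej <- vapply(1:500, function(i)
    groupShiftTest(rnorm(26, -1), rnorm(26), "less") < 0.05, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("BH adjustment matches the reference step-up", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(13)
  for (rep_ in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bhAdjust(p), bruteForceBH(p))
  }
})

test_that("odds ratios and Fisher p match hypergeometric enumeration", {
  res <- enrichmentOddsRatio(10, 10, 5, 20)
  expect_equal(res$log2OR, 2)
  flat <- enrichmentOddsRatio(1, 1, 1, 1)
  expect_equal(flat$log2OR, 0)
  expect_equal(flat$p.value, 1)
  # Haldane correction on zero cells keeps the estimate finite
  z <- enrichmentOddsRatio(5, 0, 3, 7)
  expect_true(is.finite(z$log2OR))
  expect_true(is.na(enrichmentOddsRatio(0, 0, 3, 7)$log2OR))
  set.seed(21)
  for (rep_ in 1:10) {
    cells <- rpois(4, 6) + 1
    got <- enrichmentOddsRatio(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p.value,
                 bruteForceFisherP(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-7)
  }
})

test_that("Kruskal-Wallis wrapper agrees with the two-group rank-sum", {
  g3 <- list(a = c(1, 5, 9), b = c(1, 5, 9), c = c(1, 5, 9))
  res <- kruskalPairwise(g3)
  expect_gt(res$omnibus.p, 0.9)
  expect_true(all(res$pairwise$q > 0.9))
  set.seed(17)
  a <- rnorm(15); b <- rnorm(15, 1)
  res2 <- kruskalPairwise(list(a = a, b = b))
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                      correct = FALSE))$p.value
  expect_equal(res2$omnibus.p, ref, tolerance = 1e-6)
  # H invariant under monotone transformation
  g <- list(x = c(0.2, 1, 4), y = c(9, 16, 30), z = c(2, 5, 7))
  expect_equal(kruskalPairwise(g)$omnibus.p,
               kruskalPairwise(lapply(g, log))$omnibus.p)
})
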
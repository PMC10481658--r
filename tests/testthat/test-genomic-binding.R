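library(GenomicRanges)

test_that("peak merging produces CRMs with >= 2 regulators", {
  cis <- list(TF1 = GRanges("chr1", IRanges(101, 200)),
              TF2 = GRanges("chr1", IRanges(151, 250)),
              TF3 = GRanges("chr1", IRanges(301, 400)))
  crms <- mergePeaksToCrms(cis)
  expect_length(crms, 1L)
  expect_equal(c(start(crms), end(crms)), c(101, 250))
  expect_equal(sort(unname(unlist(mcols(crms)$bound_tfs))),
               c("TF1", "TF2"))
  # identical peak sets: CRMs equal the shared intervals
  same <- GRanges("chr1", IRanges(c(10, 500), c(60, 580)))
  crms2 <- mergePeaksToCrms(list(A = same, B = same))
  expect_equal(granges(crms2), granges(same))
  expect_true(all(lengths(mcols(crms2)$bound_tfs) == 2L))
  expect_error(mergePeaksToCrms(list()), "input error")
  # touching-but-not-overlapping peaks stay separate
  touch <- mergePeaksToCrms(list(A = GRanges("chr1", IRanges(1, 100)),
                                 B = GRanges("chr1", IRanges(101, 200))))
  expect_length(touch, 0L)
})

test_that("peak merging equals the brute-force connected components", {
  set.seed(42)
  for (rep_ in 1:5) {
    cis <- lapply(setNames(1:5, paste0("T", 1:5)), function(i) {
      n <- sample(3:8, 1)
      st <- sort(sample(1:500, n))
      GRanges("chr1", IRanges(st, width = sample(10:80, n, replace = TRUE)))
    })
    crms <- mergePeaksToCrms(cis)
    oracle <- bruteForceCrms(cis)
    expect_equal(length(crms), length(oracle))
    expect_equal(start(crms), unname(vapply(oracle, `[[`, 1, "start")))
    expect_equal(end(crms), unname(vapply(oracle, `[[`, 1, "end")))
    for (i in seq_along(oracle))
      expect_equal(sort(unname(unlist(mcols(crms)$bound_tfs[i]))),
                   oracle[[i]]$tfs)
  }
})

test_that("CRM construction is idempotent", {
  set.seed(7)
  cis <- lapply(setNames(1:4, paste0("T", 1:4)), function(i)
    GRanges("chr1", IRanges(sort(sample(1:300, 5)),
                            width = sample(20:60, 5, replace = TRUE))))
  crms <- mergePeaksToCrms(cis)
  # re-merge, presenting each CRM as a peak of each of its regulators
  tfs <- sort(unique(unlist(mcols(crms)$bound_tfs)))
  again <- mergePeaksToCrms(lapply(setNames(tfs, tfs), function(tf)
    granges(crms[vapply(mcols(crms)$bound_tfs, function(s) tf %in% s,
                        logical(1))])))
  expect_equal(granges(again), granges(crms))
  expect_equal(as.list(mcols(again)$bound_tfs),
               as.list(mcols(crms)$bound_tfs))
})

test_that("promoter mapping drops ambiguous and filtered genes", {
  crms <- GRanges("chr1", IRanges(c(100, 400), c(250, 500)))
  mcols(crms)$bound_tfs <- IRanges::CharacterList(list(c("A", "B"),
                                                       c("B", "C")))
  tss <- GRanges("chr1", IRanges(c(150, 150, 420, 470, 600), width = 1),
                 gene_id = c("g1", "g1dup", "g2", "g2", "g3"))
  # TSS at 150 shared by two gene ids -> both dropped; g2 has two TSSs ->
  # dropped; g3 outside CRMs -> no record
  rec <- mapCrmsToPromoters(crms, tss)
  expect_length(rec, 0L)
  tss2 <- GRanges("chr1", IRanges(c(150, 420), width = 1),
                  gene_id = c("g1", "g2"))
  rec2 <- mapCrmsToPromoters(crms, tss2)
  expect_equal(mcols(rec2)$gene_id, c("g1", "g2"))
  rec3 <- mapCrmsToPromoters(crms, tss2, geneFilter = "g2")
  expect_equal(mcols(rec3)$gene_id, "g2")
  # one TSS overlapping two CRMs: bound sets union, interval spans both
  crmsAdj <- GRanges("chr1", IRanges(c(100, 150), c(200, 300)))
  mcols(crmsAdj)$bound_tfs <- IRanges::CharacterList(list(c("A", "B"),
                                                          c("C", "D")))
  tssSpan <- GRanges("chr1", IRanges(160, width = 1), gene_id = "gx")
  recSpan <- mapCrmsToPromoters(crmsAdj, tssSpan)
  expect_length(recSpan, 1L)
  expect_equal(c(start(recSpan), end(recSpan)), c(100, 300))
  expect_equal(sort(unname(unlist(mcols(recSpan)$bound_tfs))),
               c("A", "B", "C", "D"))
})

test_that("binding matrix mirrors the bound-TF sets", {
  rec <- GRanges("chr1", IRanges(c(1, 100), c(50, 160)),
                 gene_id = c("g1", "g2"),
                 bound_tfs = IRanges::CharacterList(list(c("A", "B"),
                                                         c("B", "C"))))
  bm <- buildBindingMatrix(rec, tfUniverse = c("A", "B", "C"))
  expect_equal(unname(bindingMatrix(bm)),
               matrix(c(1L, 0L, 1L, 1L, 0L, 1L), 2))
  expect_equal(rowSums(bindingMatrix(bm)),
               c(g1 = 2, g2 = 2))
  recDup <- c(rec, rec[1])
  expect_error(buildBindingMatrix(recDup), "duplicate")
})

test_that("zero-noise synthetic run reproduces the planted design", {
  cfg <- tinyConfig()
  cis <- generateCistromes(cfg)
  tss <- generateTssAnnotation(cfg)$tss
  crms <- mergePeaksToCrms(as.list(cis$cistromes))
  rec <- mapCrmsToPromoters(crms, tss,
                            geneFilter = names(cis$truth$promoterCluster))
  bm <- buildBindingMatrix(rec, tfUniverse = cfg$tfNames)
  expect_equal(bindingMatrix(bm), cis$membership)
  # column marginals match independent per-TF overlap counts
  marg <- vapply(cfg$tfNames, function(tf)
    sum(countOverlaps(promoterRanges(bm),
                      cis$cistromes[[tf]]) > 0), 1L)
  expect_equal(colSums(bindingMatrix(bm)), marg)
})

test_that("promoter signal extraction equals the per-base maximum", {
  track <- GRanges("chr1", IRanges(c(1, 51, 101), c(50, 100, 150)))
  mcols(track)$score <- c(3, 7.5, 2)
  rec <- GRanges("chr1", IRanges(c(10, 60, 140, 200), c(40, 120, 180, 220)),
                 gene_id = paste0("g", 1:4))
  sig <- extractPromoterSignal(track, rec)
  # g3 partially covered (negative scores impossible here): max vs 0
  expect_equal(unname(sig), c(3, 7.5, 2, 0))
  # brute force per-base oracle on random tracks
  set.seed(9)
  for (rep_ in 1:5) {
    st <- seq(1, 200, by = 10)
    tr <- GRanges("chr1", IRanges(st, width = 10))
    mcols(tr)$score <- rnorm(length(st))
    iv <- GRanges("chr1", IRanges(sample(1:150, 4), width = 30),
                  gene_id = paste0("g", 1:4))
    base <- rep(0, 300)
    for (i in seq_along(tr))
      base[start(tr)[i]:end(tr)[i]] <- mcols(tr)$score[i]
    want <- vapply(seq_along(iv), function(i)
      max(base[start(iv)[i]:end(iv)[i]]), numeric(1))
    expect_equal(unname(extractPromoterSignal(tr, iv)), want)
  }
})

test_that("breadth assignment requires distance zero", {
  domains <- GRanges("chr1", IRanges(c(1, 8000), width = c(5000, 1000)))
  tss <- GRanges("chr1", IRanges(c(2500, 5001, 8500), width = 1),
                 gene_id = c("in1", "out1", "in2"))
  b <- assignH3k4me3Breadth(domains, tss)
  expect_equal(unname(b), c(5000, NA, 1000))
  # brute-force nearest-interval scan, 5 domains x 8 TSSs
  set.seed(4)
  dom <- GRanges("chr1", IRanges(sort(sample(seq(1, 5000, 100), 5)),
                                 width = sample(50:400, 5)))
  t8 <- GRanges("chr1", IRanges(sample(1:5500, 8), width = 1),
                gene_id = paste0("g", 1:8))
  got <- assignH3k4me3Breadth(dom, t8)
  for (i in 1:8) {
    p <- start(t8)[i]
    d <- pmax(start(dom) - p, p - end(dom), 0)
    want <- if (min(d) == 0) width(dom)[which(d == 0)[1]] else NA_real_
    expect_equal(unname(got[i]), want)
  }
})

test_that("peak counting honors the +/- window", {
  tss <- GRanges("chr1", IRanges(20000, width = 1), gene_id = "g")
  peaks <- GRanges("chr1", IRanges(c(15000, 30001, 9000), width = 200))
  # 5 kb upstream counted; starting 10,001 bp downstream not; far peak not
  expect_equal(unname(countPeaksNearTss(peaks, tss, 10000)), 1L)
  expect_equal(unname(countPeaksNearTss(peaks, tss, 11000)), 3L)
  set.seed(3)
  p <- GRanges("chr1", IRanges(sample(1:40000, 30), width = 150))
  got <- countPeaksNearTss(p, tss, 10000)
  want <- sum(start(p) <= 30000 & end(p) >= 10000)
  expect_equal(unname(got), want)
})

test_that("active-TSS filter keeps enriched TSSs, best per gene", {
  bins <- GRanges("chr1", IRanges(seq(1, 4000, 100), width = 100))
  sig <- bins; ctl <- bins
  mcols(ctl)$score <- rep(1, length(bins))
  s <- rep(1, length(bins))
  s[start(bins) < 1200] <- 4          # around TSS1: enriched
  s[start(bins) >= 1200 & start(bins) < 2400] <- 1.9   # TSS2: below 2x
  s[start(bins) >= 2400] <- 6         # TSS3/TSS4 (same gene): enriched
  mcols(sig)$score <- s
  tss <- GRanges("chr1", IRanges(c(600, 1800, 2900, 3900), width = 1),
                 gene_id = c("g1", "g2", "g3", "g3"))
  kept <- selectActiveTss(tss, sig, ctl)
  expect_equal(sort(mcols(kept)$gene_id), c("g1", "g3"))
  expect_equal(sum(mcols(kept)$gene_id == "g3"), 1L)
  g3 <- kept[mcols(kept)$gene_id == "g3"]
  expect_equal(start(g3), 2900)   # fully covered window has higher mean
})
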
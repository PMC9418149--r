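# Pairwise Phi-ST, AMOVA, and PCoA.

test_that("two-level AMOVA matches the hand sums-of-squares oracle", {
  set.seed(423)
  for (rep in 1:5) {
    aln <- randomToyAlignment(15, 30, pops = rep(c("P1", "P2", "P3"),
                                                 each = 5))
    am <- amova(aln, nPerm = 20, seed = 1)
    d <- seqDistances(aln)$d
    orc <- oracleAmova(d, sampleData(aln)$population)
    expect_equal(am$components$sigma2, orc$sigma2, tolerance = 1e-9)
    expect_equal(am$components$SS, orc$SS, tolerance = 1e-9)
    expect_equal(unname(am$phi["Phi_ST"]), orc$phiST, tolerance = 1e-9)
    expect_equal(sum(am$components$percent), 100, tolerance = 1e-6)
  }
})

test_that("three-level AMOVA matches the hand oracle with grouping", {
  set.seed(424)
  for (rep in 1:4) {
    pops <- rep(c("P1", "P2", "P3", "P4"), times = c(4, 5, 4, 6))
    aln <- randomToyAlignment(length(pops), 35, pops = pops)
    layout <- list(G1 = c("P1", "P2"), G2 = c("P3", "P4"))
    am <- amova(aln, layout = layout, nPerm = 20, seed = 2)
    d <- seqDistances(aln)$d
    grp <- ifelse(sampleData(aln)$population %in% c("P1", "P2"),
                  "G1", "G2")
    orc <- oracleAmova(d, sampleData(aln)$population, grp)
    expect_equal(am$components$sigma2, orc$sigma2, tolerance = 1e-9)
    expect_equal(am$components$SS, orc$SS, tolerance = 1e-9)
    expect_equal(unname(am$phi), unname(orc$phi), tolerance = 1e-9)
  }
  # a single population is refused
  aln1 <- randomToyAlignment(6, 20)
  expect_error(amova(aln1), "two populations")
})

test_that("pairwise Phi-ST equals the two-population AMOVA Phi-ST", {
  set.seed(425)
  aln <- randomToyAlignment(18, 40, pops = rep(c("A", "B", "C"), each = 6))
  fst <- pairwiseFst(aln, nPerm = 50, seed = 3)
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    ids <- sampleData(aln)$sample_id[sampleData(aln)$population %in% pr]
    am <- amova(aln[ids], nPerm = 10, seed = 4)
    expect_equal(fst$fst[pr[1], pr[2]], unname(am$phi["Phi_ST"]),
                 tolerance = 1e-12)
  }
  expect_identical(fst$fst, t(fst$fst))
  expect_true(all(diag(fst$fst) == 0))
})

test_that("Phi-ST limits: panmixia near zero, fixation exactly one", {
  # two populations drawn identically from one panmictic pool
  set.seed(426)
  pool <- randomToyAlignment(40, 60)
  pops <- rep(c("X", "Y"), each = 20)
  aln <- matriline:::alignmentFromStates(
    states(pool), transform(sampleData(pool), population = pops),
    reference(pool))
  fst <- pairwiseFst(aln, nPerm = 200, seed = 5)
  expect_lt(abs(fst$fst["X", "Y"]), 0.05)
  expect_gt(fst$p["X", "Y"], 0.05)

  # two populations fixed for haplotypes k > 0 sites apart
  rows <- c(rep("AAAAAAAA", 5), rep("AAAAAGGG", 5))
  aln2 <- toyAlignment(rows, "AAAAAAAA",
                       pops = rep(c("P1", "P2"), each = 5))
  fst2 <- pairwiseFst(aln2, nPerm = 100, seed = 6)
  expect_equal(unname(fst2$fst["P1", "P2"]), 1, tolerance = 1e-12)
  expect_lt(fst2$p["P1", "P2"], 0.05)
})

test_that("permutation p-values are seed-reproducible and label-invariant", {
  set.seed(427)
  aln <- randomToyAlignment(16, 30, pops = rep(c("A", "B"), each = 8))
  f1 <- pairwiseFst(aln, nPerm = 100, seed = 7)
  f2 <- pairwiseFst(aln, nPerm = 100, seed = 7)
  expect_identical(f1$fst, f2$fst)
  expect_identical(f1$p, f2$p)
  # reversing sample order leaves the estimates unchanged
  aln2 <- aln[rev(seq_len(length(aln)))]
  f3 <- pairwiseFst(aln2, nPerm = 100, seed = 7)
  expect_equal(f3$fst["A", "B"], f1$fst["A", "B"], tolerance = 1e-12)
  # populations with < 2 sequences are excluded with a warning
  meta <- sampleData(aln)
  meta$population[1] <- "Solo"
  aln3 <- matriline:::alignmentFromStates(states(aln), meta,
                                          reference(aln))
  expect_warning(f4 <- pairwiseFst(aln3, nPerm = 20, seed = 8), "Solo")
  expect_false("Solo" %in% rownames(f4$fst))
})

test_that("AMOVA permutation schemes give sane p-values under structure", {
  # strong grouping signal: two groups of fixed, distant haplotypes
  rows <- c(rep("AAAAAAAAAA", 6), rep("AAAAAAAAGG", 6),
            rep("GGGGGAAAAA", 6), rep("GGGGGAAAGG", 6))
  pops <- rep(c("P1", "P2", "P3", "P4"), each = 6)
  aln <- toyAlignment(rows, "AAAAAAAAAA", pops = pops)
  am <- amova(aln, layout = list(G1 = c("P1", "P2"), G2 = c("P3", "P4")),
              nPerm = 200, seed = 9)
  expect_lt(am$p["Phi_ST"], 0.05)
  expect_gt(am$phi[["Phi_CT"]], 0.5)
  # identical population multisets: among-population share near zero (the
  # estimator is slightly negative at finite n, reported untruncated)
  rows2 <- rep(c("AAGGAAAAAA", "AAAAAAAAGG", "GGAAGAAAAA"), times = 16)
  aln2 <- toyAlignment(rows2, "AAAAAAAAAA",
                       pops = rep(c("Q1", "Q2"), each = 24))
  am2 <- amova(aln2, nPerm = 100, seed = 10)
  expect_lt(abs(am2$components$percent[1]), 5)
  expect_gt(am2$components$percent[2], 95)
})

test_that("PCoA recovers a planted Euclidean configuration", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4), c(5, 5))
  rownames(pts) <- paste0("P", 1:4)
  d <- as.matrix(dist(pts))
  pc <- pcoaFromFst(d)
  rec <- as.matrix(dist(pc$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  # axis percentages sum to 100 over positive eigenvalues, ordered
  pos <- which(!is.na(pc$percent))
  expect_equal(sum(pc$percent[pos]), 100, tolerance = 1e-9)
  expect_true(all(diff(pc$eigenvalues[pos]) <= 1e-12))
  # degenerate all-zero input is flagged
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(pcoaFromFst(z)$degenerate)
})

test_that("Phi-ST rises monotonically with generator divergence", {
  tree <- cdvMotifTree()
  ref <- defaultReference()
  demes <- data.frame(name = c("D1", "D2"), region = c("r", "r"),
                      n = c(15, 15))
  comp <- list(D1 = c(A = 1), D2 = c(A = 1))
  levelsK <- c(0, 5, 10, 20, 40)
  # three replicate datasets per level; level means must be strictly
  # ordered (rank correlation 1 with the imposed divergence)
  fstMean <- vapply(seq_along(levelsK), function(i) {
    mean(vapply(1:3, function(repl) {
      sp <- simSpec(demes, comp, thetaWithin = 3,
                    divergenceExtra = levelsK[i], migrationShare = 0,
                    seed = 1000 * repl + i)
      ds <- generateDataset(sp, tree, ref)
      pairwiseFst(ds$aln, nPerm = 10, seed = 1)$fst["D1", "D2"]
    }, 0))
  }, 0)
  expect_identical(order(fstMean), seq_along(levelsK))
  expect_equal(cor(fstMean, levelsK, method = "spearman"), 1)
})
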
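# The synthetic-data generator and its ground truth.

tree <- cdvMotifTree()
ref <- defaultReference()

test_that("bundled reference was produced by the generator recipe", {
  toks <- unique(unlist(treeNodes(tree)$motifs))
  regen <- makeSyntheticReference(toks)
  expect_identical(refBases(regen), refBases(ref))
  # reference honours every ancestral base the scheme requires
  mv <- parseMotifs(toks)
  expect_identical(refBases(ref)[mv$position], mv$ancestral)
})

test_that("founders differ from the reference exactly at their motif path", {
  founders <- makeFounders(tree, ref)
  expect_identical(founders[["ROOT"]], paste(refBases(ref), collapse = ""))
  fV <- strsplit(founders[["V"]], "")[[1]]
  diffs <- which(fV != refBases(ref))
  mv <- parseMotifs(motifPath(tree, "V"))
  expect_setequal(diffs, mv$position)
  expect_identical(fV[sort(mv$position)],
                   mv$derived[order(mv$position)])
  # D1b founder re-scored through anchoring + classification returns D1b
  a <- anchorToReference(founders[["D1b"]], ref)
  aln <- matriline:::alignmentFromStates(
    matrix(a$states, 1, dimnames = list("x", NULL)),
    data.frame(sample_id = "x", population = "P", region = "R"), ref)
  cls <- classifyHaplogroups(callSubstitutions(aln), tree,
                             sampleIds = "x")
  expect_identical(cls$haplogroup, "D1b")
})

test_that("theta = 0 with one founder yields a monomorphic deme", {
  sp <- simSpec(data.frame(name = "D", region = "r", n = 8),
                list(D = c(V = 1)), thetaWithin = 0, seed = 21)
  ds <- generateDataset(sp, tree, ref)
  expect_identical(length(unique(ds$sequences)), 1L)
  part <- collapseHaplotypes(ds$aln)
  expect_identical(nHaplotypes(part), 1L)
  expect_equal(haplotypeDiversity(part)$Hd, 0)
  expect_equal(nucleotideDiversity(ds$aln)$pi, 0)
})

test_that("two demes fixed for different founders force the known limits", {
  sp <- simSpec(data.frame(name = c("X", "Y"), region = c("r", "r"),
                           n = c(6, 6)),
                list(X = c(V = 1), Y = c(ROOT = 1)),
                thetaWithin = 0, seed = 22)
  ds <- generateDataset(sp, tree, ref)
  k <- length(motifPath(tree, "V"))
  fst <- pairwiseFst(ds$aln, nPerm = 50, seed = 1)
  expect_equal(unname(fst$fst["X", "Y"]), 1)
  net <- medianJoiningNetwork(collapseHaplotypes(ds$aln))
  e <- networkEdges(net)
  expect_identical(nrow(e), 1L)
  expect_equal(e$steps, k)
})

test_that("generation is bit-reproducible and truth verifies exactly", {
  demes <- data.frame(name = c("P1", "P2", "P3"),
                      region = c("M", "M", "I"), n = c(25, 20, 15))
  comp <- list(P1 = c(D2 = 0.4, A = 0.6), P2 = c(V = 0.5, V2 = 0.5),
               P3 = c(D1b = 1))
  sp <- simSpec(demes, comp, thetaWithin = 3, divergenceExtra = 1,
                migrationShare = 0.1, seed = 23)
  ds1 <- generateDataset(sp, tree, ref)
  ds2 <- generateDataset(sp, tree, ref)
  expect_identical(ds1$sequences, ds2$sequences)

  vt <- verifyTruth(ds1, tree)
  expect_equal(vt$classifierAccuracy, 1)
  expect_equal(vt$randIndex, 1)
  expect_identical(nrow(vt$misclassified), 0L)
  # migrants carry their donor's haplotype, so truth still verifies and the
  # emitted FASTA shares haplotypes across demes
  expect_gt(length(ds1$truth$migrants), 0L)
})

test_that("composition allocation is exact without migration", {
  sp <- simSpec(data.frame(name = "Z", region = "r", n = 10),
                list(Z = c(D1b = 0.4, A = 0.6)), thetaWithin = 2,
                seed = 24)
  ds <- generateDataset(sp, tree, ref)
  cls <- classifyHaplogroups(callSubstitutions(ds$aln), tree,
                             sampleIds = ds$popmap$sample_id)
  expect_identical(sum(cls$haplogroup == "D1b"), 4L)
  expect_identical(sum(cls$haplogroup == "A"), 6L)
})

test_that("a targeted diagnostic back-mutation is detected as fallback", {
  sp <- simSpec(data.frame(name = "Z", region = "r", n = 6),
                list(Z = c(D1b = 1)), thetaWithin = 1, seed = 25)
  ds <- generateDataset(sp, tree, ref)
  st <- states(ds$aln)
  # revert T306C (a D1 diagnostic) in one sample back to the reference base
  st[3, 306] <- "T"
  aln2 <- matriline:::alignmentFromStates(st, ds$popmap, ref)
  cls <- classifyHaplogroups(callSubstitutions(aln2), tree,
                             sampleIds = ds$popmap$sample_id)
  hit <- cls$haplogroup != "D1b"
  expect_identical(cls$sample_id[hit], ds$popmap$sample_id[3])
  expect_identical(cls$haplogroup[hit], "D")
  expect_match(cls$missing[hit], "T306C")
})

test_that("shuffling the popmap destroys the deme signal", {
  demes <- data.frame(name = c("X", "Y"), region = c("r", "r"),
                      n = c(20, 20))
  comp <- list(X = c(V = 1), Y = c(D2 = 1))
  sp <- simSpec(demes, comp, thetaWithin = 3, seed = 26)
  ds <- generateDataset(sp, tree, ref)
  meta <- ds$popmap
  set.seed(27)
  meta$population <- sample(meta$population)
  alnShuf <- matriline:::alignmentFromStates(states(ds$aln), meta, ref)
  fstTrue <- pairwiseFst(ds$aln, nPerm = 100, seed = 2)
  fstShuf <- pairwiseFst(alnShuf, nPerm = 100, seed = 2)
  expect_gt(fstTrue$fst["X", "Y"], 0.5)
  expect_lt(abs(fstShuf$fst["X", "Y"]), 0.1)
  expect_gt(fstShuf$p["X", "Y"], 0.05)
})

test_that("mean pairwise differences track the requested theta", {
  # E[mean pairwise differences] = theta under the neutral coalescent
  reps <- 120
  khat <- numeric(reps)
  for (i in seq_len(reps)) {
    sp <- simSpec(data.frame(name = "Z", region = "r", n = 12),
                  list(Z = c(A = 1)), thetaWithin = 2.5, seed = 3000 + i)
    ds <- generateDataset(sp, tree, ref)
    khat[i] <- nucleotideDiversity(ds$aln)$meanPairwiseDiff
  }
  se <- sd(khat) / sqrt(reps)
  expect_lt(abs(mean(khat) - 2.5), 3 * se)
})

test_that("position exhaustion raises a clear error", {
  tinyTree <- motifTree(data.frame(name = c("R", "Q"),
                                   parent = c(NA, "R"),
                                   motifs = I(list(character(0), "A1G"))))
  tinyRef <- makeSyntheticReference("A1G", length = 8, seed = 5)
  sp <- simSpec(data.frame(name = "Z", region = "r", n = 30),
                list(Z = c(Q = 1)), thetaWithin = 50, seed = 28)
  expect_error(generateDataset(sp, tinyTree, tinyRef), "exhausted")
})

test_that("written outputs re-score identically through file round trip", {
  dir <- file.path(tempdir(), "simout")
  sp <- simSpec(data.frame(name = c("X", "Y"), region = c("M", "I"),
                           n = c(8, 8)),
                list(X = c(V2 = 1), Y = c(D1b = 1)), thetaWithin = 2,
                seed = 29)
  ds <- generateDataset(sp, tree, ref, dir = dir)
  expect_true(file.exists(file.path(dir, "sequences.fasta")))
  rec <- readControlRegion(file.path(dir, "sequences.fasta"),
                           file.path(dir, "popmap.tsv"))
  aln <- anchorSequences(rec, ref)
  expect_identical(states(aln), states(ds$aln))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(unlist(truth$haplogroup[1:3]),
                   ds$truth$haplogroup[1:3])
})
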
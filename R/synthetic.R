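# Haplogroup-structured synthetic control-region datasets with full ground
# truth, so that every pipeline stage is testable without any download.

#' Generate a synthetic reference frame
#'
#' Builds a deterministic random reference sequence whose bases at the given
#' motif positions equal the ancestral states those motifs require, so that
#' the motif tree and the reference are mutually consistent. The package's
#' bundled `synthetic_reference.fasta` was produced by this function (seed
#' 20260101) for the bundled haplogroup scheme; it is a synthetic stand-in,
#' not the real chicken sequence.
#'
#' @param tokens motif tokens whose ancestral bases must be honoured.
#' @param length frame length (default 1232).
#' @param seed RNG seed.
#' @param id reference id.
#' @return a [ReferenceFrame-class].
#' @export
makeSyntheticReference <- function(tokens, length = 1232L, seed = 20260101L,
                                   id = "synthetic-D-loop-1232") {
  mv <- parseMotifs(tokens)
  if (any(mv$position > length))
    stop("motif position beyond frame length")
  dup <- tapply(mv$ancestral, mv$position, function(a) length(unique(a)))
  if (any(dup > 1L))
    stop("conflicting ancestral bases among motifs at position(s): ",
         paste(names(dup)[dup > 1L], collapse = ", "))
  withSeed(seed, {
    b <- sample(BASES, length, replace = TRUE)
    b[mv$position] <- mv$ancestral
    new("ReferenceFrame", refId = id, bases = b)
  })
}

#' Founder sequences for every haplogroup node
#'
#' The founder of a node is the reference with the node's cumulative
#' root-to-node motif path applied; conflicting motifs along one path raise
#' an error.
#'
#' @param tree a [MotifTree-class].
#' @param ref a [ReferenceFrame-class].
#' @return named character vector node -> full-length sequence string.
#' @export
makeFounders <- function(tree, ref) {
  vapply(treeNodes(tree)$name, function(nd)
    applyVariants(motifPath(tree, nd), ref), "")
}

#' Specify a synthetic multi-deme dataset
#'
#' @param demes data.frame with columns `name`, `region`, `n` (sample
#'   sizes >= 1).
#' @param composition named list (one entry per deme) of named numeric
#'   vectors: haplogroup node -> proportion (each summing to 1). Counts are
#'   allocated deterministically by largest remainder, so generated
#'   haplogroup frequencies match the requested proportions exactly up to
#'   integer rounding.
#' @param thetaWithin per-deme scaled mutation parameter for within-
#'   haplogroup coalescent diversity (>= 0).
#' @param divergenceExtra extra private substitutions fixed in every
#'   sequence of each deme (integer >= 0), creating between-deme divergence.
#' @param migrationShare probability that a sampled sequence is replaced by
#'   a copy from another deme (haplotype sharing), in [0, 1).
#' @param seed mandatory integer seed.
#' @return list of class `SimSpec`.
#' @export
simSpec <- function(demes, composition, thetaWithin = 5, divergenceExtra = 0,
                    migrationShare = 0, seed) {
  stopifnot(all(c("name", "region", "n") %in% colnames(demes)),
            all(demes$n >= 1), thetaWithin >= 0, divergenceExtra >= 0,
            migrationShare >= 0, migrationShare < 1)
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (!setequal(names(composition), demes$name))
    stop("composition must name every deme exactly once")
  for (nm in names(composition)) {
    pr <- composition[[nm]]
    if (abs(sum(pr) - 1) > 1e-8)
      stop("composition proportions for deme ", nm, " must sum to 1")
  }
  structure(list(demes = demes, composition = composition,
                 thetaWithin = thetaWithin,
                 divergenceExtra = divergenceExtra,
                 migrationShare = migrationShare, seed = as.integer(seed)),
            class = "SimSpec")
}

# Deterministic integer allocation of n among proportions (largest
# remainder), preserving the requested frequencies exactly.
.allocate <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(prop))
}

#' Generate a synthetic haplogroup-structured dataset
#'
#' Per deme, samples receive founder haplotypes according to the requested
#' haplogroup composition; within each (deme, haplogroup) cohort a neutral
#' infinite-sites coalescent sample overlays private substitutions at
#' positions disjoint from every diagnostic motif position (so classifier
#' ground truth stays exact); each deme optionally gains fixed private
#' substitutions (divergence), and sequences are optionally replaced by
#' copies from other demes (haplotype sharing / migration). All randomness
#' derives from `spec$seed`.
#'
#' @param spec a `SimSpec` from [simSpec()].
#' @param tree a [MotifTree-class].
#' @param ref a [ReferenceFrame-class].
#' @param dir optional output directory; when given, writes
#'   `sequences.fasta`, `popmap.tsv`, and `truth.json`.
#' @param allowDiagnosticNoise opt-in stress mode: coalescent mutations may
#'   also hit diagnostic positions (classification truth then no longer
#'   guaranteed).
#' @return list with `aln` (a [DloopAlignment-class]), `sequences` (named
#'   character vector), `popmap` (data.frame), and `truth` (list:
#'   `haplogroup`, `founder`, `partition` per sample; `positionsUsed`;
#'   `migrants`; `seed`).
#' @export
generateDataset <- function(spec, tree, ref, dir = NULL,
                            allowDiagnosticNoise = FALSE) {
  stopifnot(inherits(spec, "SimSpec"), is(tree, "MotifTree"),
            is(ref, "ReferenceFrame"))
  L <- refLength(ref)
  founders <- makeFounders(tree, ref)
  diagPos <- parseMotifs(unique(unlist(tree@nodes$motifs)))$position
  pool0 <- if (allowDiagnosticNoise) seq_len(L)
           else setdiff(seq_len(L), diagPos)
  withSeed(spec$seed, {
    pool <- sample(pool0)                 # global pool, drawn without replacement
    takePos <- function(k) {
      if (k > length(pool))
        stop("requested positions exhausted: theta/divergence too large ",
             "for the available non-diagnostic sites")
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    transit <- c(A = "G", G = "A", C = "T", T = "C")
    seqsMat <- NULL
    meta <- NULL
    trueHg <- character()
    trueFounder <- character()
    sampleCounter <- 0L
    for (di in seq_len(nrow(spec$demes))) {
      deme <- spec$demes$name[di]
      nD <- spec$demes$n[di]
      alloc <- .allocate(nD, spec$composition[[deme]])
      demeRows <- NULL
      demeHg <- character()
      for (hg in names(alloc)) {
        m <- alloc[[hg]]
        if (m == 0L) next
        base <- strsplit(founders[[hg]], "")[[1L]]
        block <- matrix(rep(base, m), nrow = m, byrow = TRUE)
        if (m >= 2L && spec$thetaWithin > 0) {
          cs <- simulateNeutralSample(m, spec$thetaWithin)
          if (cs$S > 0) {
            posS <- takePos(cs$S)
            for (s in seq_len(cs$S)) {
              carriers <- which(cs$genotypes[, s] == 1L)
              block[carriers, posS[s]] <-
                transit[[block[carriers[1L], posS[s]]]]
            }
          }
        }
        demeRows <- rbind(demeRows, block)
        demeHg <- c(demeHg, rep(hg, m))
      }
      if (spec$divergenceExtra > 0) {
        posD <- takePos(spec$divergenceExtra)
        for (p in posD) demeRows[, p] <- transit[[demeRows[1L, p]]]
      }
      ids <- sprintf("%s_%03d", deme, seq_len(nD))
      rownames(demeRows) <- ids
      seqsMat <- rbind(seqsMat, demeRows)
      meta <- rbind(meta, data.frame(sample_id = ids, population = deme,
                                     region = spec$demes$region[di],
                                     stringsAsFactors = FALSE))
      trueHg <- c(trueHg, demeHg)
      trueFounder <- c(trueFounder, demeHg)
      sampleCounter <- sampleCounter + nD
    }
    names(trueHg) <- names(trueFounder) <- meta$sample_id
    migrants <- character()
    if (spec$migrationShare > 0 && nrow(spec$demes) > 1L) {
      isMig <- runif(nrow(meta)) < spec$migrationShare
      for (i in which(isMig)) {
        donors <- which(meta$population != meta$population[i])
        j <- donors[sample.int(length(donors), 1L)]
        seqsMat[i, ] <- seqsMat[j, ]
        trueHg[i] <- trueHg[j]
        trueFounder[i] <- trueFounder[j]
        migrants <- c(migrants, meta$sample_id[i])
      }
    }
    seqs <- apply(seqsMat, 1L, paste, collapse = "")
    partition <- setNames(match(seqs, unique(seqs)), meta$sample_id)
    aln <- alignmentFromStates(seqsMat, meta, ref)
    truth <- list(haplogroup = trueHg, founder = trueFounder,
                  partition = partition,
                  positionsUsed = setdiff(pool0, c(pool)),
                  migrants = migrants, seed = spec$seed)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      writeLines(paste0(">", meta$sample_id, "\n", seqs),
                 file.path(dir, "sequences.fasta"))
      write.table(meta, file.path(dir, "popmap.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(haplogroup = as.list(trueHg), founder = as.list(trueFounder),
             partition = as.list(partition), migrants = migrants,
             seed = spec$seed),
        file.path(dir, "truth.json"), auto_unbox = TRUE)
    }
    list(aln = aln, sequences = seqs, popmap = meta, truth = truth)
  })
}

# Plain Rand index between two partitions given as label vectors.
randIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  A <- sum(ch2(tab))
  B <- sum(ch2(rowSums(tab))) - A
  C <- sum(ch2(colSums(tab))) - A
  D <- ch2(n) - A - B - C
  (A + D) / ch2(n)
}

#' Verify pipeline outputs against generator ground truth
#'
#' Re-scores the generated sequences through variant calling, the motif
#' classifier and haplotype collapsing, and compares against the truth
#' table: classifier accuracy, Rand index of the haplotype partition, and a
#' listing of any misclassified samples.
#'
#' @param dataset output of [generateDataset()].
#' @param tree the [MotifTree-class] used for generation.
#' @return list `classifierAccuracy`, `randIndex`, `misclassified`
#'   (data.frame `sample_id`, `truth`, `assigned`), `nSamples`.
#' @export
verifyTruth <- function(dataset, tree) {
  aln <- dataset$aln
  variants <- callSubstitutions(aln)
  cls <- classifyHaplogroups(variants, tree,
                             sampleIds = sampleData(aln)$sample_id)
  truthHg <- dataset$truth$haplogroup[cls$sample_id]
  ok <- cls$haplogroup == truthHg
  part <- collapseHaplotypes(aln)
  ri <- randIndex(membership(part)[names(dataset$truth$partition)],
                  dataset$truth$partition)
  list(classifierAccuracy = mean(ok), randIndex = ri,
       misclassified = data.frame(sample_id = cls$sample_id[!ok],
                                  truth = truthHg[!ok],
                                  assigned = cls$haplogroup[!ok],
                                  stringsAsFactors = FALSE),
       nSamples = length(ok))
}
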
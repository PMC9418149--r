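# End-to-end orchestration: score -> classify -> diversity -> neutrality ->
# structure -> network, with a reproducibility manifest.

#' Run the full matrilineal phylogeography pipeline
#'
#' Executes the enabled stages in dependency order on a FASTA + popmap input
#' and writes tab-separated outputs plus a JSON manifest recording package
#' version, seeds, parameters, and MD5 checksums of every input and output,
#' so that identical inputs and seeds reproduce byte-identical results.
#'
#' @param fasta path to the input FASTA.
#' @param popmap path to the popmap TSV (`sample_id`, `population`,
#'   `region`).
#' @param outDir output directory (created if missing).
#' @param reference path to a reference FASTA, or `NULL` for the bundled
#'   synthetic frame.
#' @param motifs path to a motif-tree YAML/JSON, or `NULL` for the bundled
#'   scheme.
#' @param by population column used throughout (`"population"` or
#'   `"region"`).
#' @param pooled optional named list of group levels to pool into extra
#'   diversity/neutrality rows (pooling sequences, not averaging indices).
#' @param layout optional AMOVA layout (named list group -> populations).
#' @param stages character vector of stages to run, a subset of
#'   `c("score", "classify", "diversity", "neutrality", "structure",
#'   "network")`. Later stages pull in what they need from earlier ones
#'   regardless of toggles, but only enabled stages write outputs.
#' @param neutralityReps,fstPerm,amovaPerm replicate/permutation counts.
#' @param epsilon median-joining relaxation parameter.
#' @param seed master seed; per-stage seeds are derived from it and recorded
#'   in the manifest.
#' @return invisibly, the manifest (also written to `manifest.json`).
#' @export
runPipeline <- function(fasta, popmap, outDir, reference = NULL,
                        motifs = NULL, by = "population", pooled = NULL,
                        layout = NULL,
                        stages = c("score", "classify", "diversity",
                                   "neutrality", "structure", "network"),
                        neutralityReps = 1000L, fstPerm = 1000L,
                        amovaPerm = 1000L, epsilon = 0, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  ref <- if (is.null(reference)) defaultReference()
         else readReference(reference)
  tree <- if (is.null(motifs)) cdvMotifTree()
          else loadMotifTree(motifs, frameLength = refLength(ref))
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
  }
  num <- function(x, digits = 5) formatC(x, digits = digits, format = "f")

  records <- readControlRegion(fasta, popmap)
  aln <- anchorSequences(records, ref)
  ids <- sampleData(aln)$sample_id
  variants <- callSubstitutions(aln)

  if ("score" %in% stages) {
    toks <- variantTokens(variants, ids)
    emit(data.frame(sample_id = ids,
                    motifs = vapply(toks, paste, "", collapse = ","),
                    stringsAsFactors = FALSE), "variants.tsv")
  }
  if ("classify" %in% stages) {
    cls <- classifyHaplogroups(variants, tree, sampleIds = ids)
    emit(cls, "haplogroups.tsv")
    fr <- haplogroupFrequencies(cls, sampleData(aln), by = by)
    freq <- data.frame(group = rownames(fr$counts), fr$counts,
                       check.names = FALSE)
    emit(freq, "haplogroup_counts.tsv")
  }
  if ("diversity" %in% stages) {
    dt <- diversityTable(aln, by = by, pooled = pooled)
    out <- transform(dt, Hd = num(Hd, 3), Hd_se = num(Hd_se, 3),
                     pi = num(pi, 5), pi_se = num(pi_se, 5))
    emit(out, "diversity.tsv")
    emit(dt, "diversity_full.tsv")
  }
  if ("neutrality" %in% stages) {
    nt <- neutralityTest(aln, by = by, pooled = pooled,
                         nReps = neutralityReps, seed = childSeed(seed, 1L))
    emit(nt, "neutrality.tsv")
  }
  if ("structure" %in% stages) {
    fst <- pairwiseFst(aln, by = by, nPerm = fstPerm,
                       seed = childSeed(seed, 2L))
    m <- fst$fst
    m[upper.tri(m)] <- fst$p[upper.tri(fst$p)]
    emit(data.frame(population = rownames(m), m, check.names = FALSE),
         "fst.tsv")
    am <- amova(aln, layout = layout, by = by, nPerm = amovaPerm,
                seed = childSeed(seed, 3L))
    rep_ <- am$components
    rep_$phi <- c(names(am$phi), rep("", nrow(rep_) - length(am$phi)))
    rep_$phi_value <- c(unname(am$phi),
                        rep(NA_real_, nrow(rep_) - length(am$phi)))
    rep_$p <- c(unname(am$p), rep(NA_real_, nrow(rep_) - length(am$p)))
    emit(rep_, "amova.tsv")
    if (nrow(fst$fst) >= 3L) {
      pc <- pcoaFromFst(fst)
      emit(data.frame(population = rownames(pc$coordinates),
                      pc$coordinates,
                      check.names = FALSE), "pcoa_coordinates.tsv")
      emit(data.frame(axis = seq_along(pc$eigenvalues),
                      eigenvalue = pc$eigenvalues,
                      percent = pc$percent), "pcoa_axes.tsv")
    }
  }
  if ("network" %in% stages) {
    part <- collapseHaplotypes(aln)
    if (nHaplotypes(part) >= 2L) {
      net <- medianJoiningNetwork(part, epsilon = epsilon)
      writeNetworkEdges(net, file.path(outDir, "network_edges.tsv"))
      writeNetworkGraphml(net, file.path(outDir, "network.graphml"))
      writeNetworkNexus(net, file.path(outDir, "network.nex"))
      outputs <- c(outputs, file.path(outDir, c("network_edges.tsv",
                                                "network.graphml",
                                                "network.nex")))
    }
  }

  manifest <- list(
    package = "matriline",
    version = as.character(packageVersion("matriline")),
    stages = stages,
    seed = seed,
    stageSeeds = list(neutrality = childSeed(seed, 1L),
                      fst = childSeed(seed, 2L), amova = childSeed(seed, 3L)),
    parameters = list(by = by, neutralityReps = neutralityReps,
                      fstPerm = fstPerm, amovaPerm = amovaPerm,
                      epsilon = epsilon),
    inputChecksums = as.list(tools::md5sum(c(fasta, popmap))),
    outputChecksums = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
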
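# Sequence input and anchoring to the reference coordinate frame.

#' Construct or read a reference frame
#'
#' `readReference()` reads the first record of a FASTA file;
#' `referenceFrame()` wraps a character string. `defaultReference()` returns
#' the frame bundled with the package: a 1232-bp synthetic stand-in for the
#' chicken control region (see [makeSyntheticReference()]) whose bases at all
#' diagnostic-motif positions of the bundled haplogroup scheme match the
#' ancestral states those motifs require. Users reproducing published results
#' should supply the real control-region reference via `readReference()`.
#'
#' @param path FASTA file (plain or gzip).
#' @param id reference identifier; defaults to the FASTA record name.
#' @return a [ReferenceFrame-class] object.
#' @export
readReference <- function(path, id = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no sequence in ", path)
  nm <- sub("\\s.*$", "", names(ss)[1L])
  referenceFrame(as.character(ss[[1L]]), id = if (is.null(id)) nm else id)
}

#' @rdname readReference
#' @param seq nucleotide string (A/C/G/T only).
#' @export
referenceFrame <- function(seq, id = "reference") {
  new("ReferenceFrame", refId = id,
      bases = strsplit(toupper(seq), "")[[1L]])
}

#' @rdname readReference
#' @export
defaultReference <- function() {
  readReference(system.file("extdata", "synthetic_reference.fasta",
                            package = "matriline"),
                id = "synthetic-D-loop-1232")
}

#' Read control-region sequences with population metadata
#'
#' Reads a FASTA file and joins each record to a population map, a TSV with
#' header `sample_id<TAB>population<TAB>region`. Every FASTA id must appear
#' in the popmap; popmap rows without a matching FASTA record are ignored
#' with a warning. Record order follows the FASTA.
#'
#' @param fasta path to FASTA (plain or gzip).
#' @param popmap path to the population map TSV.
#' @return list with elements `seqs` ([Biostrings::DNAStringSet]) and `meta`
#'   (data.frame `sample_id`, `population`, `region`).
#' @export
readControlRegion <- function(fasta, popmap) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  pm <- read.delim(popmap, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "region")
  if (!all(need %in% colnames(pm)))
    stop("popmap must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(pm$sample_id))
    stop("duplicate sample ids in popmap")
  orphan <- setdiff(names(seqs), pm$sample_id)
  if (length(orphan))
    stop("FASTA id(s) missing from popmap: ", paste(orphan, collapse = ", "))
  extra <- setdiff(pm$sample_id, names(seqs))
  if (length(extra))
    warning(length(extra), " popmap row(s) without a FASTA record ignored: ",
            paste(head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ...")
  meta <- pm[match(names(seqs), pm$sample_id), need, drop = FALSE]
  rownames(meta) <- NULL
  if (any(!nzchar(meta$population)))
    stop("empty population label in popmap")
  list(seqs = seqs, meta = meta)
}

# Alignment scoring, fixed for reproducibility: match +1, mismatch -1, first
# gap position -4, each further gap position -1 (affine).
.alnSubMat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Anchor one sequence to the reference frame
#'
#' Globally aligns a raw sequence to the reference (Needleman-Wunsch, affine
#' gaps) and emits one state per reference position: the aligned base, `-`
#' for a deletion relative to the reference, or `N` for missing/ambiguous
#' bases. IUPAC ambiguity codes are treated as missing so that they can never
#' match a diagnostic motif. Insertions relative to the reference are
#' returned separately and take no part in downstream statistics.
#'
#' @param seq nucleotide string (IUPAC allowed).
#' @param ref a [ReferenceFrame-class].
#' @param minIdentity minimum fraction of called bases identical to the
#'   reference (default 0.7); below it the sequence is rejected.
#' @return list with `states` (character vector along the reference),
#'   `insertions` (data.frame `after`, `seq`), `nGaps`, `nMissing`.
#' @export
anchorToReference <- function(seq, ref, minIdentity = 0.7) {
  stopifnot(is(ref, "ReferenceFrame"))
  L <- refLength(ref)
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) < 0.8 * L || nchar(seq) > 1.2 * L)
    stop("sequence length ", nchar(seq), " outside [0.8, 1.2] x reference (",
         L, " bp)")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seq),
    subject = Biostrings::DNAString(paste(refBases(ref), collapse = "")),
    type = "global", substitutionMatrix = .alnSubMat(),
    gapOpening = 3, gapExtension = 1)
  patChars <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  subChars <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  states <- character(L)
  ins <- list()
  pos <- 0L
  i <- 1L
  while (i <= length(subChars)) {
    if (subChars[i] == "-") {
      j <- i
      while (j <= length(subChars) && subChars[j] == "-") j <- j + 1L
      ins[[length(ins) + 1L]] <-
        data.frame(after = pos,
                   seq = paste(patChars[i:(j - 1L)], collapse = ""),
                   stringsAsFactors = FALSE)
      i <- j
    } else {
      pos <- pos + 1L
      p <- patChars[i]
      states[pos] <- if (p == "-") "-" else if (p %in% BASES) p else "N"
      i <- i + 1L
    }
  }
  called <- states %in% BASES
  if (!any(called))
    stop("sequence does not resemble the reference control region")
  identity <- mean(states[called] == refBases(ref)[called])
  if (identity < minIdentity)
    stop("sequence does not resemble the chicken control region (identity ",
         sprintf("%.2f", identity), " < ", minIdentity, ")")
  list(states = states,
       insertions = if (length(ins)) do.call(rbind, ins)
                    else data.frame(after = integer(), seq = character()),
       nGaps = sum(states == "-"), nMissing = sum(states == "N"))
}

#' Anchor a set of records into a DloopAlignment
#'
#' @param records output of [readControlRegion()] (or a list with `seqs` and
#'   `meta` of the same shape).
#' @param ref a [ReferenceFrame-class]; default [defaultReference()].
#' @param minIdentity passed to [anchorToReference()].
#' @return a [DloopAlignment-class].
#' @export
anchorSequences <- function(records, ref = defaultReference(),
                            minIdentity = 0.7) {
  n <- length(records$seqs)
  if (n == 0L) stop("no sequences to anchor")
  stmat <- matrix("N", nrow = n, ncol = refLength(ref),
                  dimnames = list(records$meta$sample_id, NULL))
  ins <- vector("list", n)
  names(ins) <- records$meta$sample_id
  for (i in seq_len(n)) {
    a <- anchorToReference(as.character(records$seqs[[i]]), ref, minIdentity)
    stmat[i, ] <- a$states
    ins[[i]] <- a$insertions
  }
  new("DloopAlignment", states = stmat, sampleData = records$meta,
      reference = ref, insertions = ins)
}

# Build a DloopAlignment directly from a state matrix (used by the synthetic
# generator and by tests; skips the aligner).
alignmentFromStates <- function(stmat, meta, ref) {
  rownames(stmat) <- meta$sample_id
  new("DloopAlignment", states = stmat, sampleData = meta, reference = ref,
      insertions = setNames(
        rep(list(data.frame(after = integer(), seq = character())),
            nrow(stmat)), meta$sample_id))
}

#' Score substitutions relative to the reference
#'
#' One substitution is called at every position whose state is a called base
#' (`A/C/G/T`) differing from the reference; gaps and missing states produce
#' no call. Tokens render as `"<anc><pos><der>"`, e.g. `"A281G"`.
#'
#' @param aln a [DloopAlignment-class].
#' @return data.frame `sample_id`, `position`, `ancestral`, `derived`,
#'   `token`, sorted by sample then ascending position. Samples with no
#'   substitutions contribute no rows.
#' @export
callSubstitutions <- function(aln) {
  stopifnot(is(aln, "DloopAlignment"))
  rb <- refBases(reference(aln))
  st <- states(aln)
  out <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    hit <- which(st[i, ] %in% BASES & st[i, ] != rb)
    out[[i]] <- data.frame(
      sample_id = rep(rownames(st)[i], length(hit)),
      position = hit, ancestral = rb[hit], derived = st[i, hit],
      token = formatMotifs(rb[hit], hit, st[i, hit]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname callSubstitutions
#' @param variants the data.frame returned by `callSubstitutions()`.
#' @param sampleIds which samples to report (default: all in `variants`);
#'   samples without calls get an empty token vector.
#' @return `variantTokens()`: named list, sample id -> character vector of
#'   tokens (ascending position).
#' @export
variantTokens <- function(variants, sampleIds = NULL) {
  if (is.null(sampleIds)) sampleIds <- unique(variants$sample_id)
  sp <- split(variants$token, factor(variants$sample_id, levels = sampleIds))
  lapply(sp, as.character)
}

#' Apply substitution tokens to a reference
#'
#' Rebuilds the sequence string carrying exactly the given substitutions,
#' checking each token's ancestral base against the reference.
#'
#' @param tokens character vector of motif tokens.
#' @inheritParams anchorToReference
#' @return nucleotide string of `refLength(ref)` bases.
#' @export
applyVariants <- function(tokens, ref) {
  b <- refBases(ref)
  if (length(tokens)) {
    mv <- parseMotifs(tokens)
    if (any(mv$position > length(b)))
      stop("motif position beyond reference frame: ",
           paste(mv$token[mv$position > length(b)], collapse = ", "))
    bad <- b[mv$position] != mv$ancestral
    if (any(bad))
      stop("ancestral base mismatch with reference: ",
           paste(mv$token[bad], collapse = ", "))
    if (anyDuplicated(mv$position))
      stop("conflicting motifs at one position")
    b[mv$position] <- mv$derived
  }
  paste(b, collapse = "")
}

#' Write a variants table
#'
#' @param variants data.frame from [callSubstitutions()].
#' @param sampleIds all sample ids (so that invariant samples appear with an
#'   empty motif string).
#' @param path output TSV path (`sample_id`, comma-joined tokens).
#' @export
writeVariantsTsv <- function(variants, sampleIds, path) {
  toks <- variantTokens(variants, sampleIds)
  df <- data.frame(sample_id = sampleIds,
                   motifs = vapply(toks, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
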
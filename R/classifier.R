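# Diagnostic-motif haplogroup classification.

.buildPaths <- function(nodes, root) {
  paths <- setNames(vector("list", nrow(nodes)), nodes$name)
  paths[[root]] <- nodes$motifs[[match(root, nodes$name)]]
  done <- root
  repeat {
    todo <- which(!(nodes$name %in% done) & nodes$parent %in% done)
    if (!length(todo)) break
    for (i in todo) {
      paths[[nodes$name[i]]] <-
        union(paths[[nodes$parent[i]]], nodes$motifs[[i]])
    }
    done <- c(done, nodes$name[todo])
  }
  paths
}

#' Build a motif tree from a node table
#'
#' @param nodes data.frame with columns `name`, `parent` (`NA`/`""` for the
#'   root) and either a list column `motifs` or a character column of
#'   space/comma-separated tokens; an optional `source` column documents the
#'   provenance of each node's motifs.
#' @param frameLength if given, motif positions beyond it raise an error at
#'   load (guards frame-shifted nomenclatures).
#' @return a [MotifTree-class].
#' @export
motifTree <- function(nodes, frameLength = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("name", "parent") %in% colnames(nodes)))
    stop("node table needs 'name' and 'parent' columns")
  if (!"motifs" %in% colnames(nodes)) nodes$motifs <- list(character())
  if (!is.list(nodes$motifs))
    nodes$motifs <- lapply(nodes$motifs, function(s) {
      s <- trimws(strsplit(s, "[,;[:space:]]+")[[1L]])
      s[nzchar(s)]
    })
  nodes$motifs <- lapply(nodes$motifs, function(m) as.character(m))
  if (!"source" %in% colnames(nodes)) nodes$source <- NA_character_
  nodes$parent[!is.na(nodes$parent) & !nzchar(nodes$parent)] <- NA_character_
  isRoot <- is.na(nodes$parent)
  if (sum(isRoot) != 1L) stop("exactly one root (parent-less) node required")
  for (i in seq_len(nrow(nodes))) {
    mv <- parseMotifs(nodes$motifs[[i]])   # validates token syntax
    if (!is.null(frameLength) && any(mv$position > frameLength))
      stop("node ", nodes$name[i], ": motif position beyond the ",
           frameLength, "-bp frame: ",
           paste(mv$token[mv$position > frameLength], collapse = ", "))
  }
  root <- nodes$name[isRoot]
  tr <- new("MotifTree", nodes = nodes[, c("name", "parent", "motifs",
                                           "source")],
            root = root, paths = list())
  tr@paths <- .buildPaths(tr@nodes, root)
  validObject(tr)
  tr
}

#' Load a motif tree from a YAML/JSON config
#'
#' The config is a list of nodes, each with fields `name`, `parent` (omit or
#' empty for the root), `motifs` (list of tokens) and optionally `source`.
#' Malformed tokens, duplicate nodes and unknown parents raise an error
#' naming the offending node.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @inheritParams motifTree
#' @return a [MotifTree-class].
#' @export
loadMotifTree <- function(path, frameLength = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (!is.null(raw$nodes)) raw <- raw$nodes
  nodes <- data.frame(
    name = vapply(raw, function(x) as.character(x$name), ""),
    parent = vapply(raw, function(x)
      if (is.null(x$parent)) NA_character_ else as.character(x$parent), ""),
    source = vapply(raw, function(x)
      if (is.null(x$source)) NA_character_ else as.character(x$source), ""),
    stringsAsFactors = FALSE)
  nodes$motifs <- lapply(raw, function(x)
    as.character(unlist(x$motifs, use.names = FALSE)))
  motifTree(nodes, frameLength = frameLength)
}

#' The bundled macrohaplogroup CDV classification scheme
#'
#' Loads the haplogroup scheme shipped with the package: the macrohaplogroup
#' CDV subtree (C, D, V and their sub-haplogroups) alongside the standard
#' major haplogroups A, B, E, F. Motif sets for V, V2 and D1b follow the
#' published nomenclature; nodes whose diagnostic motifs are not printed in
#' the main literature carry placeholder motifs and are marked
#' `source: synthetic-placeholder` in the config — replace the file with a
#' complete supplementary motif table for real-data work.
#'
#' @return a [MotifTree-class].
#' @export
cdvMotifTree <- function() {
  loadMotifTree(system.file("extdata", "cdv_motifs.yaml",
                            package = "matriline"),
                frameLength = 1232L)
}

#' Classify samples into haplogroups by diagnostic motifs
#'
#' Each sample is assigned to the deepest tree node whose cumulative
#' root-to-node motif set is fully contained in the sample's substitutions.
#' If two or more nodes of equal (maximal) depth are satisfied, the sample is
#' `"unclassified"` and the tied candidates are listed in `conflicts`.
#' `missing` lists, for each of the assigned node's children, the motifs that
#' blocked deeper assignment, making borderline samples auditable.
#'
#' @param variants data.frame from [callSubstitutions()], or a named list of
#'   token vectors as from [variantTokens()].
#' @param tree a [MotifTree-class].
#' @param sampleIds samples to classify (default: those in `variants`);
#'   samples without any substitution are classified to the root.
#' @return data.frame `sample_id`, `haplogroup`, `depth`, `matched_path`,
#'   `missing`, `conflicts` (token lists comma-joined).
#' @export
classifyHaplogroups <- function(variants, tree, sampleIds = NULL) {
  stopifnot(is(tree, "MotifTree"))
  toks <- if (is.data.frame(variants)) variantTokens(variants, sampleIds)
          else variants
  if (!is.null(sampleIds) && !is.data.frame(variants))
    toks <- toks[sampleIds]
  depth <- nodeDepths(tree)
  nodes <- tree@nodes$name
  children <- split(tree@nodes$name, tree@nodes$parent)
  res <- lapply(names(toks), function(sid) {
    vs <- toks[[sid]]
    sat <- nodes[vapply(nodes, function(nd)
      all(tree@paths[[nd]] %in% vs), TRUE)]
    # root has an empty cumulative path unless it carries motifs itself
    if (!length(sat)) {
      return(data.frame(sample_id = sid, haplogroup = "unclassified",
                        depth = NA_integer_, matched_path = "",
                        missing = "", conflicts = "",
                        stringsAsFactors = FALSE))
    }
    dmax <- max(depth[sat])
    deepest <- sat[depth[sat] == dmax]
    if (length(deepest) > 1L) {
      return(data.frame(sample_id = sid, haplogroup = "unclassified",
                        depth = dmax, matched_path = "",
                        missing = "",
                        conflicts = paste(sort(deepest), collapse = ","),
                        stringsAsFactors = FALSE))
    }
    hg <- deepest
    kids <- children[[hg]]
    miss <- character()
    if (!is.null(kids)) {
      for (kd in kids) {
        lacking <- setdiff(tree@paths[[kd]], vs)
        if (length(lacking)) miss <- union(miss, lacking)
      }
    }
    # substitutions at diagnostic positions of the assigned path that carry a
    # different derived state (e.g. back-mutations at deeper nodes)
    pathAll <- unique(unlist(tree@paths))
    pm <- parseMotifs(pathAll)
    vm <- if (length(vs)) parseMotifs(vs) else
      data.frame(position = integer(), token = character())
    confl <- vm$token[vm$position %in% pm$position & !(vm$token %in% pathAll)]
    data.frame(sample_id = sid, haplogroup = hg, depth = dmax,
               matched_path = paste(tree@paths[[hg]], collapse = ","),
               missing = paste(miss, collapse = ","),
               conflicts = paste(confl, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Haplogroup frequency table
#'
#' @param classification data.frame from [classifyHaplogroups()].
#' @param meta data.frame with `sample_id` and a grouping column.
#' @param by name of the grouping column in `meta` (default `"population"`).
#' @return list with `counts` (group x haplogroup integer matrix) and
#'   `percent` (rows summing to 100 up to rounding).
#' @export
haplogroupFrequencies <- function(classification, meta, by = "population") {
  m <- match(classification$sample_id, meta$sample_id)
  if (anyNA(m)) stop("classified sample(s) missing from metadata")
  grp <- meta[[by]][m]
  counts <- table(group = grp, haplogroup = classification$haplogroup)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  pct <- 100 * counts / rowSums(counts)
  list(counts = counts, percent = pct)
}
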
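#' @rdname ReferenceFrame-class
#' @export
setMethod("refId", "ReferenceFrame", function(x) x@refId)
#' @rdname ReferenceFrame-class
#' @export
setMethod("refBases", "ReferenceFrame", function(x) x@bases)
#' @rdname ReferenceFrame-class
#' @export
setMethod("refLength", "ReferenceFrame", function(x) length(x@bases))

setMethod("show", "ReferenceFrame", function(object) {
  cat("ReferenceFrame", object@refId, "|", length(object@bases), "bp\n")
  cat(" 5'-", paste(head(object@bases, 20), collapse = ""),
      if (length(object@bases) > 20) "..." else "", "\n", sep = "")
})

#' @rdname DloopAlignment-class
#' @export
setMethod("states", "DloopAlignment", function(x) x@states)
#' @rdname DloopAlignment-class
#' @export
setMethod("sampleData", "DloopAlignment", function(x) x@sampleData)
#' @rdname DloopAlignment-class
#' @export
setMethod("insertions", "DloopAlignment", function(x) x@insertions)
#' @rdname DloopAlignment-class
#' @export
setMethod("reference", "DloopAlignment", function(x) x@reference)

#' @rdname DloopAlignment-class
#' @export
setMethod("length", "DloopAlignment", function(x) nrow(x@states))

#' Subset a DloopAlignment by sample
#'
#' @param x a `DloopAlignment`
#' @param i sample indices, ids or logical vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "DloopAlignment", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleData$sample_id)
  new("DloopAlignment",
      states = x@states[i, , drop = FALSE],
      sampleData = x@sampleData[i, , drop = FALSE],
      reference = x@reference,
      insertions = x@insertions[x@sampleData$sample_id[i]])
})

setMethod("show", "DloopAlignment", function(object) {
  cat("DloopAlignment |", nrow(object@states), "samples x",
      ncol(object@states), "reference positions (", object@reference@refId,
      ")\n")
  cat(" populations:",
      paste(names(table(object@sampleData$population)), collapse = ", "), "\n")
  ng <- sum(object@states == "-"); nm <- sum(object@states == "N")
  cat(" gap states:", ng, "| missing/ambiguous states:", nm, "\n")
})

#' @rdname HaplotypePartition-class
#' @export
setMethod("membership", "HaplotypePartition", function(x) x@membership)
#' @rdname HaplotypePartition-class
#' @export
setMethod("hapStates", "HaplotypePartition", function(x) x@hapStates)
#' @rdname HaplotypePartition-class
#' @export
setMethod("includedSites", "HaplotypePartition", function(x) x@includedSites)
#' @rdname HaplotypePartition-class
#' @export
setMethod("nHaplotypes", "HaplotypePartition", function(x) nrow(x@hapStates))
#' @rdname HaplotypePartition-class
#' @export
setMethod("hapCounts", "HaplotypePartition", function(x) {
  tab <- table(factor(x@membership, levels = rownames(x@hapStates)))
  setNames(as.integer(tab), names(tab))
})

setMethod("show", "HaplotypePartition", function(object) {
  cat("HaplotypePartition |", length(object@membership), "samples ->",
      nrow(object@hapStates), "haplotypes over",
      length(object@includedSites), "included sites (site policy:",
      object@sitePolicy, ")\n")
})

#' @rdname MotifTree-class
#' @export
setMethod("treeNodes", "MotifTree", function(x) x@nodes)
#' @rdname MotifTree-class
#' @param node node name
#' @export
setMethod("motifPath", "MotifTree", function(x, node) {
  if (!node %in% names(x@paths)) stop("unknown haplogroup node: ", node)
  x@paths[[node]]
})
#' @rdname MotifTree-class
#' @export
setMethod("treeRoot", "MotifTree", function(x) x@root)
#' @rdname MotifTree-class
#' @export
setMethod("nodeDepths", "MotifTree", function(x) {
  depth <- setNames(rep(NA_integer_, nrow(x@nodes)), x@nodes$name)
  depth[x@root] <- 0L
  repeat {
    todo <- is.na(depth) & !is.na(depth[x@nodes$parent])
    if (!any(todo)) break
    depth[todo] <- depth[x@nodes$parent[todo]] + 1L
  }
  depth
})

setMethod("show", "MotifTree", function(object) {
  depth <- nodeDepths(object)
  cat("MotifTree |", nrow(object@nodes), "haplogroup nodes, root =",
      object@root, "\n")
  ord <- order(depth, object@nodes$name)
  for (i in head(ord, 20)) {
    nm <- object@nodes$name[i]
    cat(strrep("  ", depth[nm]), nm, ": ",
        paste(object@nodes$motifs[[i]], collapse = " "), "\n", sep = "")
  }
  if (nrow(object@nodes) > 20) cat("  ...\n")
})

#' @rdname MJNetwork-class
#' @export
setMethod("networkGraph", "MJNetwork", function(x) x@graph)
#' @rdname MJNetwork-class
#' @export
setMethod("nodeStates", "MJNetwork", function(x) x@nodeStates)
#' @rdname MJNetwork-class
#' @export
setMethod("networkEdges", "MJNetwork", function(x) {
  e <- igraph::as_data_frame(x@graph, what = "edges")
  data.frame(from = e$from, to = e$to, steps = e$weight,
             positions = e$positions, stringsAsFactors = FALSE)
})

setMethod("show", "MJNetwork", function(object) {
  v <- igraph::V(object@graph)
  cat("MJNetwork | ", sum(v$kind == "observed"), " observed haplotypes + ",
      sum(v$kind == "median"), " median vectors, ",
      igraph::ecount(object@graph), " edges (epsilon = ", object@epsilon,
      ")\n", sep = "")
  cat(" total network length:",
      sum(igraph::E(object@graph)$weight), "mutations\n")
})
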
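#' @import methods
#' @importFrom stats setNames rexp rpois runif pchisq cmdscale cor dist median quantile sd var
#' @importFrom utils read.delim write.table packageVersion head tail combn
NULL

#' ReferenceFrame: a fixed coordinate frame for the control region
#'
#' A reference sequence defining the 1-based coordinate frame against which
#' every sample is anchored and every substitution is scored. The shipped
#' control-region frame is 1232 bp; toy frames of any length are allowed so
#' that alignment and variant calling can be exercised on small examples.
#'
#' @slot refId single identifier, e.g. `"NC_040970"`.
#' @slot bases character vector of single upper-case bases (A/C/G/T), one per
#'   1-based position.
#' @exportClass ReferenceFrame
setClass("ReferenceFrame",
  representation(refId = "character", bases = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@refId) != 1L || !nzchar(object@refId))
      msg <- c(msg, "refId must be a single non-empty string")
    if (length(object@bases) < 1L)
      msg <- c(msg, "reference must contain at least one base")
    if (!all(object@bases %in% c("A", "C", "G", "T")))
      msg <- c(msg, "reference alphabet must be A/C/G/T")
    if (is.null(msg)) TRUE else msg
  }
)

#' DloopAlignment: sequences anchored to a reference frame
#'
#' Holds per-sample base calls at every reference position (columns), after
#' global pairwise alignment to the [ReferenceFrame]. States are
#' `A/C/G/T`, `-` (deletion relative to the reference) or `N` (missing /
#' ambiguous). Insertions relative to the reference are stored separately and
#' are excluded from the positional frame and from all downstream statistics.
#'
#' @slot states character matrix, samples x positions, rownames = sample ids.
#' @slot sampleData data.frame with columns `sample_id`, `population`,
#'   `region`, one row per sample, same order as `states`.
#' @slot reference the [ReferenceFrame] the states are expressed in.
#' @slot insertions named list (per sample) of data.frames with columns
#'   `after` (reference position preceding the insertion) and `seq`.
#' @exportClass DloopAlignment
setClass("DloopAlignment",
  representation(states = "matrix", sampleData = "data.frame",
                 reference = "ReferenceFrame", insertions = "list"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@states) != length(object@reference@bases))
      msg <- c(msg, "state matrix must have one column per reference position")
    if (nrow(object@states) != nrow(object@sampleData))
      msg <- c(msg, "sampleData rows must match state matrix rows")
    if (!all(c("sample_id", "population", "region") %in%
             colnames(object@sampleData)))
      msg <- c(msg, "sampleData needs sample_id, population, region columns")
    if (nrow(object@states) > 0 &&
        !identical(rownames(object@states), object@sampleData$sample_id))
      msg <- c(msg, "state rownames must equal sampleData$sample_id")
    if (anyDuplicated(object@sampleData$sample_id))
      msg <- c(msg, "duplicate sample ids")
    bad <- !(object@states %in% c("A", "C", "G", "T", "-", "N"))
    if (any(bad))
      msg <- c(msg, "states must be A/C/G/T/-/N")
    if (is.null(msg)) TRUE else msg
  }
)

#' MotifTree: hierarchical diagnostic-motif haplogroup nomenclature
#'
#' A rooted tree of haplogroup names. Each node carries the substitution
#' motifs diagnostic for its branch (beyond its parent); classification uses
#' the cumulative root-to-node union of motifs.
#'
#' @slot nodes data.frame with columns `name`, `parent` (`NA` for the root),
#'   `source`, and a list column `motifs` of character token vectors.
#' @slot root name of the root node.
#' @slot paths named list: cumulative motif tokens (root-to-node union).
#' @exportClass MotifTree
setClass("MotifTree",
  representation(nodes = "data.frame", root = "character", paths = "list"),
  validity = function(object) {
    msg <- NULL
    nd <- object@nodes
    if (anyDuplicated(nd$name)) msg <- c(msg, "duplicate node names")
    if (!(object@root %in% nd$name)) msg <- c(msg, "root not among nodes")
    nonroot <- nd$name != object@root
    if (any(is.na(nd$parent[nonroot])))
      msg <- c(msg, "only the root may lack a parent")
    if (!all(nd$parent[nonroot] %in% nd$name))
      msg <- c(msg, "unknown parent name")
    # reachability from the root implies acyclicity for a parent map
    reach <- object@root
    repeat {
      nxt <- nd$name[nd$parent %in% reach & !(nd$name %in% reach)]
      if (!length(nxt)) break
      reach <- c(reach, nxt)
    }
    if (!all(nd$name %in% reach))
      msg <- c(msg, "nodes unreachable from root (cycle or orphan)")
    if (is.null(msg)) TRUE else msg
  }
)

#' HaplotypePartition: identical sequences collapsed into haplotypes
#'
#' @slot membership named character vector: sample id -> haplotype id.
#' @slot hapStates character matrix, haplotypes x included sites, rownames =
#'   haplotype ids (assigned `Hap_1`, `Hap_2`, ... in first-occurrence order).
#' @slot includedSites integer vector of reference positions retained by the
#'   site policy (columns of `hapStates`).
#' @slot sampleData per-sample metadata carried over from the alignment.
#' @slot sitePolicy `"complete"` or `"pairwise"`.
#' @exportClass HaplotypePartition
setClass("HaplotypePartition",
  representation(membership = "character", hapStates = "matrix",
                 includedSites = "integer", sampleData = "data.frame",
                 sitePolicy = "character"),
  validity = function(object) {
    msg <- NULL
    if (!all(object@membership %in% rownames(object@hapStates)))
      msg <- c(msg, "membership refers to unknown haplotype ids")
    if (!all(rownames(object@hapStates) %in% object@membership))
      msg <- c(msg, "haplotype with no members")
    if (ncol(object@hapStates) != length(object@includedSites))
      msg <- c(msg, "hapStates columns must match includedSites")
    if (is.null(msg)) TRUE else msg
  }
)

#' MJNetwork: a median-joining haplotype network
#'
#' Observed haplotypes plus inferred median vectors, connected by edges
#' labelled with the reference positions that mutate along them.
#'
#' @slot graph an [igraph::igraph] with vertex attributes `name`, `kind`
#'   (`"observed"`/`"median"`), `size` (sample count; 0 for medians) and edge
#'   attributes `weight` (Hamming length) and `positions` (comma-joined
#'   mutated reference positions).
#' @slot nodeStates character matrix, nodes x variable sites (rownames match
#'   vertex names; colnames are reference positions).
#' @slot epsilon the relaxation parameter used.
#' @slot popCounts matrix of per-population sample counts per observed node
#'   (for pie-chart style exports), zero rows allowed.
#' @exportClass MJNetwork
setClass("MJNetwork",
  representation(graph = "ANY", nodeStates = "matrix", epsilon = "numeric",
                 popCounts = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (!igraph::is_igraph(object@graph)) msg <- c(msg, "graph must be igraph")
    else {
      if (!igraph::is_connected(object@graph))
        msg <- c(msg, "network must be connected")
      v <- igraph::V(object@graph)
      if (!setequal(v$name, rownames(object@nodeStates)))
        msg <- c(msg, "nodeStates rownames must match vertex names")
      med <- v$name[v$kind == "median"]
      if (length(med)) {
        deg <- igraph::degree(object@graph, med)
        if (any(deg <= 1)) msg <- c(msg, "obsolete median node of degree <= 1")
      }
    }
    if (is.null(msg)) TRUE else msg
  }
)
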
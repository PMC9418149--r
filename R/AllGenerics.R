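#' @rdname ReferenceFrame-class
#' @param x,object a `ReferenceFrame`
#' @export
setGeneric("refId", function(x) standardGeneric("refId"))
#' @rdname ReferenceFrame-class
#' @export
setGeneric("refBases", function(x) standardGeneric("refBases"))
#' @rdname ReferenceFrame-class
#' @export
setGeneric("refLength", function(x) standardGeneric("refLength"))

#' @rdname DloopAlignment-class
#' @param x,object a `DloopAlignment`
#' @export
setGeneric("states", function(x) standardGeneric("states"))
#' @rdname DloopAlignment-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @rdname DloopAlignment-class
#' @export
setGeneric("insertions", function(x) standardGeneric("insertions"))
#' @rdname DloopAlignment-class
#' @export
setGeneric("reference", function(x) standardGeneric("reference"))

#' @rdname HaplotypePartition-class
#' @param x,object a `HaplotypePartition`
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname HaplotypePartition-class
#' @export
setGeneric("hapStates", function(x) standardGeneric("hapStates"))
#' @rdname HaplotypePartition-class
#' @export
setGeneric("includedSites", function(x) standardGeneric("includedSites"))
#' @rdname HaplotypePartition-class
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
#' @rdname HaplotypePartition-class
#' @export
setGeneric("hapCounts", function(x) standardGeneric("hapCounts"))

#' @rdname MotifTree-class
#' @param x,object a `MotifTree`
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))
#' @rdname MotifTree-class
#' @export
setGeneric("motifPath", function(x, node) standardGeneric("motifPath"))
#' @rdname MotifTree-class
#' @export
setGeneric("treeRoot", function(x) standardGeneric("treeRoot"))
#' @rdname MotifTree-class
#' @export
setGeneric("nodeDepths", function(x) standardGeneric("nodeDepths"))

#' @rdname MJNetwork-class
#' @param x,object an `MJNetwork`
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))
#' @rdname MJNetwork-class
#' @export
setGeneric("nodeStates", function(x) standardGeneric("nodeStates"))
#' @rdname MJNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
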
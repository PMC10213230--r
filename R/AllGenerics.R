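#' @rdname asvCounts
#' @export
setGeneric("asvCounts", function(x, ...) standardGeneric("asvCounts"))

#' @rdname taxonomyTable
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname sampleData
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname relativeAbundance
#' @export
setGeneric("relativeAbundance",
           function(x, ...) standardGeneric("relativeAbundance"))

#' Absolute-value similarity matrix of a SimilarityMatrix
#' @rdname similarityValues
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))

#' Signed correlation matrix of a SimilarityMatrix
#' @rdname correlationValues
#' @export
setGeneric("correlationValues",
           function(x) standardGeneric("correlationValues"))

#' Underlying igraph of a CoNetwork
#' @rdname networkGraph
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' Similarity cutoff of a CoNetwork
#' @rdname networkCutoff
#' @export
setGeneric("networkCutoff", function(x) standardGeneric("networkCutoff"))

#' Edge table of a CoNetwork
#' @rdname edgeTable
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Node table of a CoNetwork
#' @rdname nodeTable
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' Module membership of a ModulePartition
#' @rdname moduleMembership
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))

#' Threshold chosen by an RMT scan
#' @rdname chosenThreshold
#' @export
setGeneric("chosenThreshold", function(x) standardGeneric("chosenThreshold"))

#' Per-threshold records of an RMT scan
#' @rdname scanRecords
#' @export
setGeneric("scanRecords", function(x) standardGeneric("scanRecords"))

#' Tabular view of an AbundancePartition
#' @rdname partitionTable
#' @export
setGeneric("partitionTable", function(x) standardGeneric("partitionTable"))

#' Taxa retained for network construction
#' @rdname retainedTaxa
#' @export
setGeneric("retainedTaxa", function(x) standardGeneric("retainedTaxa"))

#' Empirical metrics of a TopologySummary
#' @rdname topologyMetrics
#' @export
setGeneric("topologyMetrics", function(x) standardGeneric("topologyMetrics"))

#' Random-null metrics of a TopologySummary
#' @rdname topologyNulls
#' @export
setGeneric("topologyNulls", function(x) standardGeneric("topologyNulls"))
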
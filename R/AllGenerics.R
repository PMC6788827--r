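# Accessor generics for the package's S4 containers.

#' @rdname EpochSet-class
#' @param object,x An object.
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname EpochSet-class
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @rdname EpochSet-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname EpochSet-class
#' @export
setGeneric("alignment", function(x) standardGeneric("alignment"))
#' @rdname EpochSet-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EpochSet-class
#' @export
setGeneric("trialIndex", function(x) standardGeneric("trialIndex"))
#' @rdname EpochSet-class
#' @export
setGeneric("baselineWindow", function(x) standardGeneric("baselineWindow"))
#' @rdname EpochSet-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname DecodingMatrix-class
#' @export
setGeneric("azMatrix", function(x) standardGeneric("azMatrix"))
#' @rdname DecodingMatrix-class
#' @export
setGeneric("trainTimes", function(x) standardGeneric("trainTimes"))
#' @rdname DecodingMatrix-class
#' @export
setGeneric("testTimes", function(x) standardGeneric("testTimes"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname ClusterSet-class
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname ClusterSet-class
#' @param alpha Cluster-level significance level.
#' @export
setGeneric("significantClusters", function(x, alpha = 0.05) standardGeneric("significantClusters"))

#' @rdname SpatialFilterModel-class
#' @export
setGeneric("filterWeights", function(x) standardGeneric("filterWeights"))
#' @rdname SpatialFilterModel-class
#' @export
setGeneric("filterBias", function(x) standardGeneric("filterBias"))
#' @rdname SpatialFilterModel-class
#' @param newdata trials x channels matrix to project.
#' @export
setGeneric("projectTrials", function(x, newdata) standardGeneric("projectTrials"))
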
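# Accessors and show methods.

#' @rdname EpochSet-class
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)
#' @rdname EpochSet-class
#' @export
setMethod("epochTimes", "EpochSet", function(x) x@times)
#' @rdname EpochSet-class
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)
#' @rdname EpochSet-class
#' @export
setMethod("alignment", "EpochSet", function(x) x@alignment)
#' @rdname EpochSet-class
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@srate)
#' @rdname EpochSet-class
#' @export
setMethod("trialIndex", "EpochSet", function(x) x@trialIndex)
#' @rdname EpochSet-class
#' @export
setMethod("baselineWindow", "EpochSet", function(x) x@baseline)
#' @rdname EpochSet-class
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1])

#' Subset an EpochSet by trial
#'
#' @param x An EpochSet.
#' @param i Trial positions (logical or integer, in epoch order).
#' @param j,...,drop Ignored.
#' @return An EpochSet containing the selected trials.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  EpochSet(x@data[i, , , drop = FALSE], x@times, x@alignment, x@channels,
           x@srate, x@trialIndex[i], x@baseline)
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples\n", d[1], d[2], d[3]))
  cat(sprintf("  alignment: %s-locked, %g Hz, %g..%g ms\n", object@alignment,
              object@srate, min(object@times), max(object@times)))
  if (length(object@baseline)) {
    cat(sprintf("  baseline: %g..%g ms\n", object@baseline[1], object@baseline[2]))
  } else cat("  baseline: none\n")
})

#' @rdname SpatialFilterModel-class
#' @export
setMethod("filterWeights", "SpatialFilterModel", function(x) x@weights)
#' @rdname SpatialFilterModel-class
#' @export
setMethod("filterBias", "SpatialFilterModel", function(x) x@bias)
#' @rdname SpatialFilterModel-class
#' @export
setMethod("projectTrials", "SpatialFilterModel", function(x, newdata) {
  stopIfNot(ncol(newdata) == length(x@weights),
            "newdata must have one column per channel weight")
  drop(as.matrix(newdata) %*% x@weights) + x@bias
})

setMethod("show", "SpatialFilterModel", function(object) {
  cat(sprintf("SpatialFilterModel: %d channel weights, bias %.4g\n",
              length(object@weights), object@bias))
  if (length(object@trainWindow) == 2)
    cat(sprintf("  train window: %g..%g ms\n", object@trainWindow[1], object@trainWindow[2]))
})

#' @rdname DecodingMatrix-class
#' @export
setMethod("azMatrix", "DecodingMatrix", function(x) x@az)
#' @rdname DecodingMatrix-class
#' @export
setMethod("trainTimes", "DecodingMatrix", function(x) x@trainTimes)
#' @rdname DecodingMatrix-class
#' @export
setMethod("testTimes", "DecodingMatrix", function(x) x@testTimes)

setMethod("show", "DecodingMatrix", function(object) {
  cat(sprintf("DecodingMatrix (%s-condition, %s-locked): %d train x %d test windows\n",
              object@condition, object@alignment,
              nrow(object@az), ncol(object@az)))
  cat(sprintf("  Az range: %.3f..%.3f (grand mean %.3f)\n",
              min(object@az), max(object@az), mean(object@az)))
})

#' @rdname ClusterSet-class
#' @export
setMethod("clusterTable", "ClusterSet", function(x) x@clusters)
#' @rdname ClusterSet-class
#' @export
setMethod("clusterMembers", "ClusterSet", function(x) x@members)
#' @rdname ClusterSet-class
#' @export
setMethod("significantClusters", "ClusterSet", function(x, alpha = 0.05) {
  x@clusters[x@clusters$p_value < alpha, , drop = FALSE]
})
#' @rdname ClusterSet-class
#' @export
setMethod("length", "ClusterSet", function(x) nrow(x@clusters))

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet (%s): %d cluster(s), forming p = %g, %d permutations\n",
              object@connectivity, nrow(object@clusters),
              object@elementThresholdP, object@nPermutations))
  if (nrow(object@clusters)) {
    print(object@clusters, row.names = FALSE)
  }
})
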
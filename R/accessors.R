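#' @include AllClasses.R
NULL

#' Accessors for meltmark containers
#'
#' Small generic layer over the S4 slots: temperatures and fluorescence of a
#' curve set, sample ids, Tm estimates, cluster labels and confidences,
#' digest fragments, and panel components.
#'
#' @param x a meltmark object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))
#' @rdname accessors
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("tmEstimates", function(x) standardGeneric("tmEstimates"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("clusterConfidence", function(x) standardGeneric("clusterConfidence"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))
#' @rdname accessors
#' @export
setGeneric("refAlignment", function(x) standardGeneric("refAlignment"))
#' @rdname accessors
#' @export
setGeneric("refGroups", function(x) standardGeneric("refGroups"))
#' @rdname accessors
#' @export
setGeneric("markerWindow", function(x) standardGeneric("markerWindow"))

#' @rdname accessors
setMethod("temperatures", "MeltCurveSet", function(x) x@temperature)
#' @rdname accessors
setMethod("temperatures", "NormalizedCurveSet", function(x) x@temperature)
#' @rdname accessors
setMethod("curveValues", "MeltCurveSet", function(x) x@fluorescence)
#' @rdname accessors
setMethod("curveValues", "NormalizedCurveSet", function(x) x@values)
#' @rdname accessors
setMethod("sampleIds", "MeltCurveSet", function(x) colnames(x@fluorescence))
#' @rdname accessors
setMethod("sampleIds", "NormalizedCurveSet", function(x) colnames(x@values))
#' @rdname accessors
setMethod("tmEstimates", "NormalizedCurveSet", function(x) x@tmEst)
#' @rdname accessors
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)
#' @rdname accessors
setMethod("clusterConfidence", "ClusterResult", function(x) x@confidence)
#' @rdname accessors
setMethod("fragments", "DigestPattern", function(x) x@fragments)
#' @rdname accessors
setMethod("refSequences", "ReferencePanel", function(x) x@sequences)
#' @rdname accessors
setMethod("refAlignment", "ReferencePanel", function(x) x@alignment)
#' @rdname accessors
setMethod("refGroups", "ReferencePanel", function(x) x@groups)
#' @rdname accessors
setMethod("markerWindow", "ReferencePanel", function(x) x@marker)

#' Construct a MeltCurveSet
#'
#' @param temperature numeric grid (degrees C), strictly increasing, constant
#'   step.
#' @param fluorescence numeric matrix with one named column per sample.
#' @param sampleData optional `DataFrame` of per-sample annotation.
#' @return a [MeltCurveSet-class] object.
#' @export
MeltCurveSet <- function(temperature, fluorescence, sampleData = NULL) {
  if (is.null(dim(fluorescence)))
    fluorescence <- matrix(fluorescence, ncol = 1L,
                           dimnames = list(NULL, "sample1"))
  new("MeltCurveSet", temperature = as.numeric(temperature),
      fluorescence = fluorescence, sampleData = sampleData)
}
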
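#' @describeIn StrideSeries-class subject identifier
#' @param object a \code{StrideSeries}, \code{PointCloud} or
#'   \code{FeatureMatrix}
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @describeIn StrideSeries-class group label
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))

#' @describeIn StrideSeries-class stride intervals in seconds
#' @export
setGeneric("strideValues", function(object) standardGeneric("strideValues"))

#' @describeIn StrideSeries-class elapsed-time stamps in seconds
#' @export
setGeneric("strideTimes", function(object) standardGeneric("strideTimes"))

#' @describeIn StrideSeries-class number of strides
#' @export
setGeneric("nStrides", function(object) standardGeneric("nStrides"))

#' @describeIn PointCloud-class coordinate matrix (one point per row)
#' @export
setGeneric("cloudPoints", function(object) standardGeneric("cloudPoints"))

#' @describeIn PersistenceDiagram-class birth-death pairs, optionally
#'   restricted to one homology dimension
#' @param object a \code{PersistenceDiagram}
#' @param dimension if given, return only pairs of this homology dimension
#' @export
setGeneric("persistencePairs",
  function(object, dimension = NULL) standardGeneric("persistencePairs"))

#' @describeIn Landscape-class the K x G matrix of landscape levels
#' @param object a \code{Landscape} object
#' @export
setGeneric("landscapeLevels",
  function(object) standardGeneric("landscapeLevels"))

#' @describeIn Landscape-class the uniform grid the landscape is sampled on
#' @export
setGeneric("landscapeGrid", function(object) standardGeneric("landscapeGrid"))

#' @describeIn FeatureMatrix-class the numeric feature matrix
#' @param object a \code{FeatureMatrix}
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @describeIn FeatureMatrix-class group labels, one per row
#' @export
setGeneric("featureLabels", function(object) standardGeneric("featureLabels"))
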
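#' @rdname StrideSeries-class
#' @export
setMethod("subjectId", "StrideSeries", function(object) object@subjectId)

#' @rdname PointCloud-class
#' @export
setMethod("subjectId", "PointCloud", function(object) object@subjectId)

#' @rdname StrideSeries-class
#' @export
setMethod("groupLabel", "StrideSeries", function(object) object@group)

#' @rdname StrideSeries-class
#' @export
setMethod("strideValues", "StrideSeries", function(object) object@values)

#' @rdname StrideSeries-class
#' @export
setMethod("strideTimes", "StrideSeries", function(object) object@timestamps)

#' @rdname StrideSeries-class
#' @export
setMethod("nStrides", "StrideSeries", function(object) length(object@values))

#' @rdname PointCloud-class
#' @export
setMethod("cloudPoints", "PointCloud", function(object) object@points)

#' @rdname PointCloud-class
#' @export
setMethod("nrow", "PointCloud", function(x) base::nrow(x@points))

#' @rdname PersistenceDiagram-class
#' @export
setMethod("persistencePairs", "PersistenceDiagram",
  function(object, dimension = NULL) {
    p <- object@pairs
    if (!is.null(dimension)) p <- p[p$dimension == dimension, , drop = FALSE]
    rownames(p) <- NULL
    p
  })

#' @rdname Landscape-class
#' @export
setMethod("landscapeLevels", "Landscape", function(object) object@levels)

#' @rdname Landscape-class
#' @export
setMethod("landscapeGrid", "Landscape", function(object)
  seq(object@xMin, object@xMax, length.out = ncol(object@levels)))

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@features)

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureLabels", "FeatureMatrix", function(object) object@labels)

setMethod("show", "StrideSeries", function(object) {
  cat(sprintf(
    "StrideSeries '%s' (%s, %s foot): %d strides over %.1f s, mean %.3f s\n",
    object@subjectId, object@group, object@foot, length(object@values),
    diff(range(object@timestamps)), mean(object@values)))
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud '%s': %d points in %d-D (tau = %d)\n",
              object@subjectId, base::nrow(object@points),
              ncol(object@points), object@tau))
})

setMethod("show", "PersistenceDiagram", function(object) {
  p <- object@pairs
  cat(sprintf(
    "PersistenceDiagram: %d H0 pairs, %d H1 pairs (max scale %.4g)\n",
    sum(p$dimension == 0L), sum(p$dimension == 1L), object@maxScale))
})

setMethod("show", "Landscape", function(object) {
  cat(sprintf("Landscape: K = %d levels on %d grid points over [%.4g, %.4g]\n",
              base::nrow(object@levels), ncol(object@levels),
              object@xMin, object@xMax))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d subjects x %d features (tau = %s); groups: %s\n",
              base::nrow(object@features), ncol(object@features),
              object@tau, paste(levels(object@labels), collapse = ", ")))
})
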
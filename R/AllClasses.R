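#' @import methods
NULL

.GROUPS <- c("HC", "ALS", "HD", "PD")

#' StrideSeries: one subject's stride-interval recording
#'
#' Holds the timestamped stride-interval sequence of one walking trial for a
#' single foot, together with the subject identifier and clinical group
#' label. Timestamps are elapsed seconds since the start of the recording;
#' values are stride intervals in seconds (time between consecutive ground
#' contacts of the same foot).
#'
#' @slot subjectId character scalar identifying the subject.
#' @slot group group label; one of \code{"HC"}, \code{"ALS"}, \code{"HD"},
#'   \code{"PD"}, or another cohort label for synthetic data.
#' @slot foot which foot the stride intervals belong to (\code{"left"} or
#'   \code{"right"}).
#' @slot timestamps numeric vector of elapsed seconds, strictly increasing.
#' @slot values numeric vector of stride intervals in seconds, all positive,
#'   same length as \code{timestamps}.
#'
#' @examples
#' s <- StrideSeries("toy", "HC", timestamps = c(20.1, 21.2, 22.3),
#'                   values = c(1.10, 1.12, 1.09))
#' nStrides(s)
#' @export
setClass("StrideSeries",
  representation(
    subjectId = "character",
    group = "character",
    foot = "character",
    timestamps = "numeric",
    values = "numeric"
  )
)

setValidity("StrideSeries", function(object) {
  msg <- NULL
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(object@values) != length(object@timestamps))
    msg <- c(msg, "values and timestamps must have equal length")
  if (length(object@values) < 2L)
    msg <- c(msg, "a stride series needs at least 2 strides")
  if (any(!is.finite(object@values)) || any(object@values <= 0))
    msg <- c(msg, "all stride intervals must be finite and > 0")
  if (any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (!object@foot %in% c("left", "right"))
    msg <- c(msg, "foot must be 'left' or 'right'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a StrideSeries
#'
#' @param subjectId subject identifier.
#' @param group cohort label (case-insensitive; canonical labels
#'   \code{"HC"}, \code{"ALS"}, \code{"HD"}, \code{"PD"} are upper-cased).
#' @param timestamps elapsed seconds, strictly increasing.
#' @param values stride intervals in seconds.
#' @param foot \code{"right"} (default) or \code{"left"}.
#' @return A \linkS4class{StrideSeries}.
#' @export
StrideSeries <- function(subjectId, group, timestamps, values,
                         foot = "right") {
  g <- as.character(group)
  if (toupper(g) %in% .GROUPS) g <- toupper(g)
  new("StrideSeries", subjectId = as.character(subjectId), group = g,
      foot = foot, timestamps = as.numeric(timestamps),
      values = as.numeric(values))
}

#' PointCloud: delay-embedded stride dynamics
#'
#' An ordered set of d-dimensional points obtained by time-delay embedding
#' of a stride-interval series (and possibly reduced by maxmin landmark
#' subsampling). Coordinates are stride intervals in seconds.
#'
#' @slot points numeric matrix, one point per row, \code{d} columns.
#' @slot tau integer delay (in strides) used by the embedding.
#' @slot subjectId subject the cloud was derived from.
#' @export
setClass("PointCloud",
  representation(points = "matrix", tau = "integer", subjectId = "character")
)

setValidity("PointCloud", function(object) {
  msg <- NULL
  if (!is.numeric(object@points) || nrow(object@points) < 1L)
    msg <- c(msg, "points must be a nonempty numeric matrix")
  if (ncol(object@points) < 2L)
    msg <- c(msg, "embedding dimension must be at least 2")
  if (object@tau < 1L)
    msg <- c(msg, "tau must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PointCloud
#'
#' @param points numeric matrix, one point per row.
#' @param tau delay (strides) used by the embedding.
#' @param subjectId subject identifier.
#' @return a \linkS4class{PointCloud}.
#' @export
PointCloud <- function(points, tau, subjectId = NA_character_) {
  new("PointCloud", points = points, tau = as.integer(tau),
      subjectId = as.character(subjectId))
}

#' PersistenceDiagram: birth-death pairs of a Rips filtration
#'
#' Birth-death pairs \eqn{(b_\alpha, d_\alpha)} of the persistent homology
#' of a Vietoris-Rips filtration, grouped by homology dimension (0 =
#' connected components, 1 = loops). One essential H0 class per connected
#' component has death \code{Inf}. Zero-persistence pairs (birth = death)
#' are dropped.
#'
#' @slot pairs data.frame with columns \code{dimension} (integer),
#'   \code{birth}, \code{death} (numeric, \code{Inf} for essential classes).
#' @slot maxScale the enclosing filtration threshold used.
#' @export
setClass("PersistenceDiagram",
  representation(pairs = "data.frame", maxScale = "numeric")
)

setValidity("PersistenceDiagram", function(object) {
  p <- object@pairs
  msg <- NULL
  if (!all(c("dimension", "birth", "death") %in% names(p)))
    msg <- c(msg, "pairs needs columns dimension, birth, death")
  else {
    if (any(p$birth < 0)) msg <- c(msg, "births must be >= 0")
    if (any(p$death < p$birth)) msg <- c(msg, "death must be >= birth")
  }
  if (length(object@maxScale) != 1L || object@maxScale < 0)
    msg <- c(msg, "maxScale must be a single nonnegative number")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PersistenceDiagram from parallel vectors
#'
#' @param dimension integer homology dimensions (0 or 1) per pair.
#' @param birth,death numeric birth and death scales (\code{Inf} for
#'   essential classes).
#' @param maxScale enclosing filtration threshold.
#' @return a \linkS4class{PersistenceDiagram}.
#' @export
PersistenceDiagram <- function(dimension = integer(), birth = numeric(),
                               death = numeric(), maxScale = Inf) {
  new("PersistenceDiagram",
      pairs = data.frame(dimension = as.integer(dimension),
                         birth = as.numeric(birth),
                         death = as.numeric(death)),
      maxScale = as.numeric(maxScale))
}

#' Landscape: discretised persistence-landscape functions
#'
#' The persistence landscape of an H1 diagram: functions
#' \eqn{\lambda_k(x)}, k = 1..K, where \eqn{\lambda_k(x)} is the k-th
#' largest "tent" value over all birth-death pairs, sampled on a uniform
#' grid over \code{[xMin, xMax]}.
#'
#' @slot levels K x G numeric matrix of \eqn{\lambda_k} values; row k is
#'   level k on the grid.
#' @slot xMin,xMax grid range in filtration-scale units (seconds).
#' @export
setClass("Landscape",
  representation(levels = "matrix", xMin = "numeric", xMax = "numeric")
)

setValidity("Landscape", function(object) {
  msg <- NULL
  if (object@xMin >= object@xMax) msg <- c(msg, "xMin must be < xMax")
  if (ncol(object@levels) < 2L) msg <- c(msg, "grid needs >= 2 points")
  if (any(object@levels < -1e-12)) msg <- c(msg, "landscape values must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' FeatureMatrix: flattened landscapes for a cohort
#'
#' One flattened persistence landscape per subject (level-major: all of
#' \eqn{\lambda_1}'s grid samples, then \eqn{\lambda_2}'s, ...), with group
#' labels and the embedding delay that produced the features.
#'
#' @slot features numeric matrix, one subject per row, K*G columns.
#' @slot labels factor of group labels, one per row.
#' @slot tau embedding delay used (strides).
#' @export
setClass("FeatureMatrix",
  representation(features = "matrix", labels = "factor", tau = "integer")
)

setValidity("FeatureMatrix", function(object) {
  msg <- NULL
  if (nrow(object@features) != length(object@labels))
    msg <- c(msg, "one label per feature row required")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FeatureMatrix
#'
#' @param features numeric matrix, one subject per row.
#' @param labels group label per row.
#' @param tau embedding delay the features were computed at.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(features, labels, tau = NA_integer_) {
  new("FeatureMatrix", features = features,
      labels = as.factor(labels), tau = as.integer(tau))
}
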
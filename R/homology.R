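#' Euclidean distance matrix of a point cloud
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @return symmetric numeric matrix of pairwise Euclidean distances with a
#'   zero diagonal.
#' @export
pairwiseDistances <- function(cloud) {
  stopifnot(is(cloud, "PointCloud"))
  as.matrix(stats::dist(cloudPoints(cloud)))
}

#' Enclosing radius of a distance matrix
#'
#' The maximum pairwise distance. Used as the default filtration threshold:
#' at this scale the Rips complex is the complete graph with all triangles,
#' so every H1 class has died and landscapes need no infinite bars.
#'
#' @param dmat symmetric distance matrix.
#' @return a single nonnegative number.
#' @export
enclosingRadius <- function(dmat) max(dmat)

#' Build the Vietoris-Rips filtration of a distance matrix
#'
#' The Rips complex at scale \eqn{\epsilon} contains a simplex whenever all
#' pairwise distances among its vertices are at most \eqn{\epsilon}; each
#' simplex enters the filtration at its diameter. Simplices up to dimension
#' \code{maxDim} (default 2, i.e., triangles, sufficient for H0/H1) with
#' diameter at most \code{threshold} are enumerated and sorted by
#' (filtration value, dimension, lexicographic vertex order), which places
#' every face before its cofaces and makes the ordering deterministic.
#'
#' @param dmat symmetric distance matrix (zero diagonal).
#' @param threshold maximum filtration scale; default the enclosing radius.
#' @param maxDim highest simplex dimension, at most 2.
#' @return data.frame with columns \code{v1,v2,v3} (1-based vertex indices,
#'   \code{NA} when absent), \code{dim} and \code{value}, in filtration
#'   order.
#' @export
ripsFiltration <- function(dmat, threshold = enclosingRadius(dmat),
                           maxDim = 2) {
  stopifnot(is.matrix(dmat), base::nrow(dmat) == ncol(dmat), threshold >= 0)
  if (maxDim > 2) stop("only simplices up to dimension 2 are supported")
  n <- base::nrow(dmat)

  verts <- data.frame(v1 = seq_len(n), v2 = NA_integer_, v3 = NA_integer_,
                      dim = 0L, value = 0)
  parts <- list(verts)

  if (maxDim >= 1L && n >= 2L) {
    idx <- which(upper.tri(dmat), arr.ind = TRUE)
    len <- dmat[idx]
    keep <- len <= threshold
    if (any(keep)) {
      parts <- c(parts, list(data.frame(
        v1 = idx[keep, 1L], v2 = idx[keep, 2L], v3 = NA_integer_,
        dim = 1L, value = len[keep])))
    }
  }
  if (maxDim >= 2L && n >= 3L) {
    tri <- utils::combn(n, 3L)
    d12 <- dmat[cbind(tri[1L, ], tri[2L, ])]
    d13 <- dmat[cbind(tri[1L, ], tri[3L, ])]
    d23 <- dmat[cbind(tri[2L, ], tri[3L, ])]
    diam <- pmax(d12, d13, d23)
    keep <- diam <= threshold
    if (any(keep)) {
      parts <- c(parts, list(data.frame(
        v1 = tri[1L, keep], v2 = tri[2L, keep], v3 = tri[3L, keep],
        dim = 2L, value = diam[keep])))
    }
  }
  filt <- do.call(rbind, parts)
  o <- order(filt$value, filt$dim,
             filt$v1, ifelse(is.na(filt$v2), 0L, filt$v2),
             ifelse(is.na(filt$v3), 0L, filt$v3))
  filt <- filt[o, , drop = FALSE]
  rownames(filt) <- NULL
  filt
}

#' Persistent homology of an ordered filtration
#'
#' Runs the standard persistence algorithm (boundary-matrix column
#' reduction over the two-element field) on a filtration produced by
#' \code{\link{ripsFiltration}} and collects birth-death pairs for homology
#' dimensions 0 (components) and 1 (loops). Zero-persistence pairs (birth
#' equal to death) are discarded; one essential H0 pair with death
#' \code{Inf} remains per connected component at the threshold.
#'
#' @param filtration data.frame from \code{\link{ripsFiltration}} (faces
#'   must precede cofaces; this is checked).
#' @param maxScale the threshold the filtration was built with; stored on
#'   the diagram for barcode display.
#' @return a \linkS4class{PersistenceDiagram}.
#' @export
computePersistence <- function(filtration,
                               maxScale = max(filtration$value)) {
  m <- base::nrow(filtration)
  # boundary columns as filtration indices of each simplex's facets
  vkey <- function(a, b) (a - 1) * (m + 1) + b  # unique key per sorted pair
  edgeRows <- which(filtration$dim == 1L)
  edgeKey <- vkey(filtration$v1[edgeRows], filtration$v2[edgeRows])
  columns <- vector("list", m)
  for (j in seq_len(m)) columns[[j]] <- integer(0)
  vertPos <- integer(max(filtration$v1, na.rm = TRUE))
  vertRows <- which(filtration$dim == 0L)
  vertPos[filtration$v1[vertRows]] <- vertRows
  for (j in edgeRows) {
    columns[[j]] <- vertPos[c(filtration$v1[j], filtration$v2[j])]
  }
  triRows <- which(filtration$dim == 2L)
  if (length(triRows)) {
    e1 <- match(vkey(filtration$v1[triRows], filtration$v2[triRows]), edgeKey)
    e2 <- match(vkey(filtration$v1[triRows], filtration$v3[triRows]), edgeKey)
    e3 <- match(vkey(filtration$v2[triRows], filtration$v3[triRows]), edgeKey)
    if (anyNA(e1) || anyNA(e2) || anyNA(e3))
      stop("invalid filtration: a triangle has a missing edge face")
    for (t in seq_along(triRows)) {
      columns[[triRows[t]]] <- edgeRows[c(e1[t], e2[t], e3[t])]
    }
  }

  red <- .reduceBoundary(columns)
  creator <- red[, 2L] == 1L
  killed <- red[, 1L]                # creator index destroyed by each column

  births <- which(killed > 0L)       # destroyer columns
  bIdx <- killed[births]
  pdim <- filtration$dim[bIdx]
  birth <- filtration$value[bIdx]
  death <- filtration$value[births]
  keep <- death > birth & pdim <= 1L
  essential <- which(creator & !(seq_len(m) %in% bIdx))
  essential <- essential[filtration$dim[essential] <= 1L]

  PersistenceDiagram(
    dimension = c(pdim[keep], filtration$dim[essential]),
    birth = c(birth[keep], filtration$value[essential]),
    death = c(death[keep], rep(Inf, length(essential))),
    maxScale = maxScale)
}

#' Rips persistence diagram of a point cloud
#'
#' Convenience wrapper: distance matrix, Rips filtration at the given
#' threshold, then persistence.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param threshold filtration threshold; default the enclosing radius.
#' @return a \linkS4class{PersistenceDiagram}.
#' @export
ripsDiagram <- function(cloud, threshold = NULL) {
  dmat <- pairwiseDistances(cloud)
  if (is.null(threshold)) threshold <- enclosingRadius(dmat)
  computePersistence(ripsFiltration(dmat, threshold = threshold),
                     maxScale = threshold)
}

#' Barcode view of a persistence diagram
#'
#' Re-views birth-death pairs as intervals. Essential classes (infinite
#' death) are capped at the diagram's \code{maxScale} for display and
#' flagged.
#'
#' @param diagram a \linkS4class{PersistenceDiagram}.
#' @return data.frame with columns \code{dimension}, \code{start},
#'   \code{end}, \code{essential}.
#' @export
diagramToBarcode <- function(diagram) {
  p <- persistencePairs(diagram)
  if (base::nrow(p) == 0L)
    return(data.frame(dimension = integer(), start = numeric(),
                      end = numeric(), essential = logical()))
  ess <- is.infinite(p$death)
  data.frame(dimension = p$dimension, start = p$birth,
             end = ifelse(ess, diagram@maxScale, p$death), essential = ess)
}

#' Export / import a persistence diagram as delimited text
#'
#' Tab-separated with a header (\code{dimension}, \code{birth},
#' \code{death}); infinite deaths are written as \code{Inf}. For
#' interoperability with external TDA tools.
#'
#' @param diagram a \linkS4class{PersistenceDiagram}.
#' @param path file path.
#' @export
writeDiagram <- function(diagram, path) {
  utils::write.table(persistencePairs(diagram), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDiagram
#' @param maxScale threshold recorded on the imported diagram.
#' @export
readDiagram <- function(path, maxScale = Inf) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  PersistenceDiagram(tab$dimension, tab$birth, tab$death, maxScale = maxScale)
}
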
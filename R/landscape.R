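#' Tent function of a single birth-death pair
#'
#' The piecewise-linear function rising with slope 1 from the birth, peaking
#' at \eqn{(d-b)/2} at the midpoint \eqn{(b+d)/2}, falling back to zero at
#' the death, and zero outside \eqn{(b, d)}.
#'
#' @param birth,death finite birth and death values.
#' @param x numeric vector of evaluation points.
#' @return numeric vector of tent values.
#' @export
tentValue <- function(birth, death, x) {
  if (is.infinite(birth) || is.infinite(death))
    stop("tentValue requires a finite pair; exclude essential classes first")
  pmax(0, pmin(x - birth, death - x))
}

#' Persistence landscape of an H1 diagram
#'
#' The k-th landscape level \eqn{\lambda_k(x)} is the k-th largest tent
#' value at x over all H1 birth-death pairs (zero where fewer than k pairs
#' overlap). Levels are sampled on a uniform grid of \code{G} points over
#' \code{[xMin, xMax]} and stacked into a K x G matrix.
#'
#' @param diagram a \linkS4class{PersistenceDiagram}; its H1 pairs must all
#'   be finite.
#' @param kMax number of levels K (default 5).
#' @param xMin,xMax grid range; \code{xMax} defaults to the largest finite
#'   H1 death (or the max scale if H1 is empty).
#' @param G number of grid points (default 100).
#' @return a \linkS4class{Landscape}.
#' @examples
#' dg <- PersistenceDiagram(dimension = c(1L, 1L), birth = c(0, 1),
#'                          death = c(2, 3), maxScale = 4)
#' ls <- computeLandscape(dg, kMax = 2, xMin = 0, xMax = 4, G = 5)
#' landscapeLevels(ls)
#' @export
computeLandscape <- function(diagram, kMax = 5, xMin = 0, xMax = NULL,
                             G = 100) {
  stopifnot(is(diagram, "PersistenceDiagram"))
  h1 <- persistencePairs(diagram, dimension = 1L)
  if (any(is.infinite(h1$death)))
    stop("H1 diagram has essential classes; use an enclosing-radius threshold")
  if (is.null(xMax)) {
    xMax <- if (base::nrow(h1)) max(h1$death) else diagram@maxScale
    if (!is.finite(xMax) || xMax <= xMin) xMax <- xMin + 1
  }
  x <- seq(xMin, xMax, length.out = G)
  levels <- matrix(0, nrow = kMax, ncol = G)
  if (base::nrow(h1)) {
    tents <- vapply(seq_len(base::nrow(h1)),
                    function(i) tentValue(h1$birth[i], h1$death[i], x),
                    numeric(G))           # G x npairs
    k <- min(kMax, ncol(tents))
    sorted <- apply(tents, 1L, function(v) sort(v, decreasing = TRUE)[seq_len(k)])
    if (k == 1L) sorted <- matrix(sorted, nrow = 1L)
    levels[seq_len(k), ] <- sorted
  }
  new("Landscape", levels = levels, xMin = xMin, xMax = xMax)
}

#' Landscape feature matrix for a cohort of diagrams
#'
#' Computes one persistence landscape per subject on a common grid and
#' flattens each level-major (all \eqn{\lambda_1} samples, then
#' \eqn{\lambda_2}, ...) into a K*G feature vector. The grid spans
#' \code{[0, xMax]} where \code{xMax} is the largest finite H1 death over
#' the scoping set: the diagrams themselves, or an explicit \code{gridMax}
#' (e.g., fitted on a training fold to avoid leakage).
#'
#' @param diagrams list of \linkS4class{PersistenceDiagram}, one per
#'   subject.
#' @param labels group label per subject.
#' @param kMax,G landscape discretisation (defaults K = 5, G = 100).
#' @param gridMax optional fixed grid upper end; default the max finite H1
#'   death over \code{diagrams}.
#' @param tau embedding delay to record on the result.
#' @return a \linkS4class{FeatureMatrix} with one row per diagram.
#' @export
vectorizeCohort <- function(diagrams, labels, kMax = 5, G = 100,
                            gridMax = NULL, tau = NA_integer_) {
  stopifnot(length(diagrams) >= 1L, length(labels) == length(diagrams))
  if (is.null(gridMax)) {
    deaths <- unlist(lapply(diagrams, function(d) {
      h1 <- persistencePairs(d, dimension = 1L)
      h1$death[is.finite(h1$death)]
    }))
    if (length(deaths) == 0L) {
      warning("all diagrams have empty H1; returning an all-zero matrix")
      gridMax <- 1
    } else gridMax <- max(deaths)
  }
  rows <- t(vapply(diagrams, function(d) {
    ls <- computeLandscape(d, kMax = kMax, xMin = 0, xMax = gridMax, G = G)
    as.vector(t(landscapeLevels(ls)))  # level-major
  }, numeric(kMax * G)))
  ids <- vapply(seq_along(diagrams), function(i) sprintf("s%d", i),
                character(1))
  rownames(rows) <- ids
  FeatureMatrix(rows, labels = labels, tau = tau)
}
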
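#' Time-delay embedding of a stride series
#'
#' Reconstructs a phase-space point cloud from the scalar stride-interval
#' sequence f: the point at index t is
#' \eqn{(f(t), f(t+\tau), \ldots, f(t+(d-1)\tau))}, for
#' t = 1 .. N - (d-1)\eqn{\tau}. With the default d = 2 each subject's
#' series becomes a 2-D cloud whose loop structure reflects quasi-periodic
#' gait rhythm.
#'
#' @param series a \linkS4class{StrideSeries} (typically cleaned first).
#' @param tau delay in strides (>= 1).
#' @param d embedding dimension (default 2).
#' @return a \linkS4class{PointCloud} with N - (d-1)*tau points.
#' @examples
#' s <- StrideSeries("toy", "HC", timestamps = 1:6, values = 1:6 / 10 + 1)
#' cloudPoints(delayEmbed(s, tau = 2))
#' @export
delayEmbed <- function(series, tau, d = 2) {
  stopifnot(is(series, "StrideSeries"))
  tau <- as.integer(tau); d <- as.integer(d)
  if (tau < 1L) stop("tau must be >= 1")
  if (d < 2L) stop("embedding dimension must be >= 2")
  x <- strideValues(series)
  n <- length(x)
  npts <- n - (d - 1L) * tau
  if (npts < 1L)
    stop("series '", subjectId(series), "' too short for delay embedding: ",
         "N = ", n, " <= (d-1)*tau = ", (d - 1L) * tau)
  pts <- vapply(seq_len(d) - 1L,
                function(j) x[seq_len(npts) + j * tau],
                numeric(npts))
  if (npts == 1L) pts <- matrix(pts, nrow = 1L)
  PointCloud(pts, tau = tau, subjectId = subjectId(series))
}

#' Maxmin (farthest-point) landmark subsampling
#'
#' Greedily selects \code{m} landmarks that approximate the shape of the
#' cloud: starting from a seeded random point, each subsequent landmark is
#' the point farthest (Euclidean) from the landmarks chosen so far, with
#' argmax ties broken by lowest point index. Clouds with at most \code{m}
#' points are returned unchanged. Deterministic given \code{(cloud, m,
#' seed)}.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param m target number of landmarks (default 50).
#' @param seed integer seed for the initial landmark draw (default 42).
#' @return a \linkS4class{PointCloud} with \code{min(m, n)} points, a
#'   subset of the input points in selection order.
#' @export
maxminSubsample <- function(cloud, m = 50, seed = 42) {
  stopifnot(is(cloud, "PointCloud"))
  if (m < 1) stop("m must be >= 1")
  pts <- cloudPoints(cloud)
  n <- base::nrow(pts)
  if (n <= m) return(cloud)
  first <- withSeed(seed, sample.int(n, 1L))
  chosen <- integer(m)
  chosen[1L] <- first
  # running minimum distance from each point to the chosen landmark set
  dmin <- sqrt(rowSums(sweep(pts, 2L, pts[first, ])^2))
  for (i in seq_len(m - 1L)) {
    nxt <- which.max(dmin)  # ties -> lowest index
    chosen[i + 1L] <- nxt
    dn <- sqrt(rowSums(sweep(pts, 2L, pts[nxt, ])^2))
    dmin <- pmin(dmin, dn)
  }
  PointCloud(pts[chosen, , drop = FALSE], tau = cloud@tau,
             subjectId = subjectId(cloud))
}
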
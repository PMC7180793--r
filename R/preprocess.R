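#' Drop the startup transient of a walking trial
#'
#' Gait acquisition shows a startup effect; the customary remedy is to
#' discard the opening seconds of the recording. Keeps every stride whose
#' timestamp is at least \code{tMin} seconds after the first timestamp
#' (boundary strides are kept). Original timestamps are retained.
#'
#' @param series a \linkS4class{StrideSeries}.
#' @param tMin seconds to discard from the start (default 20).
#' @return the trimmed \linkS4class{StrideSeries}.
#' @export
removeStartup <- function(series, tMin = 20) {
  stopifnot(is(series, "StrideSeries"))
  ts <- strideTimes(series)
  keep <- ts >= ts[1L] + tMin
  if (!any(keep))
    stop("series '", subjectId(series), "' too short: nothing remains after ",
         tMin, " s startup removal")
  StrideSeries(subjectId(series), groupLabel(series),
               timestamps = ts[keep], values = strideValues(series)[keep],
               foot = series@foot)
}

#' Replace turn-around outliers by the median stride interval
#'
#' Walking trials include turn-backs that produce aberrant stride
#' intervals. In a single pass, the median \eqn{\hat\mu} and the sample
#' standard deviation \eqn{s} of the series are computed once, and every
#' stride interval strictly outside \eqn{[\hat\mu - 2s, \hat\mu + 2s]} is
#' replaced by \eqn{\hat\mu}; all other values and the series length are
#' unchanged. The median (not the mean) is the replacement value because
#' large outliers inflate the mean. The bounds are not recomputed after
#' replacement.
#'
#' @param series a \linkS4class{StrideSeries}.
#' @return list with elements \code{series} (cleaned
#'   \linkS4class{StrideSeries}) and \code{report} (data.frame with
#'   \code{median}, \code{std}, \code{lower}, \code{upper},
#'   \code{n_replaced}, \code{n_total}).
#' @examples
#' s <- StrideSeries("toy", "HC", timestamps = cumsum(c(1, 1, 1, 1, 10)),
#'                   values = c(1, 1, 1, 1, 10))
#' replaceOutliers(s)$report
#' @export
replaceOutliers <- function(series) {
  stopifnot(is(series, "StrideSeries"))
  x <- strideValues(series)
  mu <- stats::median(x)
  s <- stats::sd(x)
  lower <- mu - 2 * s
  upper <- mu + 2 * s
  out <- x > upper | x < lower
  x[out] <- mu
  cleaned <- StrideSeries(subjectId(series), groupLabel(series),
                          timestamps = strideTimes(series), values = x,
                          foot = series@foot)
  report <- data.frame(median = mu, std = s, lower = lower, upper = upper,
                       n_replaced = sum(out), n_total = length(x))
  list(series = cleaned, report = report)
}

#' Standard cleaning pipeline for one stride series
#'
#' Startup removal followed by median replacement of outliers, in that
#' order (the outlier bounds are computed on the trimmed series).
#'
#' @inheritParams removeStartup
#' @return the cleaned \linkS4class{StrideSeries}.
#' @export
preprocessSeries <- function(series, tMin = 20) {
  replaceOutliers(removeStartup(series, tMin = tMin))$series
}
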
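#' Channel map of the whitespace-delimited stride-interval dialect
#'
#' Column 1 is elapsed time (s), column 2 the left stride interval (s),
#' column 3 the right stride interval (s); any further columns (swing,
#' stance, double-support measures) are parsed but unused. Override to
#' accommodate files with a different layout.
#'
#' @return named integer vector mapping channel names to column indices.
#' @export
defaultChannelMap <- function() c(time = 1L, left = 2L, right = 3L)

#' Read one subject's stride-interval file
#'
#' Parses a whitespace-delimited per-subject file (one row per stride:
#' elapsed time followed by per-stride interval measures) into a
#' \linkS4class{StrideSeries}, keeping rows in file order.
#'
#' @param path path to the subject file.
#' @param group cohort label to attach.
#' @param channel which stride channel to read, \code{"right"} (default) or
#'   \code{"left"}, or a column index.
#' @param subjectId identifier; defaults to the file name without extension.
#' @param channelMap named column map, see \code{\link{defaultChannelMap}}.
#' @return A \linkS4class{StrideSeries}.
#' @examples
#' f <- tempfile(fileext = ".ts")
#' writeLines(c("20.1 1.11 1.10", "21.2 1.13 1.12", "22.3 1.08 1.09"), f)
#' readStrideFile(f, group = "HC")
#' @export
readStrideFile <- function(path, group, channel = "right",
                           subjectId = NULL,
                           channelMap = defaultChannelMap()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subjectId)) subjectId <- sub("\\.[^.]*$", "", basename(path))
  col <- if (is.numeric(channel)) as.integer(channel)
         else unname(channelMap[[as.character(channel)]])
  if (is.null(col) || is.na(col)) stop("unknown channel: ", channel)
  foot <- if (identical(col, unname(channelMap[["left"]]))) "left" else "right"

  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  arity <- lengths(fields)
  if (any(arity < max(col, channelMap[["time"]]))) {
    bad <- which(arity < max(col, channelMap[["time"]]))[1L]
    stop(sprintf("parse error in '%s' at line %d: expected at least %d columns, found %d",
                 path, bad, max(col, channelMap[["time"]]), arity[bad]))
  }
  num <- suppressWarnings(lapply(fields, as.numeric))
  nonnum <- which(vapply(num, function(v) any(is.na(v)), logical(1)))
  if (length(nonnum)) {
    stop(sprintf("parse error in '%s' at line %d: non-numeric field",
                 path, nonnum[1L]))
  }
  ts <- vapply(num, `[[`, numeric(1), channelMap[["time"]])
  vals <- vapply(num, `[[`, numeric(1), col)
  if (any(diff(ts) <= 0)) {
    bad <- which(diff(ts) <= 0)[1L] + 1L
    stop(sprintf("validation error in '%s': timestamps not strictly increasing at line %d",
                 path, bad))
  }
  StrideSeries(subjectId, group, timestamps = ts, values = vals, foot = foot)
}

#' Read a cohort of stride-interval files from a manifest
#'
#' The manifest is a delimited text table (header row) with columns
#' \code{path}, \code{subject_id} and \code{group}; relative paths are
#' resolved against the manifest's directory. Group strings are matched
#' case-insensitively against the canonical labels HC/ALS/HD/PD.
#'
#' @param manifest path to a manifest file, or a data.frame with the same
#'   columns.
#' @param channel stride channel passed to \code{\link{readStrideFile}}.
#' @param channelMap column map passed to \code{\link{readStrideFile}}.
#' @return list of \linkS4class{StrideSeries}, one per manifest row, in
#'   manifest order.
#' @export
readCohort <- function(manifest, channel = "right",
                       channelMap = defaultChannelMap()) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    tab <- utils::read.table(manifest, header = TRUE, sep = "",
                             stringsAsFactors = FALSE)
  } else {
    dir <- "."
    tab <- as.data.frame(manifest)
  }
  need <- c("path", "subject_id", "group")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) return(list())
  lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(dir, tab$path[i])
    if (!file.exists(p))
      stop("missing file for subject '", tab$subject_id[i], "': ", tab$path[i])
    readStrideFile(p, group = tab$group[i], channel = channel,
                   subjectId = tab$subject_id[i], channelMap = channelMap)
  })
}

#' Persist and restore landscape feature matrices
#'
#' Feature matrices are written as delimited text with one header row and a
#' leading \code{subject_id}, \code{group} and \code{tau} column; values are
#' written with 17 significant digits so that the read/write round trip is
#' exact.
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param path output (input) file path.
#' @return \code{readFeatures} returns a \linkS4class{FeatureMatrix};
#'   \code{writeFeatures} returns \code{path} invisibly.
#' @export
writeFeatures <- function(x, path) {
  stopifnot(is(x, "FeatureMatrix"))
  m <- featureValues(x)
  df <- data.frame(
    subject_id = if (is.null(rownames(m))) sprintf("s%d", seq_len(nrow(m)))
                 else rownames(m),
    group = as.character(featureLabels(x)),
    tau = rep(x@tau, length.out = nrow(m)),
    stringsAsFactors = FALSE)
  vals <- as.data.frame(m)
  names(vals) <- if (is.null(colnames(m)))
    sprintf("f%d", seq_len(ncol(m))) else colnames(m)
  out <- cbind(df, vals)
  # 17 significant digits round-trips IEEE doubles exactly
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "tau")
  if (!all(need %in% names(tab)))
    stop("feature file schema mismatch: expected columns ",
         paste(need, collapse = ", "))
  featcols <- setdiff(names(tab), need)
  m <- as.matrix(tab[featcols])
  if (nrow(tab) > 0L && length(featcols) && !is.numeric(m))
    stop("feature file schema mismatch: non-numeric feature columns")
  storage.mode(m) <- "double"
  rownames(m) <- tab$subject_id
  tau <- if (nrow(tab)) tab$tau[1L] else NA_integer_
  FeatureMatrix(m, labels = factor(tab$group), tau = tau)
}
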
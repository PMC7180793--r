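#' Synthetic cohort group profile
#'
#' Parameters of the stride-interval generator for one cohort. A subject's
#' series is a quasi-periodic oscillation around a baseline stride time
#' with AR(1) coloured noise and occasional turn-around outlier spikes:
#' \deqn{x_n = baseline + A \sin(2\pi n / P + \phi) + e_n,\quad
#'       e_n = \rho e_{n-1} + \sigma \epsilon_n.}
#' The sinusoid traces a loop in the 2-D delay embedding, so oscillation
#' amplitude relative to noise controls how prominent the H1 signal is:
#' healthy-like profiles get a clear loop (low noise, visible oscillation),
#' disease-like profiles a blurred one (more, and more autocorrelated,
#' noise).
#'
#' @param name cohort label.
#' @param baseline mean stride interval, seconds.
#' @param oscAmp amplitude A of the quasi-periodic component, seconds.
#' @param oscPeriod period P, strides.
#' @param arCoef AR(1) coefficient rho in [0, 1).
#' @param noiseSd innovation standard deviation sigma, seconds.
#' @param outlierRate probability per stride of a turn-around spike.
#' @param duration target walk duration, seconds (5-minute trials by
#'   default); the stride count is duration / baseline.
#' @return a \code{list} of class \code{gaitProfile}.
#' @export
gaitProfile <- function(name, baseline = 1.1, oscAmp = 0.05, oscPeriod = 20,
                        arCoef = 0.3, noiseSd = 0.01, outlierRate = 0.02,
                        duration = 300) {
  stopifnot(baseline > 0, arCoef >= 0, arCoef < 1, noiseSd >= 0,
            outlierRate >= 0, outlierRate <= 1, duration > 0)
  structure(list(name = name, baseline = baseline, oscAmp = oscAmp,
                 oscPeriod = oscPeriod, arCoef = arCoef, noiseSd = noiseSd,
                 outlierRate = outlierRate, duration = duration),
            class = "gaitProfile")
}

#' Default synthetic profiles for the four study groups
#'
#' A healthy-control-like profile with a prominent low-noise quasi-periodic
#' rhythm, and three disease-like profiles with weaker oscillation,
#' stronger and more autocorrelated fluctuations, and slower baselines —
#' the broadband/bursty character reported for neuro-degenerative gait.
#'
#' @return named list of \code{\link{gaitProfile}} objects (HC, ALS, HD,
#'   PD).
#' @export
defaultProfiles <- function() {
  list(
    HC = gaitProfile("HC", baseline = 1.10, oscAmp = 0.05, oscPeriod = 20,
                     arCoef = 0.3, noiseSd = 0.01),
    ALS = gaitProfile("ALS", baseline = 1.35, oscAmp = 0.008, oscPeriod = 24,
                      arCoef = 0.75, noiseSd = 0.06),
    HD = gaitProfile("HD", baseline = 1.15, oscAmp = 0.01, oscPeriod = 18,
                     arCoef = 0.6, noiseSd = 0.05),
    PD = gaitProfile("PD", baseline = 1.15, oscAmp = 0.005, oscPeriod = 20,
                     arCoef = 0.7, noiseSd = 0.05)
  )
}

#' Generate one synthetic subject
#'
#' Draws a stride-interval series from a \code{\link{gaitProfile}}:
#' quasi-periodic baseline rhythm plus AR(1) noise, with each stride
#' independently replaced, at the profile's outlier rate, by a turn-around
#' spike of baseline + U(3, 6) * max(sigma, 0.05) seconds. Timestamps are
#' the cumulative stride times offset by a uniform start in [0, 2] s.
#' Values are clipped to stay positive. Deterministic given the seed.
#'
#' @param profile a \code{\link{gaitProfile}}.
#' @param seed integer seed.
#' @param subjectId identifier; default derived from profile name and seed.
#' @return a \linkS4class{StrideSeries}.
#' @export
generateSubject <- function(profile, seed, subjectId = NULL) {
  stopifnot(inherits(profile, "gaitProfile"))
  if (is.null(subjectId))
    subjectId <- sprintf("%s_s%d", profile$name, as.integer(seed))
  withSeed(seed, {
    n <- max(2L, round(profile$duration / profile$baseline))
    phi <- stats::runif(1, 0, 2 * pi)
    e <- as.numeric(stats::arima.sim(
      list(ar = if (profile$arCoef > 0) profile$arCoef else numeric(0)),
      n = n, sd = profile$noiseSd))
    if (profile$arCoef == 0) e <- stats::rnorm(n, sd = profile$noiseSd)
    x <- profile$baseline +
      profile$oscAmp * sin(2 * pi * seq_len(n) / profile$oscPeriod + phi) + e
    spike <- stats::runif(n) < profile$outlierRate
    if (any(spike)) {
      x[spike] <- profile$baseline +
        stats::runif(sum(spike), 3, 6) * max(profile$noiseSd, 0.05)
    }
    x <- pmax(x, 0.05)
    start <- stats::runif(1, 0, 2)
    StrideSeries(subjectId, profile$name, timestamps = start + cumsum(x),
                 values = x)
  })
}

#' Generate a synthetic cohort on disk
#'
#' Writes one whitespace-delimited subject file per subject (elapsed time,
#' left stride, right stride — the left column is the right one with a
#' small seeded jitter, so the dialect's column map is exercised) plus a
#' manifest readable by \code{\link{readCohort}}. Default group sizes match
#' the study cohort: 16 HC, 13 ALS, 20 HD, 15 PD.
#'
#' @param dir output directory (created if needed).
#' @param profiles named list of \code{\link{gaitProfile}}s.
#' @param counts named integer vector of subjects per group, aligned with
#'   \code{profiles}.
#' @param seed integer seed; per-subject seeds are derived from it.
#' @return path of the written manifest, invisibly.
#' @export
generateCohort <- function(dir,
                           profiles = defaultProfiles(),
                           counts = c(HC = 16L, ALS = 13L, HD = 20L,
                                      PD = 15L),
                           seed = 42) {
  stopifnot(all(names(counts) %in% names(profiles)), all(counts >= 1L))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  rows <- list()
  k <- 0L
  for (g in names(counts)) {
    for (i in seq_len(counts[[g]])) {
      k <- k + 1L
      subSeed <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
      id <- sprintf("%s%02d", tolower(g), i)
      series <- generateSubject(profiles[[g]], seed = subSeed,
                                subjectId = id)
      right <- strideValues(series)
      left <- withSeed(subSeed + 1L,
                       pmax(right + stats::rnorm(length(right), sd = 0.005),
                            0.05))
      fname <- paste0(id, ".ts")
      writeLines(sprintf("%.6f %.6f %.6f", strideTimes(series), left, right),
                 file.path(dir, fname))
      rows[[k]] <- data.frame(path = fname, subject_id = id, group = g)
    }
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
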
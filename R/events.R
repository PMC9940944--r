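# threshold-crossing event detector shared by accelerations/decelerations.
# A candidate needs >= coreSec seconds beyond baseline +/- 15 bpm; its
# extent is then grown outward while the signal stays beyond +/- 5 bpm of
# baseline, and overlapping extents are merged.
.detectExcursions <- function(x, rate, b, sign = -1, coreSec = 10) {
  y <- sign * (x - b)                      # positive in the excursion
  core <- !is.na(y) & y > 15
  r <- .runs(core)
  r <- r[(r$end - r$start + 1) / rate >= coreSec, , drop = FALSE]
  if (!nrow(r)) return(r)
  keepGoing <- !is.na(y) & y > 5
  for (i in seq_len(nrow(r))) {
    s <- r$start[i]
    while (s > 1L && keepGoing[s - 1L]) s <- s - 1L
    e <- r$end[i]
    while (e < length(y) && keepGoing[e + 1L]) e <- e + 1L
    r$start[i] <- s; r$end[i] <- e
  }
  r <- r[order(r$start), , drop = FALSE]
  merged <- r[1, , drop = FALSE]
  for (i in seq_len(nrow(r))[-1]) {
    if (r$start[i] <= merged$end[nrow(merged)] + 1L)
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], r$end[i])
    else merged <- rbind(merged, r[i, ])
  }
  merged
}

#' Detect accelerations
#'
#' Accelerations are excursions >= 15 bpm above baseline lasting >= 15 s
#' and < 10 min. Events lasting 2-10 min are flagged as prolonged
#' accelerations; excursions >= 10 min are dropped as candidate baseline
#' shifts.
#'
#' @param trace a \code{\linkS4class{CTGTrace}}.
#' @param baseline a \code{\linkS4class{BaselineEstimate}} or numeric bpm.
#' @return data.frame with one row per acceleration: \code{onset},
#'   \code{peakTime}, \code{end}, \code{rise} (bpm above baseline),
#'   \code{duration}, \code{onsetToPeak} (s), \code{prolonged}.
#' @export
detectAccelerations <- function(trace, baseline) {
  b <- if (is(baseline, "BaselineEstimate")) baseline@value else baseline
  x <- trace@fhr; rate <- trace@samplingRate
  r <- .detectExcursions(x, rate, b, sign = +1)
  out <- .emptyEventFrame()
  for (i in seq_len(nrow(r))) {
    idx <- r$start[i]:r$end[i]
    dur <- length(idx) / rate
    if (dur < 15 || dur >= 600) next
    pk <- idx[which.max(x[idx])]
    rise <- max(x[idx], na.rm = TRUE) - b
    if (rise < 15) next
    out <- rbind(out, data.frame(
      onset = (idx[1] - 1) / rate, peakTime = (pk - 1) / rate,
      end = idx[length(idx)] / rate, rise = rise, duration = dur,
      onsetToPeak = (pk - idx[1]) / rate, prolonged = dur >= 120))
  }
  out
}

#' Detect decelerations (untyped)
#'
#' Decelerations are excursions >= 15 bpm below baseline lasting >= 15 s.
#' The detection floor mirrors the shared definition across systems; typing
#' and severity grading are separate steps.
#'
#' @inheritParams detectAccelerations
#' @return data.frame with one row per deceleration: \code{onset},
#'   \code{nadirTime}, \code{end}, \code{depth} (bpm below baseline),
#'   \code{nadirAbsolute} (bpm), \code{duration}, \code{onsetToNadir} (s).
#' @export
detectDecelerations <- function(trace, baseline) {
  b <- if (is(baseline, "BaselineEstimate")) baseline@value else baseline
  x <- trace@fhr; rate <- trace@samplingRate
  r <- .detectExcursions(x, rate, b, sign = -1)
  out <- data.frame(onset = numeric(0), nadirTime = numeric(0),
                    end = numeric(0), depth = numeric(0),
                    nadirAbsolute = numeric(0), duration = numeric(0),
                    onsetToNadir = numeric(0))
  for (i in seq_len(nrow(r))) {
    idx <- r$start[i]:r$end[i]
    dur <- length(idx) / rate
    if (dur < 15) next
    depth <- b - min(x[idx], na.rm = TRUE)
    if (depth < 15) next
    # deep region: contiguous samples within tolerance of full depth
    # around the deepest sample. The nadir time is its midpoint (robust
    # for contraction-lag measurement on flat-bottomed events); the
    # onset-to-nadir time runs to its first sample (robust abruptness).
    y <- b - x[idx]
    tol <- 2 + 0.05 * depth
    dr <- .runs(!is.na(y) & y >= depth - tol)
    am <- which.max(y)
    dr <- dr[dr$start <= am & dr$end >= am, , drop = FALSE]
    ndFirst <- idx[dr$start[1]]
    ndMid <- idx[floor((dr$start[1] + dr$end[1]) / 2)]
    out <- rbind(out, data.frame(
      onset = (idx[1] - 1) / rate, nadirTime = (ndMid - 1) / rate,
      end = idx[length(idx)] / rate, depth = depth,
      nadirAbsolute = b - depth, duration = dur,
      onsetToNadir = (ndFirst - idx[1]) / rate))
  }
  out
}

# per-system duration threshold above which an event is prolonged
.prolongedThreshold <- function(system)
  switch(system, FIGO = 180, NICHD = 120, PARER = 120, RCOG = 60)

#' Type decelerations (early / variable / late / prolonged)
#'
#' An event is prolonged when its duration exceeds the system's threshold
#' (NICHD/PARER > 2 min, FIGO > 3 min; RCOG defines prolonged as an abrupt
#' decrease of >= 60 s, so under RCOG an event is prolonged when abrupt and
#' >= 60 s, or of any shape and > 3 min). Otherwise abrupt events
#' (onset-to-nadir < 30 s) are variable; gradual events are early when the
#' nadir is within 20 s of the nearest contraction peak and late when the
#' nadir trails the peak by more than 20 s (a nadir leading the peak by
#' more than 20 s is kept early: an early-onset periodic slowing). A
#' gradual event with no contraction peak within 120 s is typed variable
#' by convention and flagged \code{indeterminate}.
#'
#' @param decels data.frame from \code{\link{detectDecelerations}}.
#' @param contractions data.frame with \code{onset}, \code{peak},
#'   \code{end} columns.
#' @param system classification system identifier.
#' @return \code{decels} with added \code{lag} (nadir time minus nearest
#'   contraction peak, s), \code{indeterminate} and \code{type} columns.
#' @export
typeDecelerations <- function(decels, contractions, system = "FIGO") {
  system <- .matchSystem(system)
  n <- nrow(decels)
  decels$lag <- rep(NA_real_, n)
  decels$indeterminate <- rep(FALSE, n)
  decels$type <- rep(NA_character_, n)
  thr <- .prolongedThreshold(system)
  for (i in seq_len(n)) {
    dur <- decels$duration[i]
    abrupt <- decels$onsetToNadir[i] < 30
    if (!is.null(contractions) && nrow(contractions)) {
      dl <- decels$nadirTime[i] - contractions$peak
      decels$lag[i] <- dl[which.min(abs(dl))]
    }
    if (system == "RCOG") {
      if (dur > 180 || (abrupt && dur >= 60)) {
        decels$type[i] <- "prolonged"; next
      }
    } else if (dur > thr) {
      decels$type[i] <- "prolonged"; next
    }
    if (abrupt) { decels$type[i] <- "variable"; next }
    if (is.na(decels$lag[i]) || abs(decels$lag[i]) > 120) {
      decels$type[i] <- "variable"
      decels$indeterminate[i] <- TRUE
    } else if (decels$lag[i] > 20) decels$type[i] <- "late"
    else decels$type[i] <- "early"
  }
  decels
}

#' Grade deceleration severity
#'
#' Severity follows the five-tier (Parer) grading. Variable: severe when
#' the nadir is below 70 bpm for more than 60 s; moderate when the nadir is
#' below 70 bpm for 30-60 s or below 80 bpm for more than 60 s; otherwise
#' mild. Late: mild up to 15 bpm below baseline, moderate 16-44 bpm,
#' severe >= 45 bpm. Prolonged: severe below 70 bpm, moderate 70-80 bpm,
#' otherwise mild (the monotone reading: deeper is worse). Early events
#' are graded mild. Variables are additionally marked \code{atypical}
#' (used by RCOG) when lasting >= 60 s or dipping below 70 bpm.
#'
#' @param decels typed data.frame from \code{\link{typeDecelerations}}.
#' @param system classification system identifier (grading itself is
#'   system-independent; kept for interface symmetry).
#' @return \code{decels} with \code{severity} and \code{atypical} columns.
#' @export
gradeDecelerations <- function(decels, system = "PARER") {
  n <- nrow(decels)
  decels$severity <- rep(NA_character_, n)
  decels$atypical <- rep(FALSE, n)
  for (i in seq_len(n)) {
    type <- decels$type[i]
    nad <- decels$nadirAbsolute[i]
    dur <- decels$duration[i]
    depth <- decels$depth[i]
    decels$severity[i] <- switch(type,
      early = "mild",
      variable = {
        if (nad < 70 && dur > 60) "severe"
        else if ((nad < 70 && dur >= 30 && dur <= 60) ||
                 (nad < 80 && dur > 60)) "moderate"
        else "mild"
      },
      late = {
        if (depth >= 45) "severe"
        else if (depth > 15) "moderate"
        else "mild"
      },
      prolonged = {
        if (nad < 70) "severe"
        else if (nad <= 80) "moderate"
        else "mild"
      })
    if (type == "variable")
      decels$atypical[i] <- dur >= 60 || nad < 70
  }
  decels
}

# qualifying sinusoidal duration per system (minutes)
.sinusoidalQualifies <- function(minutes, system)
  switch(system,
         FIGO = minutes > 30, RCOG = minutes >= 10,
         NICHD = minutes > 20, PARER = minutes > 20)

#' Detect sinusoidal episodes
#'
#' A minute is sinusoidal when the dominant spectral component of the
#' baseline-detrended signal lies at 3-5 cycles/min, carries more than
#' half of the oscillatory power, the half-range amplitude is 4-16 bpm and
#' no acceleration overlaps the minute. Contiguous sinusoidal minutes form
#' episodes; the longest episode is compared with the system's qualifying
#' duration (FIGO > 30 min, RCOG >= 10 min, NICHD/PARER > 20 min).
#'
#' @param trace a \code{\linkS4class{CTGTrace}}.
#' @param baseline a \code{\linkS4class{BaselineEstimate}} or numeric bpm.
#' @param accelerations data.frame of detected accelerations or NULL.
#' @param system classification system identifier.
#' @return list with \code{minutes} (logical per whole minute),
#'   \code{segments} (data.frame \code{start}/\code{end} minutes,
#'   \code{frequency} cycles/min, \code{amplitude} bpm),
#'   \code{qualifyingMinutes} (longest episode) and \code{qualifies}.
#' @export
detectSinusoidal <- function(trace, baseline, accelerations = NULL,
                             system = "FIGO") {
  system <- .matchSystem(system)
  b <- if (is(baseline, "BaselineEstimate")) baseline@value else baseline
  x <- trace@fhr; rate <- trace@samplingRate
  perMin <- as.integer(round(60 * rate))
  nMin <- floor(length(x) / perMin)
  sinMin <- rep(FALSE, nMin)
  domF <- rep(NA_real_, nMin); halfAmp <- rep(NA_real_, nMin)
  for (m in seq_len(nMin)) {
    idx <- ((m - 1L) * perMin + 1L):(m * perMin)
    y <- x[idx] - b
    if (anyNA(y)) next
    sp <- Mod(stats::fft(y))^2
    kmax <- floor(perMin / 2)
    pw <- sp[2:(kmax + 1)]              # bin k = k cycles per minute
    if (sum(pw) <= 0) next
    k <- which.max(pw)
    amp2 <- (max(y) - min(y)) / 2
    domF[m] <- k; halfAmp[m] <- amp2
    inBand <- sum(pw[3:5]) / sum(pw)
    acc <- FALSE
    if (!is.null(accelerations) && nrow(accelerations)) {
      t0 <- (m - 1) * 60; t1 <- m * 60
      acc <- any(accelerations$onset < t1 & accelerations$end > t0)
    }
    sinMin[m] <- k >= 3 && k <= 5 && inBand > 0.5 &&
      amp2 >= 4 && amp2 <= 16 && !acc
  }
  r <- .runs(sinMin)
  segments <- data.frame(start = numeric(0), end = numeric(0),
                         frequency = numeric(0), amplitude = numeric(0))
  for (i in seq_len(nrow(r))) {
    mm <- r$start[i]:r$end[i]
    segments <- rbind(segments, data.frame(
      start = (r$start[i] - 1) * 60, end = r$end[i] * 60,
      frequency = mean(domF[mm]), amplitude = mean(halfAmp[mm])))
  }
  qm <- .maxRun(sinMin)
  list(minutes = sinMin, segments = segments,
       qualifyingMinutes = as.numeric(qm),
       qualifies = .sinusoidalQualifies(qm, system))
}

#' Assess deceleration repetitiveness
#'
#' A deceleration type is repetitive when it accompanies more than 50% of
#' the contractions in the window; a deceleration accompanies a
#' contraction when its nadir falls within the contraction extended by
#' 30 s either side.
#'
#' @param decels typed data.frame from \code{\link{typeDecelerations}}.
#' @param contractions data.frame with \code{onset}, \code{peak},
#'   \code{end}.
#' @return list with per-type fractions and logical flags
#'   \code{repetitiveEarly}, \code{repetitiveVariable},
#'   \code{repetitiveLate}, \code{repetitiveProlonged}. With zero
#'   contractions all flags are FALSE and a warning is emitted.
#' @export
assessRepetitiveness <- function(decels, contractions) {
  types <- c("early", "variable", "late", "prolonged")
  if (is.null(contractions) || !nrow(contractions)) {
    warning("no contractions in window: repetitiveness flags set to FALSE")
    fr <- stats::setNames(rep(NA_real_, 4), types)
  } else if (!nrow(decels)) {
    fr <- stats::setNames(rep(0, 4), types)
  } else {
    fr <- vapply(types, function(tp) {
      ev <- decels[decels$type == tp, , drop = FALSE]
      if (!nrow(ev)) return(0)
      mean(vapply(seq_len(nrow(contractions)), function(i)
        any(ev$nadirTime >= contractions$onset[i] - 30 &
            ev$nadirTime <= contractions$end[i] + 30), logical(1)))
    }, numeric(1))
  }
  flags <- !is.na(fr) & fr > 0.5
  list(fractions = fr,
       repetitiveEarly = unname(flags["early"]),
       repetitiveVariable = unname(flags["variable"]),
       repetitiveLate = unname(flags["late"]),
       repetitiveProlonged = unname(flags["prolonged"]))
}
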
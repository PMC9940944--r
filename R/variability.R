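# per-system variability bands: reduced floor for the summary class
.variabilityClass <- function(amplitude, system) {
  lowFloor <- if (system %in% c("FIGO", "RCOG")) 5 else 6
  if (!is.finite(amplitude)) return("normal")
  if (amplitude < 2) "absent"
  else if (amplitude < lowFloor) "reduced"
  else if (amplitude > 25) "increased"
  else "normal"
}

#' Compute the minute-scale variability profile
#'
#' Variability is the bandwidth amplitude (max minus min of the signal) in
#' non-overlapping 1-minute segments. Minutes overlapping a detected
#' acceleration or deceleration (padded by 15 s either side), overlapping a
#' qualifying sinusoidal episode, or with more than half their samples
#' missing are excluded. Excluded minutes do not interrupt a reduced- or
#' increased-variability episode: duration accounting runs over the
#' sequence of included minutes. The summary amplitude is the median over
#' included minutes and is classed under the system's bands (normal 5-25
#' bpm for FIGO/RCOG, 6-25 bpm for NICHD/PARER; absent < 2 bpm;
#' increased > 25 bpm).
#'
#' @param trace a \code{\linkS4class{CTGTrace}}.
#' @param baseline a \code{\linkS4class{BaselineEstimate}} or numeric bpm.
#' @param events data.frame with \code{onset}/\code{end} columns (seconds)
#'   of detected accelerations and decelerations, or NULL.
#' @param sinusoidalMinutes logical vector (one element per whole minute)
#'   marking minutes inside a qualifying sinusoidal episode, or NULL.
#' @param system classification system identifier.
#' @return a \code{\linkS4class{VariabilityProfile}}.
#' @export
computeVariability <- function(trace, baseline, events = NULL,
                               sinusoidalMinutes = NULL, system = "FIGO") {
  system <- .matchSystem(system)
  x <- trace@fhr
  rate <- trace@samplingRate
  perMin <- as.integer(round(60 * rate))
  nMin <- floor(length(x) / perMin)
  amp <- rep(NA_real_, nMin)
  excluded <- rep(FALSE, nMin)
  for (m in seq_len(nMin)) {
    idx <- ((m - 1L) * perMin + 1L):(m * perMin)
    xm <- x[idx]
    if (mean(is.na(xm)) > 0.5) { excluded[m] <- TRUE; next }
    amp[m] <- max(xm, na.rm = TRUE) - min(xm, na.rm = TRUE)
    t0 <- (m - 1) * 60; t1 <- m * 60
    if (!is.null(events) && nrow(events) &&
        any(events$onset - 15 < t1 & events$end + 15 > t0))
      excluded[m] <- TRUE
    if (!is.null(sinusoidalMinutes) && length(sinusoidalMinutes) >= m &&
        isTRUE(sinusoidalMinutes[m]))
      excluded[m] <- TRUE
  }
  inc <- !excluded & !is.na(amp)
  ai <- amp[inc]
  summary <- if (length(ai)) stats::median(ai) else NA_real_
  if (!length(ai))
    warning("no minute free of events/missing data; variability class ",
            "defaults to normal")
  new("VariabilityProfile",
      perMinute = data.frame(minute = seq_len(nMin) - 1L, amplitude = amp,
                             excluded = excluded),
      amplitude = if (is.na(summary)) 0 else summary,
      classification = .variabilityClass(summary, system),
      reducedMinutes = as.numeric(.maxRun(ai < 5)),
      increasedMinutes = as.numeric(.maxRun(ai > 25)),
      system = system)
}

setMethod("show", "VariabilityProfile", function(object) {
  cat(sprintf(
    "VariabilityProfile (%s): %.1f bpm [%s]; reduced %g min, increased %g min\n",
    object@system, object@amplitude, object@classification,
    object@reducedMinutes, object@increasedMinutes))
})
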
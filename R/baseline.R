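#' Estimate the FHR baseline
#'
#' Per 10-minute segment the baseline is the mean FHR after iteratively
#' excluding accelerative/decelerative excursions: starting from the
#' segment median, samples deviating >= 15 bpm from the provisional
#' baseline for >= 15 s in a row are excluded and the mean recomputed,
#' until stable or five iterations. Segment values are rounded to the
#' nearest 5 bpm for NICHD and PARER (those systems state 5-bpm rounding)
#' and reported at 0.1 bpm for FIGO and RCOG. The window baseline is the
#' usable-minutes-weighted modal 5-bpm band over segments; ties go to the
#' band covering more minutes, then to the lower band (conservative toward
#' bradycardia detection).
#'
#' @param trace a \code{\linkS4class{CTGTrace}} (gaps filled as desired;
#'   missing samples are simply excluded from means).
#' @param system one of \code{"FIGO"}, \code{"RCOG"}, \code{"NICHD"},
#'   \code{"PARER"}.
#' @param segmentMinutes segment length, default 10.
#' @return a \code{\linkS4class{BaselineEstimate}}. Segments with fewer
#'   than 2 usable minutes get \code{NA} (baseline indeterminate there).
#' @export
estimateBaseline <- function(trace, system = "FIGO", segmentMinutes = 10) {
  system <- .matchSystem(system)
  x <- trace@fhr
  rate <- trace@samplingRate
  segLen <- as.integer(round(segmentMinutes * 60 * rate))
  nSeg <- ceiling(length(x) / segLen)
  segs <- data.frame(start = numeric(nSeg), value = NA_real_,
                     usableMinutes = 0)
  for (i in seq_len(nSeg)) {
    idx <- ((i - 1L) * segLen + 1L):min(i * segLen, length(x))
    xi <- x[idx]
    usable <- sum(!is.na(xi)) / rate / 60
    segs$start[i] <- (idx[1] - 1) / rate
    segs$usableMinutes[i] <- usable
    if (usable < 2) next
    b <- stats::median(xi, na.rm = TRUE)
    for (it in 1:5) {
      dev <- !is.na(xi) & abs(xi - b) >= 15
      r <- .runs(dev)
      excl <- rep(FALSE, length(xi))
      if (nrow(r)) {
        r <- r[(r$end - r$start + 1) / rate >= 15, , drop = FALSE]
        pad <- as.integer(25 * rate)   # also drop the shallow event flanks
        for (j in seq_len(nrow(r)))
          excl[max(1L, r$start[j] - pad):
                 min(length(xi), r$end[j] + pad)] <- TRUE
      }
      nb <- mean(xi[!excl], na.rm = TRUE)
      if (!is.finite(nb)) break
      done <- abs(nb - b) < 0.5
      b <- nb
      if (done) break
    }
    segs$value[i] <- if (system %in% c("NICHD", "PARER")) .round5(b)
                     else .roundHalfUp(b, 1)
  }
  ok <- !is.na(segs$value)
  if (!any(ok))
    stop("baseline indeterminate: no segment has 2 usable minutes")
  band <- .round5(segs$value[ok])
  w <- tapply(segs$usableMinutes[ok], band, sum)
  best <- as.numeric(names(w)[w == max(w)])
  modal <- min(best)                       # tie -> lower band
  inBand <- ok & .round5(segs$value) == modal
  value <- if (system %in% c("NICHD", "PARER")) modal else
    .roundHalfUp(stats::weighted.mean(segs$value[inBand],
                                      segs$usableMinutes[inBand]), 1)
  new("BaselineEstimate", value = value,
      classification = classifyBaselineValue(value, system),
      segments = segs, system = system)
}

#' Classify a baseline value under a system's numeric bands
#'
#' FIGO and NICHD use bradycardia < 110 bpm, normal 110-160 bpm and
#' tachycardia > 160 bpm. RCOG splits off moderate bands (100-109 and
#' 161-180 bpm) with abnormal outside 100-180. PARER grades bradycardia as
#' mild (100-109), moderate (80-99) or severe (< 80 bpm), matching the
#' keys of its colour rule table.
#'
#' @param value baseline in bpm.
#' @param system classification system identifier.
#' @return character class label.
#' @export
classifyBaselineValue <- function(value, system = "FIGO") {
  system <- .matchSystem(system)
  stopifnot(is.finite(value))
  if (system %in% c("FIGO", "NICHD")) {
    if (value < 110) "bradycardia"
    else if (value <= 160) "normal"
    else "tachycardia"
  } else if (system == "RCOG") {
    if (value < 100) "bradycardia"
    else if (value < 110) "moderate_bradycardia"
    else if (value <= 160) "normal"
    else if (value <= 180) "moderate_tachycardia"
    else "tachycardia"
  } else {
    if (value < 80) "severe_bradycardia"
    else if (value < 100) "moderate_bradycardia"
    else if (value < 110) "mild_bradycardia"
    else if (value <= 160) "normal"
    else "tachycardia"
  }
}

setMethod("show", "BaselineEstimate", function(object) {
  cat(sprintf("BaselineEstimate (%s): %g bpm [%s], %d segment(s)\n",
              object@system, object@value, object@classification,
              nrow(object@segments)))
})
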
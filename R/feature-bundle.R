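#' Construct a FeatureBundle directly
#'
#' Builds a classification-ready bundle from pre-annotated features,
#' bypassing signal processing. Defaults describe an unremarkable normal
#' trace; override the fields of interest. The \code{decelerations}
#' data.frame must carry the typed/graded columns produced by
#' \code{\link{typeDecelerations}} and \code{\link{gradeDecelerations}}.
#'
#' @param system classification system the bundle is parameterised for.
#' @param baselineValue window baseline, bpm.
#' @param baselineClass baseline class; derived from \code{baselineValue}
#'   when NULL.
#' @param variabilityAmplitude summary bandwidth, bpm.
#' @param variabilityClass variability class; derived when NULL.
#' @param reducedMinutes,increasedMinutes longest reduced/increased
#'   episodes, minutes; derived from the class and window length when NULL.
#' @param reducedDuringDecelerations FIGO reduced-variability-within-
#'   deceleration flag.
#' @param accelerations,decelerations event inventories.
#' @param accelerationsPresent derived from \code{accelerations} when NULL.
#' @param sinusoidal,sinusoidalMinutes sinusoidal qualification.
#' @param repetitiveEarly,repetitiveVariable,repetitiveLate,repetitiveProlonged
#'   repetitiveness flags (> 50% of contractions).
#' @param lateProlongedSpanMinutes span of late+prolonged events; derived
#'   when NULL.
#' @param prolongedMaxDuration longest prolonged deceleration, s; derived
#'   when NULL.
#' @param contractionCount contractions in window.
#' @param missingFraction fraction of missing FHR signal.
#' @param windowMinutes window length, minutes.
#' @return a \code{\linkS4class{FeatureBundle}}.
#' @export
featureBundle <- function(system = "FIGO",
                          baselineValue = 140, baselineClass = NULL,
                          variabilityAmplitude = 10,
                          variabilityClass = NULL,
                          reducedMinutes = NULL, increasedMinutes = NULL,
                          reducedDuringDecelerations = FALSE,
                          accelerations = .emptyEventFrame(),
                          decelerations = .emptyDecelFrame(),
                          accelerationsPresent = NULL,
                          sinusoidal = FALSE, sinusoidalMinutes = 0,
                          repetitiveEarly = FALSE,
                          repetitiveVariable = FALSE,
                          repetitiveLate = FALSE,
                          repetitiveProlonged = FALSE,
                          lateProlongedSpanMinutes = NULL,
                          prolongedMaxDuration = NULL,
                          contractionCount = 10,
                          missingFraction = 0, windowMinutes = 60) {
  system <- .matchSystem(system)
  if (is.null(baselineClass))
    baselineClass <- classifyBaselineValue(baselineValue, system)
  if (is.null(variabilityClass))
    variabilityClass <- .variabilityClass(variabilityAmplitude, system)
  if (is.null(reducedMinutes))
    reducedMinutes <- if (variabilityAmplitude < 5) windowMinutes else 0
  if (is.null(increasedMinutes))
    increasedMinutes <- if (variabilityAmplitude > 25) windowMinutes else 0
  if (is.null(accelerationsPresent))
    accelerationsPresent <- nrow(accelerations) > 0
  lp <- decelerations[decelerations$type %in% c("late", "prolonged"), ,
                      drop = FALSE]
  if (is.null(lateProlongedSpanMinutes))
    lateProlongedSpanMinutes <-
      if (nrow(lp)) (max(lp$end) - min(lp$onset)) / 60 else 0
  if (is.null(prolongedMaxDuration)) {
    pr <- decelerations[decelerations$type == "prolonged", , drop = FALSE]
    prolongedMaxDuration <- if (nrow(pr)) max(pr$duration) else 0
  }
  new("FeatureBundle", system = system,
      baselineValue = as.numeric(baselineValue),
      baselineClass = baselineClass,
      variabilityAmplitude = as.numeric(variabilityAmplitude),
      variabilityClass = variabilityClass,
      reducedMinutes = as.numeric(reducedMinutes),
      increasedMinutes = as.numeric(increasedMinutes),
      reducedDuringDecelerations = reducedDuringDecelerations,
      accelerations = accelerations, decelerations = decelerations,
      accelerationsPresent = accelerationsPresent,
      sinusoidal = sinusoidal,
      sinusoidalMinutes = as.numeric(sinusoidalMinutes),
      repetitiveEarly = repetitiveEarly,
      repetitiveVariable = repetitiveVariable,
      repetitiveLate = repetitiveLate,
      repetitiveProlonged = repetitiveProlonged,
      lateProlongedSpanMinutes = as.numeric(lateProlongedSpanMinutes),
      prolongedMaxDuration = as.numeric(prolongedMaxDuration),
      contractionCount = as.numeric(contractionCount),
      missingFraction = as.numeric(missingFraction),
      windowMinutes = as.numeric(windowMinutes))
}

#' Extract all classification features from a signal window
#'
#' Runs the full extraction chain with the system's parameterisation:
#' contraction detection (unless supplied), baseline estimation,
#' deceleration detection + typing + grading, acceleration detection,
#' sinusoidal detection, variability profiling (excluding event minutes)
#' and repetitiveness assessment. Windows with more than 50% missing
#' signal after gap filling are refused (clinically unusable trace).
#'
#' @param trace a \code{\linkS4class{CTGTrace}} (the analysis window).
#' @param system classification system identifier.
#' @param contractions optional contraction data.frame; detected from the
#'   toco channel when NULL.
#' @param fillMaxGap longest signal-loss gap to interpolate, seconds.
#' @return a \code{\linkS4class{FeatureBundle}}.
#' @export
buildFeatureBundle <- function(trace, system = "FIGO",
                               contractions = NULL, fillMaxGap = 15) {
  system <- .matchSystem(system)
  mf <- missingFraction(trace)
  tr <- fillGaps(trace, fillMaxGap)
  if (missingFraction(tr) > 0.5)
    stop("signal unusable: more than 50% missing after gap filling")
  if (is.null(contractions)) contractions <- detectContractions(tr)
  bl <- estimateBaseline(tr, system)
  dec <- detectDecelerations(tr, bl)
  dec <- typeDecelerations(dec, contractions, system)
  dec <- gradeDecelerations(dec, system)
  acc <- detectAccelerations(tr, bl)
  sn <- detectSinusoidal(tr, bl, acc, system)
  sinMins <- if (sn$qualifies) sn$minutes else NULL
  ev <- rbind(data.frame(onset = acc$onset, end = acc$end),
              data.frame(onset = dec$onset, end = dec$end))
  vp <- computeVariability(tr, bl, ev, sinMins, system)
  rep <- assessRepetitiveness(dec, contractions)
  featureBundle(
    system = system,
    baselineValue = bl@value, baselineClass = bl@classification,
    variabilityAmplitude = vp@amplitude, variabilityClass = vp@classification,
    reducedMinutes = vp@reducedMinutes,
    increasedMinutes = vp@increasedMinutes,
    reducedDuringDecelerations = .reducedWithinDecels(tr, dec),
    accelerations = acc, decelerations = dec,
    sinusoidal = sn$qualifies, sinusoidalMinutes = sn$qualifyingMinutes,
    repetitiveEarly = rep$repetitiveEarly,
    repetitiveVariable = rep$repetitiveVariable,
    repetitiveLate = rep$repetitiveLate,
    repetitiveProlonged = rep$repetitiveProlonged,
    contractionCount = nrow(contractions),
    missingFraction = mf,
    windowMinutes = traceDuration(tr) / 60)
}

# FIGO reduced-variability clause inside long decelerations: bandwidth of
# the middle third of any deceleration > 3 min below 5 bpm
.reducedWithinDecels <- function(trace, decels) {
  long <- decels[decels$duration > 180, , drop = FALSE]
  if (!nrow(long)) return(FALSE)
  x <- trace@fhr; rate <- trace@samplingRate
  for (i in seq_len(nrow(long))) {
    t0 <- long$onset[i] + long$duration[i] / 3
    t1 <- long$end[i] - long$duration[i] / 3
    idx <- (floor(t0 * rate) + 1L):min(floor(t1 * rate), length(x))
    xm <- x[idx]
    if (all(is.na(xm))) next
    if (max(xm, na.rm = TRUE) - min(xm, na.rm = TRUE) < 5) return(TRUE)
  }
  FALSE
}

setMethod("show", "FeatureBundle", function(object) {
  cat(sprintf("FeatureBundle [%s], %.0f-min window\n", object@system,
              object@windowMinutes))
  cat(sprintf("  baseline %g bpm (%s); variability %.1f bpm (%s)\n",
              object@baselineValue, object@baselineClass,
              object@variabilityAmplitude, object@variabilityClass))
  dd <- object@decelerations
  cat(sprintf("  %d acceleration(s); %d deceleration(s)%s\n",
              nrow(object@accelerations), nrow(dd),
              if (nrow(dd)) paste0(" [", paste(
                sprintf("%s:%s", dd$type, dd$severity), collapse = ", "),
                "]") else ""))
  flags <- c(sinusoidal = object@sinusoidal,
             repetitiveLate = object@repetitiveLate,
             repetitiveVariable = object@repetitiveVariable,
             repetitiveProlonged = object@repetitiveProlonged)
  if (any(flags))
    cat("  flags:", paste(names(flags)[flags], collapse = ", "), "\n")
})

.BUNDLE_SCHEMA <- "ctgtier-bundle/1"

#' Serialise / restore a FeatureBundle as JSON
#'
#' @param bundle a \code{\linkS4class{FeatureBundle}}.
#' @param path optional output file; when NULL the JSON text is returned.
#' @return \code{bundleToJSON}: JSON text (or \code{path} invisibly);
#'   \code{bundleFromJSON}: a \code{FeatureBundle}.
#' @export
bundleToJSON <- function(bundle, path = NULL) {
  sl <- slotNames(bundle)
  lst <- stats::setNames(lapply(sl, function(s) slot(bundle, s)), sl)
  lst$schema <- .BUNDLE_SCHEMA
  txt <- jsonlite::toJSON(lst, dataframe = "columns", auto_unbox = TRUE,
                          digits = NA, pretty = TRUE, na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname bundleToJSON
#' @param json JSON text or a file path produced by \code{bundleToJSON}.
#' @export
bundleFromJSON <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  lst <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  if (!identical(lst$schema, .BUNDLE_SCHEMA))
    stop("unrecognised bundle schema: ", lst$schema %||% "<missing>")
  asFrame <- function(x, template) {
    if (is.null(x) || !length(x) || !length(x[[1]])) return(template)
    as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
  }
  featureBundle(
    system = lst$system, baselineValue = lst$baselineValue,
    baselineClass = lst$baselineClass,
    variabilityAmplitude = lst$variabilityAmplitude,
    variabilityClass = lst$variabilityClass,
    reducedMinutes = lst$reducedMinutes,
    increasedMinutes = lst$increasedMinutes,
    reducedDuringDecelerations = lst$reducedDuringDecelerations,
    accelerations = asFrame(lst$accelerations, .emptyEventFrame()),
    decelerations = asFrame(lst$decelerations, .emptyDecelFrame()),
    accelerationsPresent = lst$accelerationsPresent,
    sinusoidal = lst$sinusoidal,
    sinusoidalMinutes = lst$sinusoidalMinutes,
    repetitiveEarly = lst$repetitiveEarly,
    repetitiveVariable = lst$repetitiveVariable,
    repetitiveLate = lst$repetitiveLate,
    repetitiveProlonged = lst$repetitiveProlonged,
    lateProlongedSpanMinutes = lst$lateProlongedSpanMinutes,
    prolongedMaxDuration = lst$prolongedMaxDuration,
    contractionCount = lst$contractionCount,
    missingFraction = lst$missingFraction,
    windowMinutes = lst$windowMinutes)
}
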
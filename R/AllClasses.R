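#' @import methods
NULL

.SYSTEMS <- c("FIGO", "RCOG", "NICHD", "PARER")

.emptyEventFrame <- function() {
  data.frame(onset = numeric(0), peakTime = numeric(0), end = numeric(0),
             rise = numeric(0), duration = numeric(0),
             onsetToPeak = numeric(0), prolonged = logical(0))
}

.emptyDecelFrame <- function() {
  data.frame(onset = numeric(0), nadirTime = numeric(0), end = numeric(0),
             depth = numeric(0), nadirAbsolute = numeric(0),
             duration = numeric(0), onsetToNadir = numeric(0),
             lag = numeric(0), indeterminate = logical(0),
             type = character(0), severity = character(0),
             atypical = logical(0))
}

#' Paired cardiotocography signal window
#'
#' A \code{CTGTrace} holds a uniformly sampled fetal-heart-rate (FHR) channel
#' and its paired uterine-activity (toco) channel on a shared timebase.
#' Missing signal (signal loss) is carried as \code{NA}; non-missing FHR
#' samples are constrained to the physiologic guard rails 30-250 bpm.
#'
#' @slot fhr numeric vector of FHR samples in beats per minute; \code{NA}
#'   marks signal loss.
#' @slot toco numeric vector of uterine-activity samples (arbitrary units,
#'   non-negative), same length as \code{fhr}.
#' @slot samplingRate sampling rate in Hz (conventionally 4 Hz).
#' @slot startTime seconds between the start of the original recording and
#'   the first sample of this window. Event times reported by the feature
#'   extractors are relative to the window start (first sample = 0 s).
#' @export
setClass("CTGTrace",
         slots = c(fhr = "numeric", toco = "numeric",
                   samplingRate = "numeric", startTime = "numeric"))

setValidity("CTGTrace", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@toco) != length(object@fhr))
    msg <- c(msg, "fhr and toco must have the same length")
  f <- object@fhr[!is.na(object@fhr)]
  if (length(f) && (min(f) < 30 || max(f) > 250))
    msg <- c(msg, "non-missing FHR samples must lie in [30, 250] bpm")
  tc <- object@toco[!is.na(object@toco)]
  if (length(tc) && min(tc) < 0)
    msg <- c(msg, "toco samples must be non-negative")
  if (length(object@startTime) != 1L || !is.finite(object@startTime))
    msg <- c(msg, "startTime must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Per-window baseline estimate
#'
#' @slot value window-level baseline in bpm (rounded to the nearest 5 bpm
#'   for NICHD/PARER, reported at 0.1 bpm resolution for FIGO/RCOG).
#' @slot classification baseline class under the system's numeric bands.
#' @slot segments data.frame of per-10-minute segment estimates with the
#'   usable minutes behind each.
#' @slot system classification system identifier.
#' @export
setClass("BaselineEstimate",
         slots = c(value = "numeric", classification = "character",
                   segments = "data.frame", system = "character"))

#' Minute-scale variability profile
#'
#' @slot perMinute data.frame with one row per whole minute of the window:
#'   bandwidth amplitude (max minus min, bpm) and whether the minute was
#'   excluded from duration accounting (overlapping a detected event or a
#'   qualifying sinusoidal segment, or mostly missing).
#' @slot amplitude summary bandwidth amplitude (median over included
#'   minutes), bpm.
#' @slot classification one of \code{"absent"}, \code{"reduced"}, \code{"normal"},
#'   \code{"increased"} under the system's bands.
#' @slot reducedMinutes longest episode (minutes) with amplitude < 5 bpm.
#' @slot increasedMinutes longest episode (minutes) with amplitude > 25 bpm.
#' @slot system classification system identifier.
#' @export
setClass("VariabilityProfile",
         slots = c(perMinute = "data.frame", amplitude = "numeric",
                   classification = "character", reducedMinutes = "numeric",
                   increasedMinutes = "numeric", system = "character"))

#' Classification-ready feature summary of one CTG window
#'
#' A \code{FeatureBundle} is the complete, serialisable summary a
#' classification system consumes: the classifiers read nothing else.
#' Bundles are produced by \code{\link{buildFeatureBundle}} (from signals),
#' by \code{\link{generateTrace}} (ground truth alongside synthetic
#' signals), or directly via \code{\link{featureBundle}} for pre-annotated
#' input.
#'
#' @slot system classification system the bundle was parameterised for.
#' @slot baselineValue window baseline, bpm.
#' @slot baselineClass baseline class under the system's bands.
#' @slot variabilityAmplitude summary minute-scale bandwidth, bpm.
#' @slot variabilityClass absent / reduced / normal / increased.
#' @slot reducedMinutes,increasedMinutes longest reduced (< 5 bpm) and
#'   increased (> 25 bpm) variability episodes, minutes.
#' @slot reducedDuringDecelerations TRUE when variability inside a
#'   deceleration longer than 3 minutes is below 5 bpm.
#' @slot accelerations data.frame of detected accelerations.
#' @slot decelerations data.frame of detected decelerations, typed
#'   (early/variable/late/prolonged) and severity-graded.
#' @slot accelerationsPresent at least one qualifying acceleration.
#' @slot sinusoidal TRUE when a sinusoidal pattern meets the system's
#'   qualifying duration.
#' @slot sinusoidalMinutes longest sinusoidal episode, minutes.
#' @slot repetitiveEarly,repetitiveVariable,repetitiveLate,repetitiveProlonged
#'   TRUE when that deceleration type accompanies more than half of the
#'   contractions in the window.
#' @slot lateProlongedSpanMinutes minutes spanned from the first onset to
#'   the last end over late plus prolonged decelerations.
#' @slot prolongedMaxDuration longest prolonged deceleration, seconds.
#' @slot contractionCount number of contractions in the window.
#' @slot missingFraction fraction of FHR samples missing before gap
#'   filling.
#' @slot windowMinutes analysed window length, minutes.
#' @export
setClass("FeatureBundle",
         slots = c(system = "character",
                   baselineValue = "numeric", baselineClass = "character",
                   variabilityAmplitude = "numeric",
                   variabilityClass = "character",
                   reducedMinutes = "numeric", increasedMinutes = "numeric",
                   reducedDuringDecelerations = "logical",
                   accelerations = "data.frame",
                   decelerations = "data.frame",
                   accelerationsPresent = "logical",
                   sinusoidal = "logical", sinusoidalMinutes = "numeric",
                   repetitiveEarly = "logical",
                   repetitiveVariable = "logical",
                   repetitiveLate = "logical",
                   repetitiveProlonged = "logical",
                   lateProlongedSpanMinutes = "numeric",
                   prolongedMaxDuration = "numeric",
                   contractionCount = "numeric",
                   missingFraction = "numeric",
                   windowMinutes = "numeric"))

setValidity("FeatureBundle", function(object) {
  msg <- character(0)
  if (!(object@system %in% .SYSTEMS))
    msg <- c(msg, sprintf("unknown system '%s'", object@system))
  for (s in c("baselineValue", "variabilityAmplitude", "reducedMinutes",
              "increasedMinutes", "sinusoidalMinutes",
              "lateProlongedSpanMinutes", "prolongedMaxDuration",
              "contractionCount", "missingFraction", "windowMinutes"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      msg <- c(msg, sprintf("incomplete bundle: missing feature '%s'", s))
  need <- c("type", "severity", "duration", "depth", "nadirAbsolute")
  if (!all(need %in% names(object@decelerations)))
    msg <- c(msg, "deceleration inventory lacks typed/graded columns")
  if (length(msg)) msg else TRUE
})

#' One category assignment
#'
#' @slot system classification system identifier.
#' @slot label category label (e.g. \code{"suspicious"}, \code{"II"},
#'   \code{"orange"}).
#' @slot ordinal 0-based ordinal, 0 = most normal, increasing with
#'   abnormality.
#' @export
setClass("CTGCategory",
         slots = c(system = "character", label = "character",
                   ordinal = "integer"))

#' RCOG per-feature grades
#'
#' @slot baseline,variability,decelerations,accelerations each one of
#'   \code{"reassuring"}, \code{"nonreassuring"}, \code{"abnormal"} or
#'   \code{"uncertain"} (accelerations only).
#' @export
setClass("RcogFeatureGrades",
         slots = c(baseline = "character", variability = "character",
                   decelerations = "character", accelerations = "character"))

#' Case/control counts per ordered category
#'
#' @slot system classification system identifier.
#' @slot labels ordered category labels, most normal first.
#' @slot cases,controls non-negative integer counts per category.
#' @export
setClass("ContingencyTable",
         slots = c(system = "character", labels = "character",
                   cases = "numeric", controls = "numeric"))

setValidity("ContingencyTable", function(object) {
  msg <- character(0)
  k <- length(object@labels)
  if (anyDuplicated(object@labels))
    msg <- c(msg, "category labels must be unique")
  if (length(object@cases) != k || length(object@controls) != k)
    msg <- c(msg, "cases/controls must have one count per category")
  cc <- c(object@cases, object@controls)
  if (any(is.na(cc)) || any(cc < 0) || any(cc != round(cc)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Ordinal AUC result
#'
#' @slot system classification system identifier.
#' @slot auc tie-corrected Mann-Whitney area under the ROC curve.
#' @slot ciLow,ciHigh confidence bounds (NA when not requested).
#' @slot level confidence level.
#' @slot method CI method identifier.
#' @slot nCases,nControls group sizes.
#' @export
setClass("AUCResult",
         slots = c(system = "character", auc = "numeric",
                   ciLow = "numeric", ciHigh = "numeric", level = "numeric",
                   method = "character", nCases = "numeric",
                   nControls = "numeric"))

#' Fleiss kappa result
#'
#' @slot kappa chance-corrected multi-rater agreement; NA when undefined
#'   (expected agreement equal to 1).
#' @slot nSubjects,nRaters,nCategories problem dimensions.
#' @slot undefined TRUE when kappa is undefined.
#' @export
setClass("FleissKappaResult",
         slots = c(kappa = "numeric", nSubjects = "numeric",
                   nRaters = "numeric", nCategories = "numeric",
                   undefined = "logical"))
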
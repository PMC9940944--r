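.SYSTEM_LABELS <- list(
  FIGO = c("normal", "suspicious", "pathological"),
  RCOG = c("normal", "suspicious", "pathological"),
  NICHD = c("I", "II", "III"),
  PARER = c("green", "blue", "yellow", "orange", "red"))

#' Ordered category labels of a classification system
#'
#' @param system classification system identifier.
#' @return character vector, most normal category first.
#' @export
systemLabels <- function(system) .SYSTEM_LABELS[[.matchSystem(system)]]

.category <- function(system, label) {
  system <- .matchSystem(system)
  ord <- match(label, .SYSTEM_LABELS[[system]])
  if (is.na(ord)) stop("unknown category '", label, "' for ", system)
  new("CTGCategory", system = system, label = label,
      ordinal = ord - 1L)
}

#' @describeIn systemLabels category label accessor
#' @param x a \code{\linkS4class{CTGCategory}}
#' @export
categoryLabel <- function(x) x@label

#' @describeIn systemLabels 0-based category ordinal accessor
#' @export
categoryOrdinal <- function(x) x@ordinal

setMethod("show", "CTGCategory", function(object) {
  cat(sprintf("%s category: %s (ordinal %d)\n", object@system,
              object@label, object@ordinal))
})

.checkSystem <- function(bundle, system) {
  if (bundle@system != system)
    stop("bundle was parameterised for ", bundle@system, ", not ", system)
}

#' Classify a feature bundle under FIGO 2015
#'
#' Pathological: baseline below 100 bpm; reduced variability beyond 50 min
#' (or below 5 bpm for over 3 min inside a deceleration); increased
#' variability beyond 30 min; a qualifying sinusoidal pattern; repetitive
#' late or prolonged decelerations spanning more than 30 min (20 min when
#' variability is reduced); or a single prolonged deceleration over 5 min.
#' Normal: baseline 110-160 bpm, variability 5-25 bpm, no repetitive
#' decelerations and no sinusoidal pattern. Everything else is suspicious
#' (lacking at least one normal characteristic without pathological
#' features). When several pathological clauses fire the category is
#' unchanged: the most severe applicable category is returned.
#'
#' @param b a \code{\linkS4class{FeatureBundle}} built with the FIGO
#'   parameterisation.
#' @return a \code{\linkS4class{CTGCategory}}.
#' @export
classifyFIGO <- function(b) {
  .checkSystem(b, "FIGO")
  reducedVar <- b@variabilityClass %in% c("absent", "reduced")
  spanNeeded <- if (reducedVar) 20 else 30
  pathological <-
    b@baselineValue < 100 ||
    b@reducedMinutes > 50 ||
    b@reducedDuringDecelerations ||
    b@increasedMinutes > 30 ||
    b@sinusoidal ||
    ((b@repetitiveLate || b@repetitiveProlonged) &&
       b@lateProlongedSpanMinutes > spanNeeded) ||
    b@prolongedMaxDuration > 300
  if (pathological) return(.category("FIGO", "pathological"))
  anyRepetitive <- b@repetitiveEarly || b@repetitiveVariable ||
    b@repetitiveLate || b@repetitiveProlonged
  normal <- b@baselineValue >= 110 && b@baselineValue <= 160 &&
    b@variabilityClass == "normal" && !anyRepetitive && !b@sinusoidal
  .category("FIGO", if (normal) "normal" else "suspicious")
}

#' Classify a feature bundle under NICHD 2008
#'
#' Category III: absent variability together with recurrent late
#' decelerations, recurrent variable decelerations or bradycardia; or a
#' sinusoidal pattern. Recurrent is the same > 50%-of-contractions rule
#' as FIGO's repetitive. Category I: baseline 110-160 bpm, moderate
#' variability (6-25 bpm), no late, variable or prolonged decelerations
#' (early decelerations present or absent). Category II: everything else.
#'
#' @param b a \code{\linkS4class{FeatureBundle}} built with the NICHD
#'   parameterisation.
#' @return a \code{\linkS4class{CTGCategory}}.
#' @export
classifyNICHD <- function(b) {
  .checkSystem(b, "NICHD")
  absent <- b@variabilityClass == "absent"
  if ((absent && (b@repetitiveLate || b@repetitiveVariable ||
                  b@baselineValue < 110)) || b@sinusoidal)
    return(.category("NICHD", "III"))
  badTypes <- any(b@decelerations$type %in%
                    c("late", "variable", "prolonged"))
  if (b@baselineValue >= 110 && b@baselineValue <= 160 &&
      b@variabilityClass == "normal" && !badTypes)
    return(.category("NICHD", "I"))
  .category("NICHD", "II")
}

#' Grade the four RCOG features
#'
#' Baseline: 110-160 bpm reassuring; 100-109 or 161-180 nonreassuring;
#' below 100, above 180, or a sinusoidal pattern of at least 10 min
#' abnormal. Variability: at least 5 bpm reassuring; below 5 bpm for
#' 40-90 min nonreassuring, beyond 90 min abnormal; above 25 bpm for
#' 15-25 min nonreassuring, beyond 25 min abnormal. Decelerations: none
#' or early only reassuring; late decelerations, repetitive atypical
#' variables, or a prolonged deceleration over 3 min abnormal; other
#' variable or prolonged decelerations nonreassuring. Accelerations:
#' present reassuring; their absence with an otherwise normal trace is of
#' uncertain significance (treated as reassuring in the category count).
#'
#' @param b a \code{\linkS4class{FeatureBundle}} built with the RCOG
#'   parameterisation.
#' @return an \code{\linkS4class{RcogFeatureGrades}}.
#' @export
gradeRCOGFeatures <- function(b) {
  .checkSystem(b, "RCOG")
  v <- b@baselineValue
  baseGrade <-
    if (v < 100 || v > 180 || b@sinusoidal) "abnormal"
    else if (v < 110 || v > 160) "nonreassuring"
    else "reassuring"
  varGrade <- "reassuring"
  if (b@reducedMinutes > 40) varGrade <- "nonreassuring"
  if (b@increasedMinutes >= 15) varGrade <- "nonreassuring"
  if (b@reducedMinutes > 90 || b@increasedMinutes > 25)
    varGrade <- "abnormal"
  dd <- b@decelerations
  decGrade <- "reassuring"
  if (nrow(dd) && any(dd$type != "early")) decGrade <- "nonreassuring"
  if (any(dd$type == "late") ||
      (b@repetitiveVariable && any(dd$type == "variable" & dd$atypical)) ||
      any(dd$type == "prolonged" & dd$duration > 180))
    decGrade <- "abnormal"
  accGrade <- if (b@accelerationsPresent) "reassuring" else "uncertain"
  new("RcogFeatureGrades", baseline = baseGrade, variability = varGrade,
      decelerations = decGrade, accelerations = accGrade)
}

#' Classify under RCOG 2001
#'
#' Pathological: at least one abnormal feature, or two or more
#' nonreassuring features. Suspicious: exactly one nonreassuring feature,
#' none abnormal. Normal: all four features reassuring (absent
#' accelerations with an otherwise normal trace count as reassuring).
#'
#' @param grades an \code{\linkS4class{RcogFeatureGrades}} or a
#'   \code{\linkS4class{FeatureBundle}} (graded first).
#' @return a \code{\linkS4class{CTGCategory}}.
#' @export
classifyRCOG <- function(grades) {
  if (is(grades, "FeatureBundle")) grades <- gradeRCOGFeatures(grades)
  g <- c(grades@baseline, grades@variability, grades@decelerations,
         grades@accelerations)
  nAb <- sum(g == "abnormal")
  nNr <- sum(g == "nonreassuring")
  label <- if (nAb >= 1 || nNr >= 2) "pathological"
           else if (nNr == 1) "suspicious"
           else "normal"
  .category("RCOG", label)
}

#' Classify under the Parer-Ikeda five-tier system
#'
#' The colour is the most severe cell of the rule table over the bundle's
#' decelerations (plus the no-deceleration cell), keyed by variability
#' class (moderate/minimal/absent/marked), baseline class and
#' \code{type:severity}. A qualifying sinusoidal pattern (over 20 min)
#' forces red. The rule table is validated (totality and severity
#' monotonicity) unless pre-validated.
#'
#' @param b a \code{\linkS4class{FeatureBundle}} built with the PARER
#'   parameterisation.
#' @param rules rule table from \code{\link{parerRuleTable}}.
#' @param validate re-validate the table before use.
#' @return a \code{\linkS4class{CTGCategory}} with an \code{audit}
#'   attribute listing the cells that fired and their provenance notes.
#' @export
classifyParer <- function(b, rules = parerRuleTable(validate = FALSE),
                          validate = TRUE) {
  .checkSystem(b, "PARER")
  if (validate) validateParerRules(rules)
  varKey <- switch(b@variabilityClass, absent = "absent",
                   reduced = "minimal", increased = "marked", "moderate")
  baseKey <- b@baselineClass
  dd <- b@decelerations
  keys <- "none"
  if (nrow(dd))
    keys <- c(keys, ifelse(dd$type == "early", "early",
                           paste0(dd$type, ":", dd$severity)))
  rows <- match(paste(varKey, baseKey, keys),
                with(rules, paste(variability, baseline, deceleration)))
  if (anyNA(rows))
    stop("rule table has no cell for ",
         paste(varKey, baseKey, keys[which(is.na(rows))[1]]))
  ords <- .parerColourOrdinal(rules$colour[rows])
  best <- rows[which.max(ords)]
  label <- rules$colour[best]
  audit <- rules[best, , drop = FALSE]
  if (b@sinusoidal) {
    label <- "red"
    audit <- data.frame(variability = varKey, baseline = baseKey,
                        deceleration = "sinusoidal", colour = "red",
                        note = "sinusoidal pattern forces red")
  }
  out <- .category("PARER", label)
  attr(out, "audit") <- audit
  out
}

#' Classify a signal window under all four systems
#'
#' Builds the four per-system feature bundles and returns the four
#' categories together with the bundles (audit trail).
#'
#' @param trace a \code{\linkS4class{CTGTrace}} (the analysis window).
#' @param contractions optional contraction data.frame; detected from the
#'   toco channel when NULL.
#' @param rules Parer rule table.
#' @return list with \code{categories} (named list of
#'   \code{CTGCategory}) and \code{bundles} (named list of
#'   \code{FeatureBundle}).
#' @export
classifyAll <- function(trace, contractions = NULL,
                        rules = parerRuleTable(validate = FALSE)) {
  validateParerRules(rules)
  if (is.null(contractions))
    contractions <- detectContractions(fillGaps(trace, 15))
  bundles <- lapply(stats::setNames(.SYSTEMS, .SYSTEMS), function(s)
    buildFeatureBundle(trace, s, contractions = contractions))
  categories <- list(
    FIGO = classifyFIGO(bundles$FIGO),
    RCOG = classifyRCOG(bundles$RCOG),
    NICHD = classifyNICHD(bundles$NICHD),
    PARER = classifyParer(bundles$PARER, rules, validate = FALSE))
  list(categories = categories, bundles = bundles)
}

#' Apply a system's rules to a (ground-truth or pre-annotated) bundle
#'
#' Dispatch helper: routes a bundle to the classifier matching its
#' \code{system} slot.
#'
#' @param b a \code{\linkS4class{FeatureBundle}}.
#' @param rules Parer rule table (used only for PARER bundles).
#' @return a \code{\linkS4class{CTGCategory}}.
#' @export
classifyBundle <- function(b, rules = parerRuleTable(validate = FALSE)) {
  switch(b@system,
         FIGO = classifyFIGO(b),
         RCOG = classifyRCOG(b),
         NICHD = classifyNICHD(b),
         PARER = classifyParer(b, rules, validate = FALSE))
}
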
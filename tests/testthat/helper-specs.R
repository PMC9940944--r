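# Shorthand for building trace specs and synthetic feature bundles.

dz <- function(type, depth, duration, lag = 0, contractions = NULL,
               at = NULL) {
  out <- list(type = type, depth = depth, duration = duration, lag = lag)
  if (!is.null(contractions)) out$contractions <- contractions
  if (!is.null(at)) out$at <- at
  out
}

az <- function(rise, duration, at) list(rise = rise, duration = duration,
                                        at = at)

# 50 unambiguous trace specs spanning all deceleration types/severities
# and baseline/variability classes; deterministic seeds
roundTripSpecs <- function(baseSeed = 100) {
  sp <- list()
  add <- function(...) {
    i <- length(sp) + 1
    sp[[i]] <<- traceSpec(..., seed = baseSeed + i)
  }
  # baselines x variability, event-free
  add(baseline = 140, variabilityAmplitude = 10)
  add(baseline = 140, variabilityAmplitude = 3)
  add(baseline = 140, variabilityAmplitude = 1)
  add(baseline = 140, variabilityAmplitude = 35)
  add(baseline = 170, variabilityAmplitude = 10)
  add(baseline = 170, variabilityAmplitude = 3)
  add(baseline = 170, variabilityAmplitude = 1)
  add(baseline = 105, variabilityAmplitude = 10)
  add(baseline = 105, variabilityAmplitude = 3)
  add(baseline = 90, variabilityAmplitude = 10)
  add(baseline = 90, variabilityAmplitude = 1)
  add(baseline = 75, variabilityAmplitude = 10)
  # early decelerations (gradual, on the contraction peak)
  add(baseline = 140, decelerations = list(dz("early", 30, 90,
                                              contractions = 1:16)))
  add(baseline = 140, decelerations = list(dz("early", 30, 90,
                                              contractions = c(1, 5, 9))))
  add(baseline = 170, decelerations = list(dz("early", 30, 90,
                                              contractions = 1:12)))
  # variable decelerations: mild / moderate / severe
  add(baseline = 140, decelerations = list(dz("variable", 30, 45,
                                              contractions = 1:14)))
  add(baseline = 140, decelerations = list(dz("variable", 30, 45,
                                              contractions = c(2, 6, 10))))
  add(baseline = 140, decelerations = list(dz("variable", 75, 45,
                                              contractions = 1:14)))
  add(baseline = 140, decelerations = list(dz("variable", 75, 90,
                                              contractions = 1:12)))
  add(baseline = 140, variabilityAmplitude = 3,
      decelerations = list(dz("variable", 75, 45, contractions = 1:14)))
  add(baseline = 140, variabilityAmplitude = 1,
      decelerations = list(dz("variable", 30, 45, contractions = 1:14)))
  add(baseline = 170, decelerations = list(dz("variable", 105, 45,
                                              contractions = 1:12)))
  add(baseline = 105, decelerations = list(dz("variable", 30, 45,
                                              contractions = 1:12)))
  add(baseline = 140, decelerations = list(dz("variable", 75, 45,
                                              at = c(400, 1000, 1600))))
  # late decelerations (gradual, nadir 40 s after the peak)
  add(baseline = 140, decelerations = list(dz("late", 30, 90, lag = 40,
                                              contractions = 1:16)))
  add(baseline = 140, decelerations = list(dz("late", 50, 90, lag = 40,
                                              contractions = 1:16)))
  add(baseline = 140, variabilityAmplitude = 3,
      decelerations = list(dz("late", 30, 90, lag = 40,
                              contractions = 1:16)))
  add(baseline = 140, variabilityAmplitude = 1,
      decelerations = list(dz("late", 30, 90, lag = 40,
                              contractions = 1:16)))
  add(baseline = 170, decelerations = list(dz("late", 30, 90, lag = 40,
                                              contractions = 1:14)))
  add(baseline = 105, decelerations = list(dz("late", 50, 90, lag = 40,
                                              contractions = 1:14)))
  add(baseline = 140, decelerations = list(dz("late", 30, 90, lag = 40,
                                              contractions = c(1, 4, 7, 10))))
  # prolonged decelerations (2-3 min, 3-5 min, > 5 min; nadir grades)
  add(baseline = 140, decelerations = list(dz("prolonged", 75, 150,
                                              at = 900)))
  add(baseline = 140, decelerations = list(dz("prolonged", 65, 150,
                                              at = 900)))
  add(baseline = 140, decelerations = list(dz("prolonged", 40, 250,
                                              at = 900)))
  add(baseline = 140, decelerations = list(dz("prolonged", 40, 360,
                                              at = 900)))
  add(baseline = 170, variabilityAmplitude = 3,
      decelerations = list(dz("prolonged", 75, 150, at = 1200)))
  add(baseline = 105, decelerations = list(dz("prolonged", 40, 150,
                                              at = 1200)))
  # combinations
  add(baseline = 140, decelerations = list(
    dz("late", 30, 90, lag = 40, contractions = 1:16),
    dz("variable", 30, 45, contractions = 17:20)))
  add(baseline = 140, variabilityAmplitude = 1, decelerations = list(
    dz("variable", 75, 45, contractions = 1:14),
    dz("prolonged", 75, 150, at = 3000)))
  add(baseline = 90, variabilityAmplitude = 1,
      decelerations = list(dz("late", 30, 90, lag = 40,
                              contractions = 1:14)))
  add(baseline = 140, decelerations = list(dz("variable", 30, 45,
                                              contractions = 1:14)),
      accelerations = list(az(20, 30, 2525), az(20, 30, 3235)))
  add(baseline = 75, variabilityAmplitude = 3)
  add(baseline = 105, variabilityAmplitude = 3,
      decelerations = list(dz("variable", 60, 45, contractions = 1:12)))
  # sinusoidal episodes
  add(baseline = 140, sinusoidal = list(amplitude = 8, frequency = 4,
                                        durationMinutes = 40,
                                        startMinute = 5))
  add(baseline = 140, sinusoidal = list(amplitude = 8, frequency = 4,
                                        durationMinutes = 15,
                                        startMinute = 10))
  add(baseline = 140, sinusoidal = list(amplitude = 12, frequency = 3,
                                        durationMinutes = 25,
                                        startMinute = 5))
  add(baseline = 170, sinusoidal = list(amplitude = 8, frequency = 5,
                                        durationMinutes = 40,
                                        startMinute = 5))
  # signal-loss gaps
  add(baseline = 140, gaps = list(c(600, 10), c(1200, 8)))
  add(baseline = 140, decelerations = list(dz("late", 30, 90, lag = 40,
                                              contractions = 1:16)),
      gaps = list(c(1047, 60)))
  add(baseline = 140, decelerations = list(dz("variable", 75, 45,
                                              contractions = 1:14)),
      gaps = list(c(1047, 10), c(2000, 5)))
  stopifnot(length(sp) == 50)
  sp
}

# --- synthetic bundles on ordinal feature scales (monotonicity tests) ---

mkDecelRow <- function(type, severity, onset, duration,
                       nadirAbsolute = 110, atypical = FALSE) {
  data.frame(onset = onset, nadirTime = onset + duration / 2,
             end = onset + duration,
             depth = 140 - nadirAbsolute, nadirAbsolute = nadirAbsolute,
             duration = duration, onsetToNadir = duration / 2,
             lag = 0, indeterminate = FALSE, type = type,
             severity = severity, atypical = atypical)
}

# cumulative deceleration burden levels 0..6 (cached: the levels are
# static and rebuilt bundles dominate test runtime otherwise)
.decelLevelCache <- new.env(parent = emptyenv())
decelLevel <- function(level) {
  key <- as.character(level)
  if (!is.null(.decelLevelCache[[key]])) return(.decelLevelCache[[key]])
  .decelLevelCache[[key]] <- .decelLevelBuild(level)
  .decelLevelCache[[key]]
}
.decelLevelBuild <- function(level) {
  ev <- ctgtier:::.emptyDecelFrame()
  flags <- list(repetitiveEarly = FALSE, repetitiveVariable = FALSE,
                repetitiveLate = FALSE, repetitiveProlonged = FALSE)
  if (level >= 1)
    ev <- rbind(ev, mkDecelRow("early", "mild", c(100, 400, 700, 1000), 60))
  if (level >= 2)
    ev <- rbind(ev, mkDecelRow("variable", "mild", c(1300, 1600, 1900), 45))
  if (level >= 3) flags$repetitiveVariable <- TRUE
  if (level >= 4)
    ev <- rbind(ev, mkDecelRow("variable", "moderate", c(2200, 2500), 50,
                               nadirAbsolute = 65, atypical = TRUE))
  if (level >= 5) {
    ev <- rbind(ev, mkDecelRow("late", "moderate",
                               seq(2800, 5500, by = 300), 90))
    flags$repetitiveLate <- TRUE
  }
  if (level >= 6)
    ev <- rbind(ev, mkDecelRow("prolonged", "moderate", 6000, 360,
                               nadirAbsolute = 75))
  c(list(decelerations = ev), flags)
}

.BASE_LEVELS <- list(low = c(140, 105, 90), high = c(140, 170, 190))
.VAR_LEVELS <- list(list(amp = 10, red = 0), list(amp = 3, red = 45),
                    list(amp = 3, red = 60), list(amp = 3, red = 95),
                    list(amp = 1, red = 95))

# bundle at ordinal feature levels; windowMinutes 120 so long reduced-
# variability episodes are expressible
gradedBundle <- function(system, side, baseLevel, varLevel, decLevel) {
  key <- paste(system, side, baseLevel, varLevel, decLevel)
  if (!is.null(.gradedBundleCache[[key]])) return(.gradedBundleCache[[key]])
  .gradedBundleCache[[key]] <- .gradedBundleBuild(system, side, baseLevel,
                                                  varLevel, decLevel)
  .gradedBundleCache[[key]]
}
.gradedBundleCache <- new.env(parent = emptyenv())
.gradedBundleBuild <- function(system, side, baseLevel, varLevel,
                               decLevel) {
  vl <- .VAR_LEVELS[[varLevel + 1]]
  dl <- decelLevel(decLevel)
  featureBundle(
    system = system,
    baselineValue = .BASE_LEVELS[[side]][baseLevel + 1],
    variabilityAmplitude = vl$amp, reducedMinutes = vl$red,
    increasedMinutes = 0,
    decelerations = dl$decelerations,
    repetitiveEarly = dl$repetitiveEarly,
    repetitiveVariable = dl$repetitiveVariable,
    repetitiveLate = dl$repetitiveLate,
    repetitiveProlonged = dl$repetitiveProlonged,
    contractionCount = 40, windowMinutes = 120)
}
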
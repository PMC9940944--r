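#' Specify a synthetic CTG trace
#'
#' A \code{traceSpec} captures the ground truth a synthetic window is
#' generated from: a baseline level, a band-limited variability carrier
#' with an exact per-minute peak-to-trough amplitude, contraction-locked
#' decelerations of given type/depth/duration/lag, accelerations,
#' an optional sinusoidal episode and signal-loss gaps. Generation is
#' deterministic given \code{seed}.
#'
#' Deceleration specs are lists with fields:
#' \itemize{
#'   \item \code{type}: \code{"early"}, \code{"late"}, \code{"variable"}
#'     or \code{"prolonged"};
#'   \item \code{depth} (bpm below baseline), \code{duration} (s);
#'   \item \code{lag} (s, nadir minus contraction peak; early/late);
#'   \item either \code{contractions} (indices of contractions carrying
#'     the event) or \code{at} (centre times in s, for events not locked
#'     to a contraction).
#' }
#' Gradual shapes (early/late) are symmetric triangles, so the
#' onset-to-nadir time is \code{duration/2} and gradual events need
#' \code{duration >= 70} s to stay unambiguously gradual; variables are
#' U-shaped with a 10-s drop; prolonged events are U-shaped with 20-s
#' ramps. The variability carrier is attenuated to 20% inside events
#' (decelerations and accelerations carry reduced internal variability).
#'
#' @param durationMinutes window length, 30-60 min.
#' @param baseline baseline FHR, bpm.
#' @param variabilityAmplitude per-minute peak-to-trough bandwidth, bpm.
#' @param variabilityBand frequency band of the carrier, cycles/min;
#'   kept above the 3-5 cycles/min sinusoidal band by default.
#' @param contractionInterval,contractionDuration uterine contraction
#'   spacing and length, s.
#' @param decelerations,accelerations lists of event specs
#'   (accelerations: \code{rise}, \code{duration}, \code{at}).
#' @param sinusoidal NULL or list(\code{amplitude} half-range bpm,
#'   \code{frequency} cycles/min, \code{durationMinutes},
#'   \code{startMinute}).
#' @param gaps list of \code{c(at, length)} signal-loss gaps, s.
#' @param noiseSD additive white-noise SD, bpm.
#' @param seed RNG seed.
#' @return validated spec of class \code{ctgTraceSpec}.
#' @export
traceSpec <- function(durationMinutes = 60, baseline = 140,
                      variabilityAmplitude = 10,
                      variabilityBand = c(6, 18),
                      contractionInterval = 180, contractionDuration = 70,
                      decelerations = list(), accelerations = list(),
                      sinusoidal = NULL, gaps = list(), noiseSD = 0,
                      seed = 1) {
  spec <- list(durationMinutes = durationMinutes, baseline = baseline,
               variabilityAmplitude = variabilityAmplitude,
               variabilityBand = variabilityBand,
               contractionInterval = contractionInterval,
               contractionDuration = contractionDuration,
               decelerations = decelerations,
               accelerations = accelerations,
               sinusoidal = sinusoidal, gaps = gaps, noiseSD = noiseSD,
               seed = seed)
  class(spec) <- "ctgTraceSpec"
  stopifnot(durationMinutes >= 30, durationMinutes <= 60,
            baseline >= 60, baseline <= 200,
            variabilityAmplitude >= 0,
            length(variabilityBand) == 2, variabilityBand[1] > 0,
            noiseSD >= 0)
  for (d in decelerations) {
    stopifnot(d$type %in% c("early", "late", "variable", "prolonged"),
              d$depth > 0, d$duration >= 15)
    if (baseline - d$depth < 30)
      stop("deceleration depth ", d$depth, " violates the 30 bpm floor")
    if (d$type %in% c("early", "late") && d$duration < 70)
      stop("gradual decelerations need duration >= 70 s")
    if (d$type == "prolonged" && d$duration <= 120)
      stop("prolonged deceleration specs need duration > 120 s")
  }
  if (!is.null(sinusoidal))
    stopifnot(sinusoidal$frequency >= 3, sinusoidal$frequency <= 5,
              sinusoidal$amplitude >= 5, sinusoidal$amplitude <= 15)
  spec
}

# contraction grid of a spec (onset/peak/end, s)
.specContractions <- function(spec) {
  total <- spec$durationMinutes * 60
  onsets <- seq(30, total - spec$contractionDuration - 30,
                by = spec$contractionInterval)
  data.frame(onset = onsets,
             peak = onsets + spec$contractionDuration / 2,
             end = onsets + spec$contractionDuration)
}

# realised event instances (times resolved against the contraction grid)
.specEvents <- function(spec) {
  ctr <- .specContractions(spec)
  dec <- data.frame(onset = numeric(0), nadirTime = numeric(0),
                    end = numeric(0), depth = numeric(0),
                    nadirAbsolute = numeric(0), duration = numeric(0),
                    onsetToNadir = numeric(0))
  for (d in spec$decelerations) {
    nadirs <- if (!is.null(d$contractions)) {
      if (any(d$contractions > nrow(ctr)))
        stop("deceleration references contraction beyond the window")
      ctr$peak[d$contractions] + (d$lag %||% 0)
    } else d$at
    o2n <- switch(d$type, early = , late = d$duration / 2,
                  variable = 10, prolonged = 20)
    dec <- rbind(dec, data.frame(
      onset = nadirs - o2n, nadirTime = nadirs,
      end = nadirs - o2n + d$duration, depth = d$depth,
      nadirAbsolute = spec$baseline - d$depth, duration = d$duration,
      onsetToNadir = o2n))
  }
  acc <- data.frame(onset = numeric(0), peakTime = numeric(0),
                    end = numeric(0), rise = numeric(0),
                    duration = numeric(0), onsetToPeak = numeric(0),
                    prolonged = logical(0))
  for (a in spec$accelerations)
    acc <- rbind(acc, data.frame(
      onset = a$at - a$duration / 2, peakTime = a$at,
      end = a$at + a$duration / 2, rise = a$rise, duration = a$duration,
      onsetToPeak = 10, prolonged = a$duration >= 120))
  total <- spec$durationMinutes * 60
  iv <- rbind(dec[, c("onset", "end")], acc[, c("onset", "end")])
  if (nrow(iv)) {
    if (min(iv$onset) < 0 || max(iv$end) > total)
      stop("event extends beyond the window")
    iv <- iv[order(iv$onset), ]
    if (nrow(iv) > 1 &&
        any(iv$onset[-1] < iv$end[-nrow(iv)] + 10))
      stop("infeasible packing: events overlap or are closer than 10 s")
  }
  if (!is.null(spec$sinusoidal)) {
    s0 <- (spec$sinusoidal$startMinute %||% 0) * 60
    s1 <- s0 + spec$sinusoidal$durationMinutes * 60
    if (s1 > total) stop("sinusoidal episode extends beyond the window")
    if (nrow(iv) && any(iv$onset < s1 & iv$end > s0))
      stop("infeasible packing: events overlap the sinusoidal episode")
  }
  list(decelerations = dec, accelerations = acc, contractions = ctr)
}

# band-limited noise carrier with exact per-minute peak-to-trough span
.carrier <- function(n, rate, band, amplitude) {
  if (amplitude <= 0) return(rep(0, n))
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  cyc <- (seq_len(n) - 1) * rate * 60 / n            # cycles/min, 0..rate*60
  cyc <- pmin(cyc, rate * 60 - cyc)                  # two-sided
  mask <- cyc >= band[1] & cyc <= band[2]
  x <- Re(stats::fft(f * mask, inverse = TRUE)) / n
  perMin <- as.integer(round(60 * rate))
  for (m in seq_len(ceiling(n / perMin))) {
    idx <- ((m - 1L) * perMin + 1L):min(m * perMin, n)
    span <- max(x[idx]) - min(x[idx])
    if (span > 0) {
      seg <- x[idx] * amplitude / span
      x[idx] <- seg - (max(seg) + min(seg)) / 2 + 0  # centre on 0
    }
  }
  x
}

.decelShape <- function(t, ev) {
  # negative contribution of one deceleration at times t
  y <- numeric(length(t))
  if (ev$onsetToNadir >= 30) {                       # gradual triangle
    up <- ev$duration - ev$onsetToNadir
    inDown <- t >= ev$onset & t < ev$nadirTime
    inUp <- t >= ev$nadirTime & t < ev$end
    y[inDown] <- -ev$depth * (t[inDown] - ev$onset) / ev$onsetToNadir
    y[inUp] <- -ev$depth * (ev$end - t[inUp]) / up
  } else {                                           # U: ramp, plateau, ramp
    ramp <- ev$onsetToNadir
    inDown <- t >= ev$onset & t < ev$onset + ramp
    inFlat <- t >= ev$onset + ramp & t < ev$end - ramp
    inUp <- t >= ev$end - ramp & t < ev$end
    y[inDown] <- -ev$depth * (t[inDown] - ev$onset) / ramp
    y[inFlat] <- -ev$depth
    y[inUp] <- -ev$depth * (ev$end - t[inUp]) / ramp
  }
  y
}

#' Generate a synthetic CTG window with ground truth
#'
#' Renders the spec as paired FHR/toco signals (4 Hz) and derives, for
#' each classification system, the ground-truth
#' \code{\linkS4class{FeatureBundle}} implied by the spec (events typed
#' and graded with the same shared rules the extractors use, so the
#' bundle states exactly what a perfect extractor should report).
#'
#' @param spec a \code{\link{traceSpec}}.
#' @return list with \code{trace} (\code{CTGTrace}), \code{contractions}
#'   (data.frame), \code{truth} (named list of per-system
#'   \code{FeatureBundle}s) and \code{spec}.
#' @export
generateTrace <- function(spec) {
  stopifnot(inherits(spec, "ctgTraceSpec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  rate <- 4
  n <- as.integer(spec$durationMinutes * 60 * rate)
  t <- (seq_len(n) - 1) / rate
  ev <- .specEvents(spec)
  ctr <- ev$contractions

  tocov <- rep(10, n)
  for (i in seq_len(nrow(ctr))) {
    inC <- t >= ctr$onset[i] & t < ctr$end[i]
    tocov[inC] <- 10 + 50 *
      (1 - cos(2 * pi * (t[inC] - ctr$onset[i]) /
                 (ctr$end[i] - ctr$onset[i]))) / 2
  }

  carrier <- .carrier(n, rate, spec$variabilityBand,
                      spec$variabilityAmplitude)
  sinWave <- numeric(n)
  if (!is.null(spec$sinusoidal)) {
    s0 <- (spec$sinusoidal$startMinute %||% 0) * 60
    s1 <- s0 + spec$sinusoidal$durationMinutes * 60
    inS <- t >= s0 & t < s1
    carrier[inS] <- 0
    sinWave[inS] <- spec$sinusoidal$amplitude *
      sin(2 * pi * spec$sinusoidal$frequency * (t[inS] - s0) / 60)
  }

  attn <- rep(1, n)
  shape <- numeric(n)
  for (i in seq_len(nrow(ev$decelerations))) {
    e <- ev$decelerations[i, ]
    shape <- shape + .decelShape(t, e)
    attn[t >= e$onset & t < e$end] <- 0.2
  }
  for (i in seq_len(nrow(ev$accelerations))) {
    a <- ev$accelerations[i, ]
    ramp <- 10
    inDown <- t >= a$onset & t < a$onset + ramp
    inFlat <- t >= a$onset + ramp & t < a$end - ramp
    inUp <- t >= a$end - ramp & t < a$end
    shape[inDown] <- shape[inDown] + a$rise * (t[inDown] - a$onset) / ramp
    shape[inFlat] <- shape[inFlat] + a$rise
    shape[inUp] <- shape[inUp] + a$rise * (a$end - t[inUp]) / ramp
    attn[t >= a$onset & t < a$end] <- 0.2
  }

  fhrv <- spec$baseline + carrier * attn + sinWave + shape
  if (spec$noiseSD > 0) fhrv <- fhrv + stats::rnorm(n, 0, spec$noiseSD)
  fhrv <- pmin(pmax(fhrv, 30), 250)
  for (g in spec$gaps) {
    idx <- t >= g[1] & t < g[1] + g[2]
    fhrv[idx] <- NA_real_
  }

  trace <- CTGTrace(fhrv, tocov, samplingRate = rate, startTime = 0)
  truth <- lapply(stats::setNames(.SYSTEMS, .SYSTEMS), function(s)
    .truthBundle(spec, ev, s))
  list(trace = trace, contractions = ctr, truth = truth, spec = spec)
}

# ground-truth bundle implied by a spec under one system's definitions
.truthBundle <- function(spec, ev, system) {
  ctr <- ev$contractions
  dec <- typeDecelerations(ev$decelerations, ctr, system)
  dec <- gradeDecelerations(dec, system)
  rep <- if (nrow(ctr)) assessRepetitiveness(dec, ctr) else
    suppressWarnings(assessRepetitiveness(dec, ctr))
  blv <- if (system %in% c("NICHD", "PARER")) .round5(spec$baseline)
         else spec$baseline
  sinMinutes <- if (is.null(spec$sinusoidal)) 0 else
    spec$sinusoidal$durationMinutes
  sinQ <- .sinusoidalQualifies(sinMinutes, system)
  # minutes free of (padded) events and of a qualifying sinusoidal episode:
  # the duration-accounting base the extractor uses
  nMin <- spec$durationMinutes
  included <- rep(TRUE, nMin)
  allEv <- rbind(ev$decelerations[, c("onset", "end")],
                 ev$accelerations[, c("onset", "end")])
  for (m in seq_len(nMin)) {
    t0 <- (m - 1) * 60; t1 <- m * 60
    if (nrow(allEv) && any(allEv$onset - 15 < t1 & allEv$end + 15 > t0))
      included[m] <- FALSE
    if (sinQ && !is.null(spec$sinusoidal)) {
      s0 <- (spec$sinusoidal$startMinute %||% 0) * 60
      s1 <- s0 + sinMinutes * 60
      if (s0 < t1 && s1 > t0) included[m] <- FALSE
    }
    for (g in spec$gaps)
      if (g[1] < t1 && g[1] + g[2] > t0 &&
          min(t1, g[1] + g[2]) - max(t0, g[1]) > 30)
        included[m] <- FALSE
  }
  nInc <- sum(included)
  amp <- spec$variabilityAmplitude
  featureBundle(
    system = system, baselineValue = blv,
    variabilityAmplitude = amp,
    reducedMinutes = if (amp < 5) nInc else 0,
    increasedMinutes = if (amp > 25) nInc else 0,
    reducedDuringDecelerations =
      any(ev$decelerations$duration > 180) && 0.2 * amp < 5,
    accelerations = ev$accelerations, decelerations = dec,
    sinusoidal = sinQ, sinusoidalMinutes = sinMinutes,
    repetitiveEarly = rep$repetitiveEarly,
    repetitiveVariable = rep$repetitiveVariable,
    repetitiveLate = rep$repetitiveLate,
    repetitiveProlonged = rep$repetitiveProlonged,
    contractionCount = nrow(ctr),
    missingFraction = sum(vapply(spec$gaps, `[`, numeric(1), 2)) /
      (spec$durationMinutes * 60),
    windowMinutes = spec$durationMinutes)
}

#' Generate a cohort with exact per-system category counts
#'
#' Cohorts are generated at the category level: counts are assigned, not
#' sampled, so every per-system contingency table reproduces the spec
#' exactly (no sampling error in contingency-level statistics). Default
#' counts are the packaged case-control study counts
#' (\code{\link{table5Counts}}).
#'
#' @param counts named list of \code{\linkS4class{ContingencyTable}}s
#'   (one per system); all must share the same group sizes.
#' @param shuffleSeed optional seed to permute category assignments
#'   within groups (the tables are invariant to this).
#' @return data.frame with columns \code{id}, \code{group} and one
#'   lower-case column per system.
#' @export
generateCohort <- function(counts = table5Counts(), shuffleSeed = NULL) {
  nCase <- unique(vapply(counts, function(tt) sum(tt@cases), numeric(1)))
  nCtrl <- unique(vapply(counts, function(tt) sum(tt@controls),
                         numeric(1)))
  if (length(nCase) != 1 || length(nCtrl) != 1)
    stop("all systems must have the same group sizes")
  rec <- data.frame(
    id = sprintf("S%03d", seq_len(nCase + nCtrl)),
    group = c(rep("case", nCase), rep("control", nCtrl)))
  for (s in names(counts)) {
    tt <- counts[[s]]
    caseLab <- rep(tt@labels, tt@cases)
    ctrlLab <- rep(tt@labels, tt@controls)
    if (!is.null(shuffleSeed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(shuffleSeed)
      caseLab <- sample(caseLab); ctrlLab <- sample(ctrlLab)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    rec[[tolower(s)]] <- c(caseLab, ctrlLab)
  }
  rec
}

#' Generate a multi-rater rating matrix with tunable agreement
#'
#' Each subject has a latent category; each rater independently copies it
#' with probability \code{agreement} and otherwise rates uniformly at
#' random. \code{agreement = 1} gives perfect agreement;
#' \code{agreement = 0} gives independent uniform ratings (kappa near 0).
#'
#' @param nSubjects,nRaters matrix dimensions.
#' @param agreement copy probability in [0, 1].
#' @param nCategories number of categories.
#' @param seed RNG seed.
#' @return integer matrix (subjects x raters) of categories 1..K.
#' @export
generateRaterMatrix <- function(nSubjects, nRaters, agreement,
                                nCategories = 3, seed = 1) {
  stopifnot(agreement >= 0, agreement <= 1, nSubjects >= 1, nRaters >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  latent <- sample.int(nCategories, nSubjects, replace = TRUE)
  copy <- matrix(stats::runif(nSubjects * nRaters) < agreement,
                 nSubjects, nRaters)
  rand <- matrix(sample.int(nCategories, nSubjects * nRaters,
                            replace = TRUE), nSubjects, nRaters)
  out <- ifelse(copy, latent, rand)
  storage.mode(out) <- "integer"
  out
}
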
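mkTrace <- function(x) CTGTrace(x, samplingRate = 4)

test_that("acceleration detection obeys the 15 bpm / 15 s / 10 min rules", {
  n <- 1800 * 4
  expect_equal(nrow(detectAccelerations(mkTrace(rep(140, n)), 140)), 0)

  x <- rep(140, n)
  x[2001:2080] <- 160                      # +20 bpm for 20 s
  acc <- detectAccelerations(mkTrace(x), 140)
  expect_equal(nrow(acc), 1)
  expect_equal(acc$rise, 20)
  expect_equal(acc$duration, 20, tolerance = 1)

  x2 <- rep(140, n)
  x2[2001:(2000 + 11 * 60 * 4)] <- 160     # 11 min: a baseline shift
  expect_equal(nrow(detectAccelerations(mkTrace(x2), 140)), 0)

  x3 <- rep(140, n)
  x3[2001:(2000 + 3 * 60 * 4)] <- 160      # 3 min: prolonged acceleration
  acc3 <- detectAccelerations(mkTrace(x3), 140)
  expect_true(acc3$prolonged)
})

test_that("deceleration detection obeys the depth/duration floor", {
  n <- 1800 * 4
  expect_equal(nrow(detectDecelerations(mkTrace(rep(140, n)), 140)), 0)

  x <- rep(140, n); x[2001:2200] <- 100    # 50 s V to 100
  dec <- detectDecelerations(mkTrace(x), 140)
  expect_equal(nrow(dec), 1)
  expect_equal(dec$depth, 40)
  expect_equal(dec$onset, 500, tolerance = 0.5)
  expect_equal(dec$end, 550, tolerance = 0.5)

  x2 <- rep(140, n); x2[2001:2200] <- 130  # only 10 bpm deep
  expect_equal(nrow(detectDecelerations(mkTrace(x2), 140)), 0)
})

test_that("typing partitions events by shape, duration and lag", {
  ctr <- data.frame(onset = 100, peak = 135, end = 170)
  base <- data.frame(onset = 0, nadirTime = 0, end = 0, depth = 30,
                     nadirAbsolute = 110, duration = 0, onsetToNadir = 0)
  mk <- function(nadir, dur, o2n) {
    d <- base
    d$nadirTime <- nadir; d$onset <- nadir - o2n
    d$end <- nadir - o2n + dur; d$duration <- dur; d$onsetToNadir <- o2n
    d
  }
  # gradual, nadir at the contraction peak -> early
  expect_equal(typeDecelerations(mk(135, 80, 40), ctr, "FIGO")$type,
               "early")
  # gradual, nadir 30 s after the peak -> late
  expect_equal(typeDecelerations(mk(165, 80, 40), ctr, "FIGO")$type,
               "late")
  # abrupt (onset-to-nadir 10 s) -> variable
  expect_equal(typeDecelerations(mk(135, 40, 10), ctr, "FIGO")$type,
               "variable")
  # duration beyond the system threshold -> prolonged
  expect_equal(typeDecelerations(mk(135, 150, 20), ctr, "NICHD")$type,
               "prolonged")
  expect_equal(typeDecelerations(mk(135, 150, 20), ctr, "FIGO")$type,
               "variable")                 # FIGO prolonged only > 3 min
  expect_equal(typeDecelerations(mk(165, 150, 60), ctr, "RCOG")$type,
               "late")                     # gradual 60-180 s stays late
  expect_equal(typeDecelerations(mk(165, 200, 100), ctr, "RCOG")$type,
               "prolonged")                # any shape > 3 min under RCOG
  expect_equal(typeDecelerations(mk(135, 90, 10), ctr, "RCOG")$type,
               "prolonged")                # abrupt >= 60 s under RCOG
  # gradual with no contraction nearby -> variable, flagged
  far <- typeDecelerations(mk(800, 80, 40), ctr, "FIGO")
  expect_equal(far$type, "variable")
  expect_true(far$indeterminate)
  # typing is a partition: exactly one type per event
  typed <- typeDecelerations(rbind(mk(135, 80, 40), mk(165, 80, 40),
                                   mk(400, 40, 10)), ctr, "NICHD")
  expect_false(anyNA(typed$type))
})

test_that("severity grading matches the five-tier cut points", {
  mk <- function(type, depth, dur, nadir) {
    d <- data.frame(onset = 0, nadirTime = dur / 2, end = dur,
                    depth = depth, nadirAbsolute = nadir, duration = dur,
                    onsetToNadir = dur / 2, lag = 0,
                    indeterminate = FALSE, type = type)
    gradeDecelerations(d)$severity
  }
  expect_equal(mk("late", 50, 80, 90), "severe")    # decline >= 45 bpm
  expect_equal(mk("late", 15, 80, 125), "mild")     # up to 15 bpm
  expect_equal(mk("late", 30, 80, 110), "moderate")
  expect_equal(mk("variable", 75, 90, 65), "severe")  # < 70 for > 60 s
  expect_equal(mk("variable", 75, 45, 65), "moderate")
  expect_equal(mk("variable", 65, 90, 75), "moderate") # < 80 for > 60 s
  expect_equal(mk("variable", 30, 45, 110), "mild")
  expect_equal(mk("prolonged", 75, 150, 65), "severe")
  expect_equal(mk("prolonged", 65, 150, 75), "moderate")
  expect_equal(mk("prolonged", 30, 150, 110), "mild")
})

test_that("severity is monotone in depth and duration", {
  depths <- c(20, 30, 45, 60, 75)
  durs <- c(20, 45, 75, 100)
  sevRank <- function(s) match(s, c("mild", "moderate", "severe"))
  for (type in c("variable", "late", "prolonged")) {
    grid <- expand.grid(depth = depths, dur = durs)
    r <- matrix(NA_integer_, length(depths), length(durs))
    for (i in seq_along(depths)) for (j in seq_along(durs)) {
      d <- data.frame(onset = 0, nadirTime = 1, end = durs[j],
                      depth = depths[i], nadirAbsolute = 140 - depths[i],
                      duration = durs[j], onsetToNadir = 1, lag = 0,
                      indeterminate = FALSE, type = type)
      r[i, j] <- sevRank(gradeDecelerations(d)$severity)
    }
    expect_true(all(apply(r, 2, function(cl) all(diff(cl) >= 0))),
                info = paste("depth monotone for", type))
    expect_true(all(apply(r, 1, function(rw) all(diff(rw) >= 0))),
                info = paste("duration monotone for", type))
  }
})

test_that("sinusoidal episodes qualify per system duration", {
  mkSin <- function(minutes, amp = 10, freq = 4, total = 60) {
    sp <- traceSpec(durationMinutes = total, baseline = 140,
                    variabilityAmplitude = 10,
                    sinusoidal = list(amplitude = amp, frequency = freq,
                                      durationMinutes = minutes,
                                      startMinute = 2),
                    seed = 91)
    generateTrace(sp)$trace
  }
  tr35 <- mkSin(35)
  for (s in c("FIGO", "RCOG", "PARER"))
    expect_true(detectSinusoidal(tr35, 140, system = s)$qualifies,
                info = s)
  tr15 <- mkSin(15)
  expect_true(detectSinusoidal(tr15, 140, system = "RCOG")$qualifies)
  expect_false(detectSinusoidal(tr15, 140, system = "FIGO")$qualifies)
  expect_false(detectSinusoidal(tr15, 140, system = "PARER")$qualifies)
  # band-limited noise variability must not read as sinusoidal
  g <- generateTrace(traceSpec(durationMinutes = 30, seed = 17))
  sn <- detectSinusoidal(g$trace, 140, system = "RCOG")
  expect_false(sn$qualifies)
  expect_lt(sn$qualifyingMinutes, 3)
})

test_that("repetitiveness uses a strict > 50% contraction rule", {
  ctr <- data.frame(onset = (0:9) * 180 + 30, peak = (0:9) * 180 + 65,
                    end = (0:9) * 180 + 100)
  mkLate <- function(idx) data.frame(
    onset = ctr$peak[idx] + 20, nadirTime = ctr$peak[idx] + 40,
    end = ctr$peak[idx] + 60, depth = 30, nadirAbsolute = 110,
    duration = 40, onsetToNadir = 20, lag = 40, indeterminate = FALSE,
    type = "late")
  expect_true(assessRepetitiveness(mkLate(1:6), ctr)$repetitiveLate)
  expect_false(assessRepetitiveness(mkLate(1:5), ctr)$repetitiveLate)
  none <- assessRepetitiveness(ctgtier:::.emptyDecelFrame(), ctr)
  expect_false(none$repetitiveLate)
  expect_false(none$repetitiveVariable)
  noCtr <- data.frame(onset = numeric(0), peak = numeric(0),
                      end = numeric(0))
  expect_warning(r0 <- assessRepetitiveness(mkLate(1), noCtr),
                 "no contractions")
  expect_false(r0$repetitiveLate)
})

test_that("detected events always satisfy their defining floors", {
  # property over generator output
  for (i in c(16, 18, 25, 26)) {
    sp <- roundTripSpecs()[[i]]
    g <- generateTrace(sp)
    dec <- detectDecelerations(fillGaps(g$trace), sp$baseline)
    if (nrow(dec)) {
      expect_true(all(dec$depth >= 15))
      expect_true(all(dec$duration >= 15))
      expect_true(all(dec$onsetToNadir <= dec$duration))
    }
  }
})
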
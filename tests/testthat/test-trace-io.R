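test_that("a constant 30-min CSV loads with a full uniform timebase", {
  path <- withr::local_tempfile(fileext = ".csv")
  n <- 7200
  utils::write.csv(data.frame(time_s = (0:(n - 1)) / 4, fhr_bpm = 140,
                              toco = 12),
                   path, row.names = FALSE)
  tr <- readCTGTrace(path)
  expect_s4_class(tr, "CTGTrace")
  expect_length(fhr(tr), 7200)
  expect_equal(samplingRate(tr), 4)
  expect_equal(missingFraction(tr), 0)
  expect_true(all(fhr(tr) == 140))
})

test_that("out-of-range FHR values are coerced to missing and reported", {
  path <- withr::local_tempfile(fileext = ".csv")
  f <- rep(140, 1200); f[100] <- 300; f[200] <- 20
  utils::write.csv(data.frame(time_s = (0:1199) / 4, fhr_bpm = f, toco = 0),
                   path, row.names = FALSE)
  expect_message(tr <- readCTGTrace(path), "2 FHR sample")
  expect_equal(sum(is.na(fhr(tr))), 2)
  expect_true(is.na(fhr(tr)[100]) && is.na(fhr(tr)[200]))
})

test_that("non-monotone time and unusable traces are refused", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = c(0, 0.5, 0.25, 0.75),
                              fhr_bpm = 140, toco = 0),
                   path, row.names = FALSE)
  expect_error(readCTGTrace(path), "non-monotone")
  f <- rep(NA_real_, 1200); f[1:400] <- 140
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = (0:1199) / 4, fhr_bpm = f, toco = 0),
                   path2, row.names = FALSE)
  expect_error(readCTGTrace(path2), "unusable")
})

test_that("write -> read round-trips a generated trace exactly", {
  g <- generateTrace(traceSpec(durationMinutes = 30, seed = 11,
                               gaps = list(c(600, 30))))
  path <- withr::local_tempfile(fileext = ".csv")
  writeCTGTrace(g$trace, path)
  tr2 <- readCTGTrace(path)
  expect_equal(fhr(tr2), fhr(g$trace), tolerance = 1e-10)
  expect_equal(toco(tr2), toco(g$trace), tolerance = 1e-10)
  expect_equal(samplingRate(tr2), 4)
})

test_that("physiologic guard rails are enforced at construction", {
  expect_error(CTGTrace(c(140, 260)), "30, 250")
  expect_error(CTGTrace(rep(140, 4), toco = rep(-1, 4)), "non-negative")
  expect_silent(CTGTrace(c(140, NA, 140)))
})

test_that("short gaps interpolate linearly; long gaps survive", {
  x <- rep(140, 480)                       # 2 min at 4 Hz
  x[101:108] <- NA                         # 2 s gap
  tr <- fillGaps(CTGTrace(x), maxGap = 15)
  expect_equal(sum(is.na(fhr(tr))), 0)
  expect_true(all(fhr(tr) == 140))

  x2 <- rep(140, 1200)
  x2[401:640] <- NA                        # 60 s gap
  tr2 <- fillGaps(CTGTrace(x2), maxGap = 15)
  expect_equal(which(is.na(fhr(tr2))), 401:640)

  # ramp: interpolated values equal the analytic line
  x3 <- seq(120, 160, length.out = 481)
  gap <- 201:216                           # 4 s
  x3na <- x3; x3na[gap] <- NA
  tr3 <- fillGaps(CTGTrace(x3na, samplingRate = 4), maxGap = 15)
  expect_equal(fhr(tr3)[gap], x3[gap], tolerance = 1e-9)
})

test_that("fillGaps never alters non-missing samples", {
  g <- generateTrace(traceSpec(durationMinutes = 30, seed = 7,
                               gaps = list(c(300, 5), c(900, 120))))
  keep <- !is.na(fhr(g$trace))
  filled <- fillGaps(g$trace, maxGap = 15)
  expect_equal(fhr(filled)[keep], fhr(g$trace)[keep])
})

test_that("extractWindow anchors to the end and is idempotent", {
  tr <- CTGTrace(rep(140, 90 * 60 * 4))    # 90 min
  w <- extractWindow(tr, 60)
  expect_equal(traceDuration(w), 3600)
  expect_equal(startTime(w), 30 * 60)
  expect_error(extractWindow(CTGTrace(rep(140, 45 * 60 * 4)), 60),
               "shorter")
  tr2 <- CTGTrace(rep(140, 60 * 60 * 4))
  w2 <- extractWindow(tr2, 30)
  expect_equal(startTime(w2), 1800)
  expect_equal(fhr(extractWindow(w2, 30)), fhr(w2))
  expect_error(extractWindow(tr, 20), "between 30 and 60")
})

test_that("contraction detection recovers the generated grid", {
  g <- generateTrace(traceSpec(durationMinutes = 60, seed = 5))
  found <- detectContractions(g$trace)
  expect_equal(nrow(found), nrow(g$contractions))
  expect_equal(found$peak, g$contractions$peak, tolerance = 2)
})
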
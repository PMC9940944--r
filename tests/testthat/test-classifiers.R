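rules <- parerRuleTable()

test_that("FIGO category rules fire as specified", {
  expect_equal(categoryLabel(classifyFIGO(featureBundle("FIGO"))),
               "normal")
  expect_equal(categoryLabel(classifyFIGO(
    featureBundle("FIGO", baselineValue = 90))), "pathological")
  expect_equal(categoryLabel(classifyFIGO(
    featureBundle("FIGO", baselineValue = 165))), "suspicious")
  expect_equal(categoryLabel(classifyFIGO(
    featureBundle("FIGO", baselineValue = 105))), "suspicious")
  # reduced variability needs > 50 min to turn pathological
  expect_equal(categoryLabel(classifyFIGO(
    featureBundle("FIGO", variabilityAmplitude = 3,
                  reducedMinutes = 45))), "suspicious")
  expect_equal(categoryLabel(classifyFIGO(
    featureBundle("FIGO", variabilityAmplitude = 3,
                  reducedMinutes = 55))), "pathological")
  # one prolonged deceleration > 5 min
  expect_equal(categoryLabel(classifyFIGO(
    featureBundle("FIGO",
                  decelerations = mkDecelRow("prolonged", "moderate",
                                             900, 360,
                                             nadirAbsolute = 75)))),
    "pathological")
  # repetitive late needs a > 30 min span (20 with reduced variability)
  lates <- mkDecelRow("late", "moderate", seq(100, 1500, by = 200), 90)
  expect_equal(categoryLabel(classifyFIGO(
    featureBundle("FIGO", decelerations = lates,
                  repetitiveLate = TRUE))), "suspicious")   # 25 min span
  expect_equal(categoryLabel(classifyFIGO(
    featureBundle("FIGO", variabilityAmplitude = 3, reducedMinutes = 30,
                  decelerations = lates, repetitiveLate = TRUE))),
    "pathological")                                         # 20 min rule
})

test_that("NICHD III/I/II conditions match the category definitions", {
  expect_equal(categoryLabel(classifyNICHD(
    featureBundle("NICHD", variabilityAmplitude = 1,
                  decelerations = mkDecelRow("late", "moderate",
                                             c(100, 400, 700), 90),
                  repetitiveLate = TRUE))), "III")
  expect_equal(categoryLabel(classifyNICHD(
    featureBundle("NICHD", variabilityAmplitude = 1,
                  baselineValue = 90))), "III")
  expect_equal(categoryLabel(classifyNICHD(
    featureBundle("NICHD", sinusoidal = TRUE,
                  sinusoidalMinutes = 25))), "III")
  expect_equal(categoryLabel(classifyNICHD(
    featureBundle("NICHD",
                  decelerations = mkDecelRow("early", "mild",
                                             c(100, 400), 60)))), "I")
  expect_equal(categoryLabel(classifyNICHD(
    featureBundle("NICHD", baselineValue = 170))), "II")
  # bradycardia with preserved variability is II, not III
  expect_equal(categoryLabel(classifyNICHD(
    featureBundle("NICHD", baselineValue = 90))), "II")
})

test_that("RCOG feature grades and category counting follow the bands", {
  g <- gradeRCOGFeatures(featureBundle("RCOG", baselineValue = 105))
  expect_equal(g@baseline, "nonreassuring")
  expect_equal(categoryLabel(classifyRCOG(g)), "suspicious")

  g2 <- gradeRCOGFeatures(featureBundle("RCOG",
    decelerations = mkDecelRow("prolonged", "mild", 900, 240,
                               nadirAbsolute = 110)))
  expect_equal(g2@decelerations, "abnormal")  # single prolonged > 3 min
  expect_equal(categoryLabel(classifyRCOG(g2)), "pathological")

  g3 <- gradeRCOGFeatures(featureBundle("RCOG",
    decelerations = mkDecelRow("prolonged", "mild", 900, 150,
                               nadirAbsolute = 110)))
  expect_equal(g3@decelerations, "nonreassuring")  # up to 3 min

  g4 <- gradeRCOGFeatures(featureBundle("RCOG", variabilityAmplitude = 3,
                                        reducedMinutes = 60,
                                        windowMinutes = 120))
  expect_equal(g4@variability, "nonreassuring")    # 40-90 min band
  g5 <- gradeRCOGFeatures(featureBundle("RCOG", variabilityAmplitude = 3,
                                        reducedMinutes = 95,
                                        windowMinutes = 120))
  expect_equal(g5@variability, "abnormal")         # > 90 min

  expect_equal(categoryLabel(classifyRCOG(featureBundle("RCOG"))),
               "normal")
  # two nonreassuring features -> pathological
  expect_equal(categoryLabel(classifyRCOG(
    featureBundle("RCOG", baselineValue = 165, variabilityAmplitude = 3,
                  reducedMinutes = 60, windowMinutes = 120))),
    "pathological")
})

test_that("the Parer rule table is total, monotone and matches key cells", {
  expect_true(validateParerRules(rules))
  expect_equal(nrow(rules), 4 * 5 * 11)
  # early decelerations with an otherwise normal trace stay green
  expect_equal(categoryLabel(classifyParer(
    featureBundle("PARER",
                  decelerations = mkDecelRow("early", "mild",
                                             c(100, 400), 60)),
    rules, validate = FALSE)), "green")
  # any severe bradycardia with moderate variability -> orange
  expect_equal(categoryLabel(classifyParer(
    featureBundle("PARER", baselineValue = 75), rules,
    validate = FALSE)), "orange")
  # absent variability with any deceleration -> red
  expect_equal(categoryLabel(classifyParer(
    featureBundle("PARER", variabilityAmplitude = 1,
                  decelerations = mkDecelRow("early", "mild", 100, 60)),
    rules, validate = FALSE)), "red")
  # isolated tachycardia with moderate variability -> blue
  expect_equal(categoryLabel(classifyParer(
    featureBundle("PARER", baselineValue = 170), rules,
    validate = FALSE)), "blue")
  # sinusoidal pattern forces red
  expect_equal(categoryLabel(classifyParer(
    featureBundle("PARER", sinusoidal = TRUE, sinusoidalMinutes = 25),
    rules, validate = FALSE)), "red")
  # a broken table is rejected
  bad <- rules; bad$colour[1] <- "magenta"
  expect_error(validateParerRules(bad), "unknown colour")
  bad2 <- rules[-5, ]
  expect_error(validateParerRules(bad2), "not total")
})

test_that("an all-normal trace is normal in all four systems", {
  g <- generateTrace(traceSpec(durationMinutes = 30, baseline = 140,
                               variabilityAmplitude = 10, seed = 41))
  res <- classifyAll(g$trace, contractions = g$contractions,
                     rules = rules)
  expect_equal(categoryLabel(res$categories$FIGO), "normal")
  expect_equal(categoryLabel(res$categories$RCOG), "normal")
  expect_equal(categoryLabel(res$categories$NICHD), "I")
  expect_equal(categoryLabel(res$categories$PARER), "green")
})

test_that("absent variability with recurrent lates is maximal everywhere", {
  sp <- traceSpec(durationMinutes = 60, baseline = 140,
                  variabilityAmplitude = 1,
                  decelerations = list(dz("late", 30, 90, lag = 40,
                                          contractions = 1:16)),
                  seed = 42)
  g <- generateTrace(sp)
  res <- classifyAll(g$trace, contractions = g$contractions,
                     rules = rules)
  expect_equal(categoryLabel(res$categories$FIGO), "pathological")
  expect_equal(categoryLabel(res$categories$RCOG), "pathological")
  expect_equal(categoryLabel(res$categories$NICHD), "III")
  expect_equal(categoryLabel(res$categories$PARER), "red")
})

test_that("NICHD II is exactly the complement of I and III", {
  set.seed(77)
  for (i in 1:300) {
    b <- gradedBundle("NICHD", sample(c("low", "high"), 1),
                      sample(0:2, 1), sample(0:4, 1), sample(0:6, 1))
    lab <- categoryLabel(classifyNICHD(b))
    isIII <- (b@variabilityClass == "absent" &&
                (b@repetitiveLate || b@repetitiveVariable ||
                   b@baselineValue < 110)) || b@sinusoidal
    isI <- !isIII && b@baselineValue >= 110 && b@baselineValue <= 160 &&
      b@variabilityClass == "normal" &&
      !any(b@decelerations$type %in% c("late", "variable", "prolonged"))
    expect_equal(lab, if (isIII) "III" else if (isI) "I" else "II")
  }
})

test_that("classifiers refuse bundles built for another system", {
  expect_error(classifyFIGO(featureBundle("RCOG")), "parameterised")
  expect_error(classifyNICHD(featureBundle("FIGO")), "parameterised")
})
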
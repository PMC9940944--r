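counts <- table5Counts()

test_that("cohort records tabulate back to the packaged counts", {
  rec <- generateCohort(counts)
  for (s in names(counts)) {
    tab <- buildContingency(rec, s)
    expect_equal(tab@cases, counts[[s]]@cases)
    expect_equal(tab@controls, counts[[s]]@controls)
  }
  # permutation invariance
  rec2 <- rec[sample(nrow(rec)), ]
  tab2 <- buildContingency(rec2, "PARER")
  expect_equal(tab2@cases, counts$PARER@cases)
  expect_equal(tab2@cases, c(2, 0, 13, 17, 11))
  expect_equal(tab2@controls, c(33, 8, 1, 1, 0))
  # missing categories are reported with ids
  rec3 <- rec; rec3$figo[3] <- NA
  expect_error(buildContingency(rec3, "FIGO"), "S003")
})

test_that("an empty cohort tabulates to zeros", {
  zero <- lapply(counts, function(tt)
    contingencyTable(tt@system, tt@cases * 0, tt@controls * 0))
  rec <- generateCohort(zero)
  expect_equal(nrow(rec), 0)
})

test_that("per-category diagnostics reproduce the hand-derived 2x2s", {
  d <- categoryDiagnostics(counts$FIGO, "normal")
  expect_equal(d$polarity, "category_is_negative_test")
  expect_equal(d$sensitivity, 41 / 43)
  expect_equal(d$specificity, 14 / 43)
  expect_equal(d$ppv, 41 / 70)
  expect_equal(d$npv, 14 / 16)
  expect_equal(d$lrPositive, (41 / 43) / (1 - 14 / 43))
  expect_equal(d$lrNegative, (2 / 43) / (14 / 43))

  dRed <- categoryDiagnostics(counts$PARER, "red")
  expect_equal(dRed$polarity, "category_is_positive_test")
  expect_equal(dRed$specificity, 1)
  expect_true("lrPositive" %in% dRed$undefined)
  expect_true(is.na(dRed$lrPositive))

  # degenerate: everyone in one category
  tab <- contingencyTable("FIGO", c(10, 0, 0), c(10, 0, 0))
  d1 <- categoryDiagnostics(tab, "normal")
  expect_equal(d1$sensitivity, 0)
  expect_equal(d1$specificity, 1)
})

test_that("LR+ > 1 iff sens + spec > 1, and PPV/NPV obey Bayes", {
  set.seed(5)
  for (i in 1:50) {
    tb <- randomTable()
    tab <- contingencyTable("FIGO", tb$cases, tb$controls,
                            labels = paste0("c", seq_along(tb$cases)))
    for (lab in tab@labels) {
      d <- categoryDiagnostics(tab, lab)
      if (anyNA(c(d$sensitivity, d$specificity, d$lrPositive, d$ppv,
                  d$npv)))
        next
      expect_equal(d$lrPositive > 1, d$sensitivity + d$specificity > 1)
      prev <- sum(tab@cases) / (sum(tab@cases) + sum(tab@controls))
      ppvBayes <- d$sensitivity * prev /
        (d$sensitivity * prev + (1 - d$specificity) * (1 - prev))
      expect_equal(d$ppv, ppvBayes, tolerance = 1e-12)
      npvBayes <- d$specificity * (1 - prev) /
        (d$specificity * (1 - prev) + (1 - d$sensitivity) * prev)
      expect_equal(d$npv, npvBayes, tolerance = 1e-12)
    }
  }
})

test_that("ordinal AUC handles the canonical edge cases", {
  sep <- contingencyTable("FIGO", c(0, 0, 10), c(10, 0, 0))
  expect_equal(auc(ordinalAUC(sep, ci = "none")), 1)
  same <- contingencyTable("FIGO", c(5, 3, 2), c(5, 3, 2))
  expect_equal(auc(ordinalAUC(same, ci = "none")), 0.5)
  expect_error(ordinalAUC(contingencyTable("FIGO", c(0, 0, 0),
                                           c(1, 1, 1)), ci = "none"),
               "at least one")
})

test_that("reversing the category order maps AUC to 1 - AUC", {
  set.seed(9)
  for (i in 1:25) {
    tb <- randomTable()
    a <- ctgtier:::.aucFromCounts(tb$cases, tb$controls)
    aRev <- ctgtier:::.aucFromCounts(rev(tb$cases), rev(tb$controls))
    expect_equal(a, 1 - aRev, tolerance = 1e-12)
  }
})

test_that("ROC points trapezoid back to the ordinal AUC", {
  pts <- rocPoints(counts$PARER)
  expect_equal(nrow(pts), 6)
  area <- ctgtier:::.trapezoid(pts$fpr, pts$tpr)
  expect_equal(area, auc(ordinalAUC(counts$PARER, ci = "none")),
               tolerance = 1e-12)
  # the "category >= III" point for NICHD has perfect specificity
  ptsN <- rocPoints(counts$NICHD)
  p3 <- ptsN[ptsN$threshold == ">=III", ]
  expect_equal(p3$fpr, 0)
  expect_equal(p3$tpr, 17 / 43)
  # identical distributions lie on the diagonal
  same <- contingencyTable("FIGO", c(5, 3, 2), c(5, 3, 2))
  ptsS <- rocPoints(same)
  expect_equal(ptsS$fpr, ptsS$tpr, tolerance = 1e-12)
})

test_that("analytic CIs bracket the point estimate and match the paper's
          reported band within method tolerance", {
  r <- ordinalAUC(counts$FIGO, ci = "hanley_mcneil")
  expect_true(r@ciLow <= r@auc && r@auc <= r@ciHigh)
  expect_lt(abs(r@ciLow - 0.63), 0.03)
  expect_lt(abs(r@ciHigh - 0.84), 0.03)
  rd <- ordinalAUC(counts$FIGO, ci = "delong")
  expect_true(rd@ciLow <= rd@auc && rd@auc <= rd@ciHigh)
  # degenerate separation: analytic methods fall back to bootstrap
  sep <- contingencyTable("FIGO", c(0, 0, 10), c(10, 0, 0))
  expect_warning(rs <- ordinalAUC(sep, ci = "hanley_mcneil", B = 500,
                                  seed = 1), "degenerate")
  expect_equal(rs@ciHigh, 1)
})

test_that("bootstrap CI is reproducible under a seed", {
  b1 <- aucCI(counts$RCOG, method = "bootstrap", B = 200, seed = 7)
  b2 <- aucCI(counts$RCOG, method = "bootstrap", B = 200, seed = 7)
  expect_identical(as.numeric(b1), as.numeric(b2))
})

test_that("Fleiss kappa: perfect agreement, published example, oracle", {
  perfect <- matrix(rep(c(1, 2, 3, 1, 2), each = 4), ncol = 4,
                    byrow = TRUE)
  expect_equal(fleissKappa(perfect)@kappa, 1)

  pub <- fleissPublishedRatings()
  r <- fleissKappa(pub)
  expect_equal(round(r@kappa, 3), 0.210)   # printed value of the example
  expect_equal(r@kappa, pairwiseKappaOracle(pub), tolerance = 1e-12)

  set.seed(13)
  for (i in 1:10) {
    m <- matrix(sample(1:4, 60, replace = TRUE), ncol = 3)
    expect_equal(fleissKappa(m)@kappa, pairwiseKappaOracle(m),
                 tolerance = 1e-12)
  }

  # all ratings identical everywhere: expected agreement 1, undefined
  expect_warning(r0 <- fleissKappa(matrix(1, 5, 3)), "undefined")
  expect_true(r0@undefined)
  expect_error(fleissKappa(matrix(c(1, NA, 2, 2), 2, 2)), "complete")
})
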
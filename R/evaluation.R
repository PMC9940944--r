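#' Construct a case/control contingency table
#'
#' @param system classification system identifier.
#' @param cases,controls counts per ordered category (most normal first).
#' @param labels category labels; the system's canonical labels by
#'   default.
#' @return a \code{\linkS4class{ContingencyTable}}.
#' @export
contingencyTable <- function(system, cases, controls,
                             labels = systemLabels(system)) {
  new("ContingencyTable", system = .matchSystem(system),
      labels = labels, cases = as.numeric(cases),
      controls = as.numeric(controls))
}

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable [%s]: %g cases vs %g controls\n",
              object@system, sum(object@cases), sum(object@controls)))
  print(data.frame(category = object@labels, cases = object@cases,
                   controls = object@controls), row.names = FALSE)
})

#' Tabulate classified cohort records
#'
#' @param records data.frame with a \code{group} column
#'   (\code{"case"}/\code{"control"}) and one lower-case column per
#'   system holding category labels (as written by
#'   \code{\link{generateCohort}}).
#' @param system classification system identifier.
#' @return a \code{\linkS4class{ContingencyTable}}.
#' @export
buildContingency <- function(records, system) {
  system <- .matchSystem(system)
  col <- tolower(system)
  if (!col %in% names(records))
    stop("records lack a '", col, "' column")
  labels <- systemLabels(system)
  cat <- records[[col]]
  bad <- is.na(cat) | !(cat %in% labels)
  if (any(bad)) {
    ids <- if ("id" %in% names(records)) records$id[bad] else which(bad)
    stop("records with missing/unknown ", system, " category: ",
         paste(utils::head(ids, 5), collapse = ", "))
  }
  f <- factor(cat, levels = labels)
  contingencyTable(system,
                   cases = as.numeric(table(f[records$group == "case"])),
                   controls = as.numeric(table(f[records$group == "control"])))
}

#' Per-category diagnostic values
#'
#' Dichotomises the ordered table at one category and reports the 2x2
#' statistics. Default polarity: the system's most-normal category is a
#' negative test (test positive = any other category); every other
#' category is itself the positive test. Ratios with a zero denominator
#' are flagged undefined (\code{NA}), mirroring the em-dash convention of
#' printed tables, never infinite.
#'
#' @param tab a \code{\linkS4class{ContingencyTable}}.
#' @param category category label in \code{tab}.
#' @param polarity \code{"auto"} (default rule above),
#'   \code{"category_is_positive_test"} or
#'   \code{"category_is_negative_test"}.
#' @return list of class \code{ctgDiagnosticRow}: proportions
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{npv},
#'   ratios \code{lrPositive}, \code{lrNegative}, the underlying
#'   \code{counts} (TP/FP/FN/TN) and \code{undefined} (names of flagged
#'   statistics).
#' @export
categoryDiagnostics <- function(tab, category,
                                polarity = c("auto",
                                             "category_is_positive_test",
                                             "category_is_negative_test")) {
  polarity <- match.arg(polarity)
  k <- match(category, tab@labels)
  if (is.na(k)) stop("category '", category, "' not in table")
  if (polarity == "auto")
    polarity <- if (k == 1L) "category_is_negative_test"
                else "category_is_positive_test"
  nCase <- sum(tab@cases); nCtrl <- sum(tab@controls)
  if (polarity == "category_is_positive_test") {
    TP <- tab@cases[k];          FN <- nCase - TP
    FP <- tab@controls[k];       TN <- nCtrl - FP
  } else {
    FN <- tab@cases[k];          TP <- nCase - FN
    TN <- tab@controls[k];       FP <- nCtrl - TN
  }
  undef <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  sens <- div(TP, TP + FN, "sensitivity")
  spec <- div(TN, TN + FP, "specificity")
  lrp <- if (!is.na(spec) && spec < 1) sens / (1 - spec) else {
    undef <- c(undef, "lrPositive"); NA_real_ }
  lrn <- if (!is.na(spec) && spec > 0) (1 - sens) / spec else {
    undef <- c(undef, "lrNegative"); NA_real_ }
  structure(list(category = category, polarity = polarity,
                 sensitivity = sens, specificity = spec,
                 lrPositive = lrp, lrNegative = lrn,
                 ppv = div(TP, TP + FP, "ppv"),
                 npv = div(TN, TN + FN, "npv"),
                 counts = c(TP = TP, FP = FP, FN = FN, TN = TN),
                 undefined = undef),
            class = "ctgDiagnosticRow")
}

#' @describeIn categoryDiagnostics all categories of a table as a
#'   data.frame (default polarity).
#' @export
systemDiagnostics <- function(tab) {
  rows <- lapply(tab@labels, function(cg) {
    d <- categoryDiagnostics(tab, cg)
    data.frame(system = tab@system, category = cg, polarity = d$polarity,
               sensitivity = d$sensitivity, specificity = d$specificity,
               lrPositive = d$lrPositive, lrNegative = d$lrNegative,
               ppv = d$ppv, npv = d$npv)
  })
  do.call(rbind, rows)
}

.aucFromCounts <- function(cases, controls) {
  nCase <- sum(cases); nCtrl <- sum(controls)
  below <- cumsum(c(0, controls))[seq_along(controls)]
  sum(cases * (below + 0.5 * controls)) / (nCase * nCtrl)
}

#' Ordinal (tie-corrected Mann-Whitney) AUC
#'
#' The area under the ROC curve of an ordered-category classifier: the
#' probability that a random case is assigned a worse category than a
#' random control, counting ties as one half.
#'
#' @param tab a \code{\linkS4class{ContingencyTable}} with at least one
#'   case and one control.
#' @param ci confidence-interval method: \code{"hanley_mcneil"}
#'   (default), \code{"delong"}, \code{"bootstrap"}, or \code{"none"}.
#' @param level confidence level.
#' @param B bootstrap resamples (bootstrap method only).
#' @param seed optional seed for the bootstrap, applied to a local RNG
#'   scope.
#' @return an \code{\linkS4class{AUCResult}}.
#' @export
ordinalAUC <- function(tab, ci = c("hanley_mcneil", "delong", "bootstrap",
                                   "none"),
                       level = 0.95, B = 2000, seed = NULL) {
  ci <- match.arg(ci)
  if (sum(tab@cases) < 1 || sum(tab@controls) < 1)
    stop("need at least one case and one control")
  a <- .aucFromCounts(tab@cases, tab@controls)
  lo <- NA_real_; hi <- NA_real_
  if (ci != "none") {
    b <- aucCI(tab, method = ci, level = level, B = B, seed = seed)
    lo <- b[1]; hi <- b[2]; ci <- attr(b, "method")
  }
  new("AUCResult", system = tab@system, auc = a, ciLow = lo, ciHigh = hi,
      level = level, method = ci, nCases = sum(tab@cases),
      nControls = sum(tab@controls))
}

#' @describeIn ordinalAUC point-estimate accessor
#' @param x an \code{AUCResult}
#' @export
auc <- function(x) x@auc

setMethod("show", "AUCResult", function(object) {
  cat(sprintf("Ordinal AUC [%s]: %.3f", object@system, object@auc))
  if (!is.na(object@ciLow))
    cat(sprintf(" (%g%% CI %.3f-%.3f, %s)", 100 * object@level,
                object@ciLow, object@ciHigh, object@method))
  cat(sprintf("; %g cases vs %g controls\n", object@nCases,
              object@nControls))
})

#' Confidence interval for the ordinal AUC
#'
#' \code{hanley_mcneil}: the classic binormal-free variance approximation.
#' \code{delong}: the empirical placement-value variance. Both are normal
#' intervals clipped to [0, 1]; with a degenerate AUC (0 or 1) they fall
#' back to the bootstrap with a warning. \code{bootstrap}: percentile
#' interval over multinomial resampling of subjects within groups.
#'
#' @inheritParams ordinalAUC
#' @param method CI method.
#' @return numeric \code{c(low, high)} with a \code{method} attribute.
#' @export
aucCI <- function(tab, method = c("hanley_mcneil", "delong", "bootstrap"),
                  level = 0.95, B = 2000, seed = NULL) {
  method <- match.arg(method)
  cases <- tab@cases; controls <- tab@controls
  m <- sum(cases); n <- sum(controls)
  a <- .aucFromCounts(cases, controls)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method %in% c("hanley_mcneil", "delong") && (a <= 0 || a >= 1)) {
    warning("degenerate AUC (", a, "); falling back to bootstrap CI")
    method <- "bootstrap"
  }
  if (method == "hanley_mcneil") {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    v <- (a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) /
      (m * n)
    out <- c(max(0, a - z * sqrt(v)), min(1, a + z * sqrt(v)))
  } else if (method == "delong") {
    k <- length(cases)
    ctrlBelow <- cumsum(c(0, controls))[seq_len(k)]
    v10 <- (ctrlBelow + 0.5 * controls) / n      # placement per case cat
    caseAbove <- rev(cumsum(c(0, rev(cases))))[-1]
    v01 <- (caseAbove + 0.5 * cases) / m         # placement per ctrl cat
    s10 <- sum(cases * (v10 - a)^2) / (m - 1)
    s01 <- sum(controls * (v01 - a)^2) / (n - 1)
    v <- s10 / m + s01 / n
    out <- c(max(0, a - z * sqrt(v)), min(1, a + z * sqrt(v)))
  } else {
    runBoot <- function() {
      bc <- stats::rmultinom(B, m, cases / m)
      bn <- stats::rmultinom(B, n, controls / n)
      below <- apply(bn, 2, function(col) cumsum(c(0, col))[seq_along(col)])
      aucs <- colSums(bc * (below + 0.5 * bn)) / (m * n)
      stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2),
                      names = FALSE)
    }
    out <- if (is.null(seed)) runBoot() else {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      runBoot()
    }
  }
  attr(out, "method") <- method
  out
}

#' ROC points of an ordered-category classifier
#'
#' One point per cumulative threshold "category >= k is positive", plus
#' (0,0) and (1,1). The trapezoidal area over these points equals the
#' tie-corrected Mann-Whitney AUC.
#'
#' @param tab a \code{\linkS4class{ContingencyTable}}.
#' @return data.frame with columns \code{threshold}, \code{fpr}
#'   (1 - specificity) and \code{tpr} (sensitivity), ordered from (0,0)
#'   to (1,1).
#' @export
rocPoints <- function(tab) {
  k <- length(tab@labels)
  m <- sum(tab@cases); n <- sum(tab@controls)
  tpr <- c(0, rev(cumsum(rev(tab@cases))) / m)   # pos 1+j: ">= category j"
  fpr <- c(0, rev(cumsum(rev(tab@controls))) / n)
  pts <- data.frame(threshold = c("none", paste0(">=", tab@labels)),
                    fpr = fpr, tpr = tpr)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  pts
}

#' Fleiss kappa for multi-rater categorical agreement
#'
#' Standard formula: kappa = (Pbar - Pe) / (1 - Pe), with the expected
#' agreement Pe from the marginal category proportions. With complete
#' agreement forced by the margins (Pe = 1, e.g. every rating identical)
#' kappa is undefined and flagged.
#'
#' @param ratings subjects x raters matrix (or data.frame) of category
#'   labels; at least 2 raters and 2 subjects, no missing entries.
#' @return a \code{\linkS4class{FleissKappaResult}}.
#' @export
fleissKappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete")
  nSub <- nrow(ratings); nRat <- ncol(ratings)
  if (nSub < 2 || nRat < 2) stop("need >= 2 subjects and >= 2 raters")
  cats <- sort(unique(as.vector(ratings)))
  counts <- vapply(cats, function(cg) rowSums(ratings == cg),
                   numeric(nSub))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nSub)
  pObs <- (rowSums(counts^2) - nRat) / (nRat * (nRat - 1))
  pBar <- mean(pObs)
  pj <- colSums(counts) / (nSub * nRat)
  pe <- sum(pj^2)
  undefined <- abs(1 - pe) < .Machine$double.eps^0.5
  kap <- if (undefined) NA_real_ else (pBar - pe) / (1 - pe)
  if (undefined)
    warning("expected agreement is 1; kappa undefined")
  new("FleissKappaResult", kappa = kap, nSubjects = nSub, nRaters = nRat,
      nCategories = length(cats), undefined = undefined)
}

setMethod("show", "FleissKappaResult", function(object) {
  cat(sprintf(
    "Fleiss kappa: %s (%g subjects, %g raters, %g categories)\n",
    if (object@undefined) "undefined" else sprintf("%.4f", object@kappa),
    object@nSubjects, object@nRaters, object@nCategories))
})
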
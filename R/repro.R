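# recorded digest of the packaged case/control counts; guards against a
# silently edited fixture
.TABLE5_MD5 <- "4e26650e883d31e44e79e34d1a19d552"

#' Packaged case/control category counts
#'
#' The per-system counts of the source case-control study: 43 CTG traces
#' with umbilical artery pH < 7.00 (cases) and 43 with pH >= 7.00
#' (controls), classified by consensus under each of the four systems.
#'
#' @param file path to a counts CSV (columns \code{system},
#'   \code{category}, \code{cases}, \code{controls}); defaults to the
#'   packaged fixture.
#' @param verifyChecksum verify the packaged file's md5 digest (only
#'   applied to the default file).
#' @return named list of \code{\linkS4class{ContingencyTable}}s.
#' @export
table5Counts <- function(file = NULL, verifyChecksum = TRUE) {
  default <- is.null(file)
  if (default)
    file <- system.file("extdata", "table5_counts.csv",
                        package = "ctgtier")
  if (default && verifyChecksum &&
      !identical(unname(tools::md5sum(file)), .TABLE5_MD5))
    stop("fixture checksum mismatch for ", file)
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  out <- lapply(stats::setNames(.SYSTEMS, .SYSTEMS), function(s) {
    ds <- d[d$system == s, ]
    labels <- systemLabels(s)
    if (!identical(sort(ds$category), sort(labels)))
      stop("fixture categories for ", s, " incomplete")
    ds <- ds[match(labels, ds$category), ]
    contingencyTable(s, ds$cases, ds$controls)
  })
  out
}

.printedTable6 <- function()
  utils::read.csv(system.file("extdata", "table6_printed.csv",
                              package = "ctgtier"),
                  stringsAsFactors = FALSE)

.printedAUC <- function()
  utils::read.csv(system.file("extdata", "auc_printed.csv",
                              package = "ctgtier"),
                  stringsAsFactors = FALSE)

# cells of the printed diagnostics table that cannot be reproduced from
# the printed counts under any single polarity convention; "*" = whole row
.KNOWN_DISCREPANCIES <- data.frame(
  system = c("PARER", "NICHD", "FIGO", "PARER"),
  category = c("blue", "II", "pathological", "red"),
  metric = c("*", "*", "npv", "lr_neg"),
  note = c(
    "blue row not reproducible under any single polarity convention",
    "Category II specificity/LRs/PPV/NPV inconsistent with the counts",
    "printed 67.4%; counts give 36/57 = 63.2%",
    "printed 0.4; counts give (1-0.256)/1 = 0.74"))

.METRIC_MAP <- c(sensitivity = "sensitivity", specificity = "specificity",
                 lr_pos = "lrPositive", lr_neg = "lrNegative",
                 ppv = "ppv", npv = "npv")

#' Recompute the published diagnostics from the packaged counts
#'
#' From the packaged contingency tables this computes, per system, the
#' per-category diagnostic values and the ordinal AUC, and compares every
#' printed table cell and AUC with the recomputation. Proportions are
#' compared in percentage points (tolerance \code{tolProportion}),
#' likelihood ratios on their own scale (\code{tolRatio}), and AUCs after
#' rounding to the two printed decimals (\code{tolAUC}). Cells known to
#' be internally inconsistent in the printed table are annotated and fail
#' soft: they are flagged, not matched. There is no randomness anywhere
#' in this path, so the report is identical across runs.
#'
#' @param countsFile alternate counts CSV (see \code{\link{table5Counts}}).
#' @param tolProportion tolerance for percentages, percentage points.
#' @param tolRatio tolerance for likelihood ratios.
#' @param tolAUC tolerance for AUCs after rounding to 2 decimals.
#' @return list of class \code{ctgReproReport}: \code{tables} (counts),
#'   \code{diagnostics} (computed per system), \code{cells} (long
#'   comparison of every printed cell), \code{auc} (comparison of the
#'   four AUCs with analytic CIs), \code{knownDiscrepancies} and
#'   \code{unexplained} (non-annotated mismatches, if any).
#' @export
reproducePaper <- function(countsFile = NULL, tolProportion = 0.15,
                           tolRatio = 0.05, tolAUC = 0.005) {
  counts <- table5Counts(countsFile)
  printed <- .printedTable6()
  diagnostics <- lapply(counts, systemDiagnostics)
  cells <- NULL
  for (i in seq_len(nrow(printed))) {
    pr <- printed[i, ]
    comp <- diagnostics[[pr$system]]
    comp <- comp[comp$category == pr$category, ]
    for (mt in names(.METRIC_MAP)) {
      isProp <- !(mt %in% c("lr_pos", "lr_neg"))
      cv <- comp[[.METRIC_MAP[[mt]]]]
      if (isProp && !is.na(cv)) cv <- 100 * cv
      pv <- pr[[mt]]
      diff <- abs(cv - pv)
      match <- if (is.na(pv) || is.na(cv)) is.na(pv) && is.na(cv)
               else diff <= (if (isProp) tolProportion else tolRatio)
      known <- which(.KNOWN_DISCREPANCIES$system == pr$system &
                     .KNOWN_DISCREPANCIES$category == pr$category &
                     (.KNOWN_DISCREPANCIES$metric == mt |
                        .KNOWN_DISCREPANCIES$metric == "*"))
      cells <- rbind(cells, data.frame(
        system = pr$system, category = pr$category, metric = mt,
        computed = cv, printed = pv, difference = diff,
        match = match,
        knownDiscrepancy = length(known) > 0,
        note = if (length(known)) .KNOWN_DISCREPANCIES$note[known[1]]
               else ""))
    }
  }
  printedA <- .printedAUC()
  aucRows <- NULL
  for (i in seq_len(nrow(printedA))) {
    s <- printedA$system[i]
    res <- ordinalAUC(counts[[s]], ci = "hanley_mcneil")
    aucRows <- rbind(aucRows, data.frame(
      system = s, computed = res@auc,
      ciLow = res@ciLow, ciHigh = res@ciHigh,
      printed = printedA$auc[i],
      printedCiLow = printedA$ci_low[i],
      printedCiHigh = printedA$ci_high[i],
      match = abs(round(res@auc, 2) - printedA$auc[i]) <= tolAUC + 1e-12))
  }
  unexplained <- cells[!cells$match & !cells$knownDiscrepancy, ,
                       drop = FALSE]
  structure(list(tables = counts, diagnostics = diagnostics,
                 cells = cells, auc = aucRows,
                 knownDiscrepancies = .KNOWN_DISCREPANCIES,
                 unexplained = unexplained),
            class = "ctgReproReport")
}

#' @export
print.ctgReproReport <- function(x, ...) {
  cat("Reproduction report: per-category diagnostics and ordinal AUCs\n")
  cat(sprintf("  %d printed cells compared; %d match, %d known",
              nrow(x$cells), sum(x$cells$match),
              sum(x$cells$knownDiscrepancy)))
  cat(sprintf(" discrepancies, %d unexplained mismatch(es)\n",
              nrow(x$unexplained)))
  cat("  AUC (computed vs printed):\n")
  for (i in seq_len(nrow(x$auc)))
    cat(sprintf("    %-5s %.3f vs %.2f %s\n", x$auc$system[i],
                x$auc$computed[i], x$auc$printed[i],
                if (x$auc$match[i]) "" else "[MISMATCH]"))
  if (nrow(x$unexplained)) {
    cat("  unexplained cells:\n")
    for (i in seq_len(nrow(x$unexplained)))
      cat(sprintf("    %s %s %s: computed %.3g vs printed %.3g\n",
                  x$unexplained$system[i], x$unexplained$category[i],
                  x$unexplained$metric[i], x$unexplained$computed[i],
                  x$unexplained$printed[i]))
  }
  invisible(x)
}

#' Write a repro report as JSON
#'
#' @param report a \code{ctgReproReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReproReport <- function(report, path) {
  out <- list(schema = "ctgtier-repro/1",
              cells = report$cells, auc = report$auc,
              knownDiscrepancies = report$knownDiscrepancies,
              unexplained = report$unexplained)
  writeLines(jsonlite::toJSON(out, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, na = "null"),
             path)
  invisible(path)
}
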
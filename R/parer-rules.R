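# Parer-Ikeda colour matrix ------------------------------------------------
#
# The five-tier system maps (variability class, baseline class, worst
# deceleration) to a colour. The matrix shipped in inst/extdata/
# parer_rules.csv is reconstructed from the published three-variability-
# column layout (moderate / minimal / absent, plus marked variability as
# its own row). Several printed cells are garbled or missing in the
# source table; those cells default to the MORE severe adjacent colour
# (fail-safe direction for a clinical screening rule) and carry a note in
# the `note` column. `marked` variability is graded as at least yellow,
# otherwise following the moderate-variability column.

.PARER_COLOURS <- c("green", "blue", "yellow", "orange", "red")
.PARER_VARIABILITY <- c("moderate", "minimal", "absent", "marked")
.PARER_BASELINES <- c("normal", "tachycardia", "mild_bradycardia",
                      "moderate_bradycardia", "severe_bradycardia")
.PARER_DECELS <- c("none", "early",
                   "variable:mild", "variable:moderate", "variable:severe",
                   "late:mild", "late:moderate", "late:severe",
                   "prolonged:mild", "prolonged:moderate",
                   "prolonged:severe")

.parerColourOrdinal <- function(colour)
  match(colour, .PARER_COLOURS) - 1L

# canonical reconstruction used to generate the shipped CSV (and as the
# reference in tests); the CSV remains the editable artefact of record
.buildParerRuleTable <- function() {
  cell <- function(var, base, dec) {
    sev <- sub("^.*:", "", dec)
    type <- sub(":.*$", "", dec)
    if (var == "moderate") {
      switch(base,
        normal = switch(type,
          none = "green", early = "green",
          variable = c(mild = "green", moderate = "blue",
                       severe = "yellow")[[sev]],
          late = "yellow",
          prolonged = c(mild = "yellow", moderate = "yellow",
                        severe = "orange")[[sev]]),
        tachycardia = switch(type,
          none = "blue", early = "blue",
          variable = c(mild = "blue", moderate = "yellow",
                       severe = "orange")[[sev]],
          late = c(mild = "yellow", moderate = "yellow",
                   severe = "orange")[[sev]],
          prolonged = c(mild = "yellow", moderate = "yellow",
                        severe = "orange")[[sev]]),
        mild_bradycardia = switch(type,
          none = "yellow", early = "yellow",
          variable = , late = , prolonged =
            c(mild = "yellow", moderate = "yellow",
              severe = "orange")[[sev]]),
        moderate_bradycardia = switch(type,
          none = "yellow", early = "yellow",
          variable = , late = , prolonged = "orange"),
        severe_bradycardia = "orange")
    } else if (var == "minimal") {
      switch(base,
        normal = switch(type,
          none = "blue", early = "blue",
          variable = c(mild = "yellow", moderate = "orange",
                       severe = "orange")[[sev]],
          late = c(mild = "orange", moderate = "orange",
                   severe = "red")[[sev]],
          prolonged = c(mild = "orange", moderate = "orange",
                        severe = "red")[[sev]]),
        tachycardia = switch(type,
          none = "blue", early = "yellow",
          variable = c(mild = "yellow", moderate = "orange",
                       severe = "orange")[[sev]],
          late = c(mild = "orange", moderate = "orange",
                   severe = "red")[[sev]],
          prolonged = c(mild = "orange", moderate = "orange",
                        severe = "red")[[sev]]),
        # any bradycardia with minimal variability: decelerations -> red
        switch(type, none = "orange", early = "orange", "red"))
    } else if (var == "absent") {
      if (base == "normal" && type %in% c("none")) "orange" else "red"
    } else {                               # marked: at least yellow
      mod <- cell("moderate", base, dec)
      .PARER_COLOURS[max(.parerColourOrdinal(mod),
                         .parerColourOrdinal("yellow")) + 1L]
    }
  }
  grid <- expand.grid(variability = .PARER_VARIABILITY,
                      baseline = .PARER_BASELINES,
                      deceleration = .PARER_DECELS,
                      stringsAsFactors = FALSE)
  grid$colour <- mapply(cell, grid$variability, grid$baseline,
                        grid$deceleration)
  garbled <- with(grid,
    (variability == "moderate" & baseline == "normal" &
       deceleration == "late:mild") |
    (variability == "moderate" & baseline == "moderate_bradycardia" &
       !(deceleration %in% c("none", "early")) &
       !grepl("severe", deceleration)) |
    (variability == "absent" & baseline != "normal" &
       deceleration %in% c("none", "early")))
  grid$note <- ifelse(garbled,
                      "cell garbled/unlisted in source table; fail-safe severe",
                      "")
  grid[order(match(grid$variability, .PARER_VARIABILITY),
             match(grid$baseline, .PARER_BASELINES),
             match(grid$deceleration, .PARER_DECELS)), ]
}

#' Load the Parer-Ikeda colour rule table
#'
#' The matrix ships as an editable CSV keyed by variability class
#' (moderate 6-25 bpm, minimal < 6, absent < 2, marked > 25 bpm),
#' baseline class and worst deceleration (\code{type:severity} or
#' \code{none}/\code{early}); ambiguous cells of the published layout
#' default to the more severe colour and carry a provenance note.
#'
#' @param file path to a rule CSV; defaults to the packaged table.
#' @param validate check totality and severity monotonicity before
#'   returning (see \code{\link{validateParerRules}}).
#' @return data.frame with columns \code{variability}, \code{baseline},
#'   \code{deceleration}, \code{colour}, \code{note}.
#' @export
parerRuleTable <- function(file = system.file("extdata", "parer_rules.csv",
                                              package = "ctgtier"),
                           validate = TRUE) {
  tbl <- utils::read.csv(file, stringsAsFactors = FALSE)
  tbl$note[is.na(tbl$note)] <- ""
  if (validate) validateParerRules(tbl)
  tbl
}

#' Validate a Parer-Ikeda rule table
#'
#' Checks totality (every combination of variability class, baseline class
#' and deceleration key maps to exactly one colour) and severity
#' monotonicity (at fixed variability, baseline and deceleration type the
#' colour never improves as severity increases, and no deceleration maps
#' below the no-deceleration cell).
#'
#' @param rules data.frame as returned by \code{\link{parerRuleTable}}.
#' @return TRUE, invisibly; otherwise an error.
#' @export
validateParerRules <- function(rules) {
  need <- c("variability", "baseline", "deceleration", "colour")
  if (!all(need %in% names(rules)))
    stop("rule table lacks columns: ",
         paste(setdiff(need, names(rules)), collapse = ", "))
  if (!all(rules$colour %in% .PARER_COLOURS))
    stop("unknown colour(s): ",
         paste(setdiff(rules$colour, .PARER_COLOURS), collapse = ", "))
  key <- with(rules, paste(variability, baseline, deceleration))
  expect <- with(expand.grid(v = .PARER_VARIABILITY, b = .PARER_BASELINES,
                             d = .PARER_DECELS, stringsAsFactors = FALSE),
                 paste(v, b, d))
  if (anyDuplicated(key)) stop("duplicate rule cells")
  if (length(miss <- setdiff(expect, key)))
    stop("rule table not total; missing ", length(miss), " cell(s), e.g. ",
         miss[1])
  ord <- .parerColourOrdinal(rules$colour)
  names(ord) <- key
  for (v in .PARER_VARIABILITY) for (b in .PARER_BASELINES) {
    base <- ord[paste(v, b, "none")]
    for (tp in c("variable", "late", "prolonged")) {
      sev <- ord[paste(v, b, paste0(tp, ":", c("mild", "moderate",
                                               "severe")))]
      if (any(diff(sev) < 0))
        stop(sprintf("severity not monotone at %s/%s/%s", v, b, tp))
      if (any(sev < base))
        stop(sprintf("deceleration cell below 'none' at %s/%s/%s",
                     v, b, tp))
    }
    if (ord[paste(v, b, "early")] < base)
      stop(sprintf("early cell below 'none' at %s/%s", v, b))
  }
  invisible(TRUE)
}
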
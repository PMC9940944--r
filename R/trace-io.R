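#' Construct a paired CTG signal window
#'
#' @param fhr numeric FHR samples in bpm; \code{NA} marks signal loss.
#'   Values outside the physiologic guard rails 30-250 bpm are rejected;
#'   use \code{\link{readCTGTrace}} to coerce out-of-range file values to
#'   missing.
#' @param toco numeric uterine-activity samples (non-negative, arbitrary
#'   units); defaults to a flat zero channel of matching length.
#' @param samplingRate sampling rate in Hz, default 4 (conventional CTG
#'   acquisition rate).
#' @param startTime seconds from the start of the original recording to the
#'   first sample.
#' @return a \code{\linkS4class{CTGTrace}}.
#' @export
CTGTrace <- function(fhr, toco = NULL, samplingRate = 4, startTime = 0) {
  if (is.null(toco)) toco <- rep(0, length(fhr))
  new("CTGTrace", fhr = as.numeric(fhr), toco = as.numeric(toco),
      samplingRate = as.numeric(samplingRate),
      startTime = as.numeric(startTime))
}

#' @describeIn CTGTrace FHR channel accessor
#' @param x a \code{CTGTrace}
#' @export
fhr <- function(x) x@fhr

#' @describeIn CTGTrace toco channel accessor
#' @export
toco <- function(x) x@toco

#' @describeIn CTGTrace sampling rate (Hz)
#' @export
samplingRate <- function(x) x@samplingRate

#' @describeIn CTGTrace offset of the window within the recording (s)
#' @export
startTime <- function(x) x@startTime

#' @describeIn CTGTrace window length in seconds
#' @export
traceDuration <- function(x) length(x@fhr) / x@samplingRate

#' @describeIn CTGTrace fraction of missing FHR samples
#' @export
missingFraction <- function(x) mean(is.na(x@fhr))

# time of sample i relative to the window start
.timeAxis <- function(x) (seq_along(x@fhr) - 1) / x@samplingRate

setMethod("show", "CTGTrace", function(object) {
  cat(sprintf(
    "CTGTrace: %.1f min at %g Hz (%d samples), %.1f%% FHR missing\n",
    traceDuration(object) / 60, samplingRate(object),
    length(object@fhr), 100 * missingFraction(object)))
  f <- object@fhr[!is.na(object@fhr)]
  if (length(f))
    cat(sprintf("  FHR range %.0f-%.0f bpm, start offset %.0f s\n",
                min(f), max(f), object@startTime))
})

#' Read a delimited CTG recording
#'
#' Reads a plain-text recording with time, FHR and toco columns, rebuilds a
#' uniform timebase by nearest-neighbour placement onto the sample grid,
#' and coerces FHR values outside 30-250 bpm to missing (reported via a
#' message). Empty fields are missing.
#'
#' @param path file path; comma- or tab-delimited with a header.
#' @param columns named character vector mapping \code{time}, \code{fhr},
#'   \code{toco} to column names in the file.
#' @param samplingRate target rate in Hz; inferred from the median time
#'   step when \code{NULL}.
#' @return a \code{\linkS4class{CTGTrace}}.
#' @export
readCTGTrace <- function(path,
                         columns = c(time = "time_s", fhr = "fhr_bpm",
                                     toco = "toco"),
                         samplingRate = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         na.strings = c("", "NA"), check.names = FALSE)
  miss <- setdiff(columns[c("time", "fhr", "toco")], names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  tm <- d[[columns[["time"]]]]
  if (any(is.na(tm)) || any(diff(tm) <= 0))
    stop("non-monotone or missing time values in ", path)
  if (is.null(samplingRate)) {
    step <- stats::median(diff(tm))
    if (!is.finite(step) || step <= 0) stop("cannot infer sampling rate")
    samplingRate <- 1 / step
  }
  idx <- as.integer(round((tm - tm[1]) * samplingRate)) + 1L
  n <- max(idx)
  fhrv <- rep(NA_real_, n); tocov <- rep(NA_real_, n)
  fhrv[idx] <- d[[columns[["fhr"]]]]
  tocov[idx] <- d[[columns[["toco"]]]]
  out <- !is.na(fhrv) & (fhrv < 30 | fhrv > 250)
  if (any(out)) {
    message(sum(out), " FHR sample(s) outside 30-250 bpm marked missing")
    fhrv[out] <- NA_real_
  }
  tocov[!is.na(tocov) & tocov < 0] <- NA_real_
  tr <- CTGTrace(fhrv, tocov, samplingRate = samplingRate,
                 startTime = tm[1])
  if (missingFraction(tr) > 0.5)
    stop("signal unusable: more than 50% of FHR samples missing")
  tr
}

#' Write a CTG trace as delimited text
#'
#' Inverse of \code{\link{readCTGTrace}}: missing samples become empty
#' fields, so load-write-load is the identity on non-missing samples.
#'
#' @param trace a \code{CTGTrace}.
#' @param path output file path (CSV).
#' @return \code{path}, invisibly.
#' @export
writeCTGTrace <- function(trace, path) {
  d <- data.frame(time_s = trace@startTime + .timeAxis(trace),
                  fhr_bpm = trace@fhr, toco = trace@toco)
  utils::write.csv(d, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Interpolate short signal-loss gaps
#'
#' Gaps no longer than \code{maxGap} seconds with valid samples on both
#' sides are filled linearly; longer gaps (and gaps touching the window
#' edge) are preserved as missing. Non-missing samples are never altered.
#'
#' @param trace a \code{CTGTrace}.
#' @param maxGap maximum gap length to interpolate, seconds (default 15).
#' @return a \code{CTGTrace} with short gaps filled.
#' @export
fillGaps <- function(trace, maxGap = 15) {
  stopifnot(maxGap >= 0)
  x <- trace@fhr
  gaps <- .runs(is.na(x))
  if (!nrow(gaps)) return(trace)
  rate <- trace@samplingRate
  for (i in seq_len(nrow(gaps))) {
    s <- gaps$start[i]; e <- gaps$end[i]
    len <- (e - s + 1) / rate
    if (len > maxGap || s == 1L || e == length(x)) next
    x[s:e] <- x[s - 1L] + (x[e + 1L] - x[s - 1L]) *
      seq_len(e - s + 1L) / (e - s + 2L)
  }
  new("CTGTrace", fhr = x, toco = trace@toco,
      samplingRate = trace@samplingRate, startTime = trace@startTime)
}

#' Extract the trailing analysis window
#'
#' The classification convention analyses the last 30-60 minutes before
#' delivery, so the window is anchored to the end of the recording.
#'
#' @param trace a \code{CTGTrace}.
#' @param minutes window length in minutes, between 30 and 60 inclusive.
#' @return the trailing \code{minutes} of \code{trace}; \code{startTime}
#'   records the offset into the original recording.
#' @export
extractWindow <- function(trace, minutes = 60) {
  sec <- minutes * 60
  if (sec < 1800 || sec > 3600)
    stop("analysis window must be between 30 and 60 minutes")
  total <- traceDuration(trace)
  if (total < sec)
    stop(sprintf("recording (%.1f min) shorter than requested window (%g min)",
                 total / 60, minutes))
  n <- as.integer(round(sec * trace@samplingRate))
  keep <- (length(trace@fhr) - n + 1L):length(trace@fhr)
  new("CTGTrace", fhr = trace@fhr[keep], toco = trace@toco[keep],
      samplingRate = trace@samplingRate,
      startTime = trace@startTime + (total - sec))
}

#' Detect uterine contractions on the toco channel
#'
#' Contractions are contiguous episodes where the toco signal exceeds its
#' resting tone by a quarter of the observed dynamic range for at least
#' \code{minDuration} seconds; the peak is the maximum within the episode.
#'
#' @param trace a \code{CTGTrace}.
#' @param minDuration minimum episode length in seconds.
#' @return data.frame with columns \code{onset}, \code{peak}, \code{end}
#'   (seconds from window start), ordered and non-overlapping.
#' @export
detectContractions <- function(trace, minDuration = 20) {
  x <- trace@toco
  rate <- trace@samplingRate
  ok <- !is.na(x)
  if (!any(ok)) return(data.frame(onset = numeric(0), peak = numeric(0),
                                  end = numeric(0)))
  rest <- stats::quantile(x[ok], 0.1, names = FALSE)
  rng <- max(x[ok]) - rest
  if (rng < 5) return(data.frame(onset = numeric(0), peak = numeric(0),
                                 end = numeric(0)))
  thr <- rest + 0.25 * rng
  r <- .runs(!is.na(x) & x > thr)
  r <- r[(r$end - r$start + 1) / rate >= minDuration, , drop = FALSE]
  if (!nrow(r)) return(data.frame(onset = numeric(0), peak = numeric(0),
                                  end = numeric(0)))
  tvec <- .timeAxis(trace)
  peak <- vapply(seq_len(nrow(r)), function(i) {
    seg <- r$start[i]:r$end[i]
    tvec[seg[which.max(x[seg])]]
  }, numeric(1))
  data.frame(onset = tvec[r$start], peak = peak,
             end = tvec[r$end] + 1 / rate)
}
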
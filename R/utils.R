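# internal helpers shared across modules

# runs of TRUE in a logical vector -> data.frame(start, end) of 1-based
# inclusive indices; NA counts as FALSE
.runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# round half up to the nearest multiple of `to`
.round5 <- function(x, to = 5) to * floor(x / to + 0.5)

.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.matchSystem <- function(system) {
  m <- match.arg(toupper(system), .SYSTEMS)
  m
}

# longest run (in elements) of TRUE in a logical vector
.maxRun <- function(x) {
  if (!length(x)) return(0L)
  r <- .runs(x)
  if (!nrow(r)) 0L else max(r$end - r$start + 1L)
}

.trapezoid <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
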
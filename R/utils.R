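# internal helpers shared across modules

# Lower weighted median: smallest x whose cumulative weight reaches half the
# total.  Used for baselines and locus summaries; robust to <=50% aberrant mass.
weightedMedian <- function(x, w) {
  stopifnot(length(x) == length(w))
  if (length(x) == 0L) stop("weightedMedian: empty input")
  if (any(!is.finite(x)) || any(!is.finite(w)) || any(w < 0)) {
    stop("weightedMedian: weights must be non-negative and values finite")
  }
  o <- order(x)
  x <- x[o]
  cw <- cumsum(as.numeric(w[o]))
  x[which(cw >= cw[length(cw)] / 2)[1L]]
}

isProb <- function(p) is.numeric(p) && all(is.finite(p)) && all(p >= 0) && all(p <= 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix so callers can grep stage failures
mbStop <- function(..., call. = FALSE) stop(..., call. = call.)
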
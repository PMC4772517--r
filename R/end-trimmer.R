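#' Sliding-window masking of low-quality read ends
#'
#' Step 1 of the detector. Windows are examined inward from the 5' end: while
#' a window's mean quality is below the threshold all of its positions are
#' marked and scanning advances; the first window at or above the threshold
#' stops the scan. The same procedure runs inward from the 3' end. Only a
#' contiguous prefix and/or suffix can ever be marked; marked positions are
#' converted to N downstream rather than physically cut, so later steps see
#' one unified mask set.
#'
#' @param qual integer vector of Phred scores for one read, or a single-read
#'   [fastq()] object.
#' @param window window length in bases (default 5). A window longer than the
#'   read treats the whole read as one window.
#' @param threshold mean-quality threshold (default 20).
#' @param step advance between successive windows; defaults to `window`
#'   (non-overlapping windows).
#' @return Sorted integer vector of masked positions (1-based), a prefix
#'   and/or suffix of the read, possibly empty.
#' @examples
#' sliding_window_mask(c(2, 2, 2, rep(30, 7)), window = 3, threshold = 20)
#' @export
sliding_window_mask <- function(qual, window = 5L, threshold = 20,
                                step = window) {
  if (inherits(qual, "fastq")) {
    stopifnot(length(qual) == 1L)
    qual <- qual$qual[[1L]]
  }
  stopifnot(window >= 1L, step >= 1L)
  L <- length(qual)
  if (L == 0L) return(integer(0))
  w <- min(window, L)
  prefix <- .scan_end(qual, w, threshold, step)
  suffix <- .scan_end(rev(qual), w, threshold, step)
  sort(unique(c(prefix, L + 1L - suffix)))
}

# Scan from the start of `qual`; return masked positions (prefix).
.scan_end <- function(qual, w, threshold, step) {
  L <- length(qual)
  hi <- 0L
  s <- 1L
  while (s <= L) {
    e <- min(s + w - 1L, L)
    if (mean(qual[s:e]) < threshold) {
      hi <- max(hi, e)
      s <- s + step
    } else {
      break
    }
  }
  seq_len(hi)
}
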
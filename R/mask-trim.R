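#' Mask detected positions to N
#'
#' Replaces the base at every detected position with `N` and sets its quality
#' to zero, preserving read coordinates. All other positions are untouched.
#'
#' @param x a [fastq()] object.
#' @param positions list of integer position vectors (1-based), one per read;
#'   a plain vector is accepted for a single-read set.
#' @return A [fastq()] object of the same shape with masked bases.
#' @examples
#' fq <- fastq("r1", "ACGT", list(c(30L, 30L, 30L, 30L)))
#' apply_mask(fq, list(2L))$seq  # "ANGT"
#' @export
apply_mask <- function(x, positions) {
  stopifnot(inherits(x, "fastq"))
  if (!is.list(positions)) positions <- list(positions)
  stopifnot(length(positions) == length(x))
  for (i in seq_len(length(x))) {
    p <- positions[[i]]
    if (!length(p)) next
    if (any(p < 1L) || any(p > nchar(x$seq[i]))) {
      stop("mask position out of range in read ", i, " ('", x$id[i], "')")
    }
    ch <- strsplit(x$seq[i], "", fixed = TRUE)[[1L]]
    ch[p] <- "N"
    x$seq[i] <- paste(ch, collapse = "")
    x$qual[[i]][p] <- 0L
  }
  x
}

#' Trim terminal N runs and enforce a minimum length
#'
#' Removes the maximal run of N at the 5' end and at the 3' end of every read
#' (whether planted by masking or present in the input). Reads whose
#' remainder is shorter than `min_len` are discarded.
#'
#' @param x a [fastq()] object (typically after [apply_mask()]).
#' @param min_len minimum surviving length in bases (default 50).
#' @param strict if `TRUE`, require length strictly greater than `min_len`
#'   instead of at least `min_len`.
#' @return A list: `reads` (the surviving, trimmed [fastq()]), `kept`
#'   (logical per input read), `trimmed_bases` (total bases removed from the
#'   survivors).
#' @export
trim_terminal_ns <- function(x, min_len = 50L, strict = FALSE) {
  stopifnot(inherits(x, "fastq"))
  lead <- attr(regexpr("^N*", x$seq), "match.length")
  trail <- attr(regexpr("N*$", x$seq), "match.length")
  L <- nchar(x$seq)
  start <- lead + 1L
  end <- L - trail
  core <- pmax(end - start + 1L, 0L)
  kept <- if (strict) core > min_len else core >= min_len
  reads <- x[kept]
  if (any(kept)) {
    reads$seq <- substr(reads$seq, start[kept], end[kept])
    reads$qual <- mapply(function(q, s, e) q[s:e], reads$qual,
                         start[kept], end[kept], SIMPLIFY = FALSE)
  }
  list(reads = reads, kept = kept,
       trimmed_bases = sum((L - core)[kept]))
}

#' Split reads at interior Ns, keeping the longest fragment
#'
#' Cuts each read at every remaining N and retains the single longest N-free
#' fragment (the 5'-most on ties), with its quality substring, subject to the
#' same minimum-length rule. Intended to run after [trim_terminal_ns()];
#' outputs contain no N at all.
#'
#' @inheritParams trim_terminal_ns
#' @param annotate if `TRUE`, append `"|start-end"` (1-based original
#'   coordinates within the trimmed read) to the identifier of reads that
#'   were actually split.
#' @return Same structure as [trim_terminal_ns()].
#' @export
split_at_internal_ns <- function(x, min_len = 50L, strict = FALSE,
                                 annotate = FALSE) {
  stopifnot(inherits(x, "fastq"))
  n <- length(x)
  kept <- logical(n)
  starts <- integer(n)
  ends <- integer(n)
  for (i in seq_len(n)) {
    m <- gregexpr("[^N]+", x$seq[i])[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    best <- which.max(len)  # which.max takes the first maximum: 5'-most
    frag <- len[best]
    if (if (strict) frag > min_len else frag >= min_len) {
      kept[i] <- TRUE
      starts[i] <- m[best]
      ends[i] <- m[best] + frag - 1L
    }
  }
  reads <- x[kept]
  if (any(kept)) {
    was_split <- (starts[kept] > 1L | ends[kept] < nchar(reads$seq))
    reads$seq <- substr(reads$seq, starts[kept], ends[kept])
    reads$qual <- mapply(function(q, s, e) q[s:e], reads$qual,
                         starts[kept], ends[kept], SIMPLIFY = FALSE)
    if (annotate) {
      reads$id[was_split] <- paste0(reads$id[was_split], "|",
                                    starts[kept][was_split], "-",
                                    ends[kept][was_split])
    }
  }
  list(reads = reads, kept = kept,
       trimmed_bases = sum(nchar(x$seq[kept])) - sum(nchar(reads$seq)))
}

#' Route trimmed mates to paired, unpaired or discarded outputs
#'
#' @param kept1,kept2 logical vectors: whether each R1 / R2 mate survived
#'   trimming.
#' @return Character vector per pair: `"paired"` (both survived), `"unpaired"`
#'   (exactly one), `"discarded"` (neither).
#' @export
route_pair <- function(kept1, kept2) {
  stopifnot(length(kept1) == length(kept2))
  ifelse(kept1 & kept2, "paired",
         ifelse(kept1 | kept2, "unpaired", "discarded"))
}
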
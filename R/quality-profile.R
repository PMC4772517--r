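#' Convert a Phred quality score to an error probability
#'
#' Implements the standard Phred relation `P = 10^(-Q/10)`.
#'
#' @param q numeric vector of non-negative Phred scores.
#' @return Numeric vector of base-call error probabilities.
#' @examples
#' phred_to_error_prob(c(0, 10, 30))  # 1, 0.1, 0.001
#' @export
phred_to_error_prob <- function(q) {
  if (any(q < 0)) stop("Phred scores must be non-negative")
  10^(-q / 10)
}

#' Reservoir-sample reads from a stream or set
#'
#' Uniform sampling without replacement of `min(k, total)` records in a single
#' pass (Algorithm R), so arbitrarily large files can be sampled without
#' loading them. Deterministic for a fixed seed.
#'
#' @param x a [fastq()] object, or a character vector of FASTQ paths which are
#'   streamed and pooled in order.
#' @param k target sample size (>= 1).
#' @param seed integer RNG seed (default 42).
#' @param offset quality offset for file input; `NULL` auto-detects per file.
#' @param buffer records read per I/O burst when streaming files.
#' @return A [fastq()] object of `min(k, total)` records.
#' @export
sample_reads <- function(x, k, seed = 42L, offset = NULL, buffer = 10000L) {
  stopifnot(k >= 1L)
  set.seed(seed)
  if (inherits(x, "fastq")) {
    if (!length(x)) stop("cannot sample from an empty read set")
    return(.reservoir_update(NULL, x, k)$sample)
  }
  res <- NULL
  for (path in x) {
    off <- if (is.null(offset)) detect_quality_encoding(path) else offset
    st <- .fastq_stream(path, off)
    repeat {
      chunk <- st$read(buffer)
      if (!length(chunk)) break
      res <- .reservoir_update(res, chunk, k)
    }
    st$close()
  }
  if (is.null(res) || !res$seen) stop("cannot sample from an empty read set")
  res$sample
}

# One reservoir pass over `chunk`. `state` is NULL or list(sample, seen).
.reservoir_update <- function(state, chunk, k) {
  if (is.null(state)) state <- list(sample = chunk[integer(0)], seen = 0L)
  sample <- state$sample
  seen <- state$seen
  for (i in seq_len(length(chunk))) {
    seen <- seen + 1L
    if (length(sample) < k) {
      sample <- c(sample, chunk[i])
    } else {
      j <- sample.int(seen, 1L)
      if (j <= k) {
        sample$id[j] <- chunk$id[i]
        sample$seq[j] <- chunk$seq[i]
        sample$qual[[j]] <- chunk$qual[[i]]
      }
    }
  }
  list(sample = sample, seen = seen)
}

#' Build the position-specific quality-score profile of a run
#'
#' Tallies, for every read position (1-based from the 5' end), the histogram
#' of Phred scores observed across the sampled reads, plus per-position mean,
#' minimum, maximum and population standard deviation. This profile is the
#' baseline every detection threshold is measured against: a score is judged
#' by where it falls inside its own position's distribution, not against a
#' fixed cutoff.
#'
#' @param reads a [fastq()] object of sampled reads (at least one).
#' @return An object of class `"quality_profile"` with components `counts`
#'   (positions x 94 matrix, column j = count of score j-1), `n`, `mean`,
#'   `min`, `max`, `sd` (per-position vectors) and `max_len`.
#' @seealso [percentile_below()], [sample_reads()], [write_profile()]
#' @export
build_profile <- function(reads) {
  stopifnot(inherits(reads, "fastq"))
  if (!length(reads)) stop("cannot profile an empty read set")
  lens <- lengths(reads$qual)
  max_len <- max(lens)
  pos <- sequence(lens)
  q <- unlist(reads$qual, use.names = FALSE)
  counts <- matrix(tabulate(q * max_len + pos, nbins = 94L * max_len),
                   nrow = max_len, ncol = 94L)
  n <- as.integer(rowSums(counts))
  qv <- 0:93
  mean <- as.numeric(counts %*% qv) / n
  ex2 <- as.numeric(counts %*% qv^2) / n
  sd <- sqrt(pmax(ex2 - mean^2, 0))
  nonzero <- counts > 0L
  min <- apply(nonzero, 1L, function(r) which(r)[1L]) - 1L
  max <- 94L - apply(nonzero[, 94:1, drop = FALSE], 1L, function(r) which(r)[1L])
  # cumulative counts strictly below each score: pbelow[p, q + 1] in [0, 1]
  below <- cbind(0, t(apply(counts, 1L, cumsum))[, 1:93, drop = FALSE])
  structure(list(counts = counts, n = n, mean = mean, min = as.integer(min),
                 max = as.integer(max), sd = sd, max_len = max_len,
                 pbelow = below / n),
            class = "quality_profile")
}

#' @export
print.quality_profile <- function(x, ...) {
  cat("quality_profile:", x$max_len, "positions,", x$n[1L],
      "reads sampled at position 1\n")
  cat(sprintf("  mean quality %.1f-%.1f, overall range [%d, %d]\n",
              min(x$mean), max(x$mean), min(x$min), max(x$max)))
  invisible(x)
}

#' Fraction of sampled scores strictly below a score
#'
#' The percentile semantics of the whole detector: `percentile_below(p, i, q)`
#' is the fraction of sampled scores at position `i` that are strictly less
#' than `q`. "Above the median" therefore means a fraction > 0.5, and ties at
#' a threshold do not pass it.
#'
#' @param profile a [build_profile()] result.
#' @param pos integer position(s), 1-based; must not exceed `profile$max_len`.
#' @param q integer Phred score(s), recycled against `pos`.
#' @return Numeric fraction(s) in `[0, 1]`.
#' @export
percentile_below <- function(profile, pos, q) {
  stopifnot(inherits(profile, "quality_profile"))
  if (any(pos < 1L) || any(pos > profile$max_len)) {
    stop("position out of profiled range [1, ", profile$max_len, "]")
  }
  k <- pmin(pmax(as.integer(q), 0L), 93L)
  profile$pbelow[cbind(as.integer(pos), k + 1L)]
}

# Internal lookup used by the detector: positions beyond the profiled length
# fall back to the last profiled position's distribution.
.pb_lookup <- function(profile, pos, q) {
  over <- pos > profile$max_len
  if (any(over)) pos[over] <- profile$max_len
  k <- pmin(pmax(as.integer(q), 0L), 93L)
  list(pb = profile$pbelow[cbind(pos, k + 1L)], clamped = any(over))
}

#' Export a quality profile as a tab-separated table
#'
#' One row per position: `position`, `n`, `mean`, `min`, `max`, `sd`, and the
#' histogram as comma-separated `q:count` pairs, so profiling and detection
#' can run as separate steps.
#'
#' @param profile a [build_profile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  hist <- apply(profile$counts, 1L, function(r) {
    nz <- which(r > 0L)
    paste0(nz - 1L, ":", r[nz], collapse = ",")
  })
  df <- data.frame(position = seq_len(profile$max_len), n = profile$n,
                   mean = profile$mean, min = profile$min, max = profile$max,
                   sd = profile$sd, hist = hist)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a quality profile written by [write_profile()]
#'
#' @param path path to the tab-separated profile table.
#' @return A `"quality_profile"` object.
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  max_len <- nrow(df)
  counts <- matrix(0L, nrow = max_len, ncol = 94L)
  for (i in seq_len(max_len)) {
    pairs <- strsplit(strsplit(df$hist[i], ",", fixed = TRUE)[[1L]], ":",
                      fixed = TRUE)
    for (p in pairs) counts[i, as.integer(p[1L]) + 1L] <- as.integer(p[2L])
  }
  below <- cbind(0, t(apply(counts, 1L, cumsum))[, 1:93, drop = FALSE])
  structure(list(counts = counts, n = as.integer(df$n), mean = df$mean,
                 min = as.integer(df$min), max = as.integer(df$max),
                 sd = df$sd, max_len = max_len, pbelow = below / df$n),
            class = "quality_profile")
}
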
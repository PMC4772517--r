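#' Simulation parameters for Illumina-like reads with planted errors
#'
#' The defaults emulate a modern Illumina run: a high quality plateau with a
#' linear 3' decay over the final third of the read, Gaussian per-base noise,
#' and planted substitution errors whose own quality is strongly depressed
#' and whose +/-1 and +/-2 neighbors are mildly depressed relative to the run
#' average -- the local signature the detector exploits.
#'
#' @param n_reads number of reads (default 10,000).
#' @param read_len read length in bases (default 100).
#' @param base_mean_curve per-position mean quality; `NULL` (default) uses a
#'   plateau at 37 over the first two thirds decaying linearly to 25 at the
#'   3' end.
#' @param qual_sd Gaussian quality noise standard deviation (default 4).
#' @param error_rate per-base planted-substitution probability (default 0.01).
#' @param error_qual_drop mean-quality depression at planted error positions
#'   (default 22).
#' @param neighbor_qual_drop depression at the +/-1 and +/-2 neighbors of a
#'   planted error (default 10); not stacked when neighborhoods overlap, and
#'   an error position always takes the error drop.
#' @param gc_content G+C fraction of the random sequence (default 0.5).
#' @param qual_min,qual_max truncation range for drawn qualities (defaults 2
#'   and 41, the usual Illumina score range).
#' @param seed RNG seed (default 42).
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(n_reads = 10000L, read_len = 100L,
                       base_mean_curve = NULL, qual_sd = 4,
                       error_rate = 0.01, error_qual_drop = 22,
                       neighbor_qual_drop = 10, gc_content = 0.5,
                       qual_min = 2L, qual_max = 41L, seed = 42L) {
  if (is.null(base_mean_curve)) {
    base_mean_curve <- default_mean_curve(read_len)
  }
  stopifnot(n_reads >= 1L, read_len >= 1L,
            length(base_mean_curve) == read_len,
            error_rate >= 0, error_rate <= 1,
            error_qual_drop >= 0, neighbor_qual_drop >= 0,
            gc_content >= 0, gc_content <= 1,
            qual_min >= 0L, qual_max <= 93L, qual_min <= qual_max)
  structure(list(n_reads = as.integer(n_reads),
                 read_len = as.integer(read_len),
                 base_mean_curve = base_mean_curve, qual_sd = qual_sd,
                 error_rate = error_rate, error_qual_drop = error_qual_drop,
                 neighbor_qual_drop = neighbor_qual_drop,
                 gc_content = gc_content, qual_min = as.integer(qual_min),
                 qual_max = as.integer(qual_max), seed = as.integer(seed)),
            class = "sim_params")
}

#' Default per-position mean-quality curve
#'
#' Plateau at `plateau` over the first two thirds of the read, then linear
#' decay to `floor` at the 3' end.
#'
#' @param read_len read length.
#' @param plateau plateau mean quality (default 37).
#' @param floor 3'-end mean quality (default 25).
#' @return Numeric vector of length `read_len`.
#' @export
default_mean_curve <- function(read_len, plateau = 37, floor = 25) {
  knee <- ceiling(2 * read_len / 3)
  c(rep(plateau, knee),
    if (read_len > knee) {
      plateau + (floor - plateau) * seq_len(read_len - knee) /
        (read_len - knee)
    })
}

#' Simulate reads with planted substitution errors
#'
#' Sequences are random (reference-free): detection uses only qualities and
#' positions, never base identity. Qualities are drawn as rounded Gaussians
#' around the mean curve, truncated to `[qual_min, qual_max]`; at planted
#' errors the mean is lowered by `error_qual_drop` and at their +/-1, +/-2
#' neighbors by `neighbor_qual_drop`. Planted errors substitute the base for
#' a different one. Deterministic for a fixed seed.
#'
#' @param params a [sim_params()] object.
#' @return A list: `reads` (a [fastq()] object) and `truth` (a list of sorted
#'   1-based planted-error position vectors, one per read).
#' @export
simulate_reads <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  nr <- params$n_reads
  L <- params$read_len
  err <- matrix(stats::runif(nr * L) < params$error_rate, nr, L)
  neigh <- matrix(FALSE, nr, L)
  for (m in c(-2L, -1L, 1L, 2L)) {
    src <- seq_len(L) - m
    ok <- src >= 1L & src <= L
    neigh[, ok] <- neigh[, ok] | err[, src[ok]]
  }
  mu <- matrix(params$base_mean_curve, nr, L, byrow = TRUE)
  mu[neigh] <- mu[neigh] - params$neighbor_qual_drop
  mu[err] <- matrix(params$base_mean_curve, nr, L, byrow = TRUE)[err] -
    params$error_qual_drop
  qual <- round(stats::rnorm(nr * L, mean = as.vector(mu), sd = params$qual_sd))
  qual <- matrix(pmin(pmax(qual, params$qual_min), params$qual_max), nr, L)
  gc <- params$gc_content
  bases <- c("A", "C", "G", "T")
  pr <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  base_idx <- matrix(sample.int(4L, nr * L, replace = TRUE, prob = pr), nr, L)
  # substitute planted errors with one of the three other bases
  ne <- sum(err)
  if (ne) {
    shift <- sample.int(3L, ne, replace = TRUE)
    base_idx[err] <- ((base_idx[err] - 1L + shift) %% 4L) + 1L
  }
  seqs <- apply(base_idx, 1L, function(r) paste(bases[r], collapse = ""))
  reads <- fastq(sprintf("sim_%d", seq_len(nr)), seqs,
                 lapply(seq_len(nr), function(i) as.integer(qual[i, ])))
  truth <- lapply(seq_len(nr), function(i) which(err[i, ]))
  list(reads = reads, truth = truth)
}

#' Write / read a planted-error truth table
#'
#' Tab-separated: read identifier, then comma-separated 1-based error
#' positions (empty field for an error-free read).
#'
#' @param truth list of integer position vectors.
#' @param ids read identifiers, same length as `truth`.
#' @param path file path.
#' @return `path` invisibly, or for the reader a named list of integer
#'   vectors.
#' @export
write_truth <- function(truth, ids, path) {
  stopifnot(length(truth) == length(ids))
  lines <- paste0(ids, "\t",
                  vapply(truth, function(p) paste(p, collapse = ","), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  truth <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2L])) integer(0)
    else as.integer(strsplit(p[2L], ",", fixed = TRUE)[[1L]])
  })
  names(truth) <- vapply(parts, `[[`, "", 1L)
  truth
}

#' Per-position evaluation of detected against planted errors
#'
#' For every read position, counts detected planted errors (TP), detections
#' at correct bases (FP) and missed planted errors (FN), and derives the
#' three headline fractions: the true positive rate `TP / (TP + FN)`, the
#' fraction of calls that are wrong `FP / (TP + FP)`, and the fraction of
#' reads covering the position with a false call `FP / covered`. Fractions
#' with a zero denominator are `NA`.
#'
#' @param predictions list of detected position vectors, one per read.
#' @param truth list of planted-error position vectors over the same reads,
#'   in the same order.
#' @param lens integer read lengths (for per-position coverage).
#' @return A data frame with columns `position`, `covered`, `tp`, `fp`, `fn`,
#'   `tpr`, `fp_frac_calls`, `fp_frac_reads`.
#' @export
evaluate_detection <- function(predictions, truth, lens) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth cover different read sets (",
         length(predictions), " vs ", length(truth), " reads)")
  }
  stopifnot(length(lens) == length(truth))
  max_len <- max(lens)
  key <- function(pos_list) {
    ri <- rep.int(seq_along(pos_list), lengths(pos_list))
    (ri - 1) * max_len + unlist(pos_list, use.names = FALSE)
  }
  pk <- key(predictions)
  tk <- key(truth)
  pos_of <- function(k) as.integer((k - 1) %% max_len) + 1L
  tp_k <- pk[pk %in% tk]
  fp_k <- pk[!pk %in% tk]
  fn_k <- tk[!tk %in% pk]
  tp <- tabulate(pos_of(tp_k), max_len)
  fp <- tabulate(pos_of(fp_k), max_len)
  fn <- tabulate(pos_of(fn_k), max_len)
  covered <- vapply(seq_len(max_len), function(p) sum(lens >= p), 0L)
  frac <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(position = seq_len(max_len), covered = covered,
             tp = tp, fp = fp, fn = fn,
             tpr = frac(tp, tp + fn),
             fp_frac_calls = frac(fp, tp + fp),
             fp_frac_reads = frac(fp, covered))
}

#' Naive single-base quality-threshold detector
#'
#' The comparator every conventional trimmer reduces to: flag a base purely
#' because its own quality is below a fixed cutoff, ignoring position and
#' neighborhood.
#'
#' @param x a [fastq()] object.
#' @param q_cutoff flag positions with quality strictly below this value.
#' @return A list of integer position vectors, one per read.
#' @export
baseline_threshold_detector <- function(x, q_cutoff) {
  stopifnot(inherits(x, "fastq"))
  lapply(x$qual, function(q) which(q < q_cutoff))
}

#' Choose the baseline cutoff matching a target call volume
#'
#' Sweeps every integer cutoff and returns the one whose total number of
#' flagged bases over `x` is closest to `target_calls` (ties to the lower
#' cutoff), enabling like-for-like comparison with the full detector.
#'
#' @param x a [fastq()] object.
#' @param target_calls desired total number of flagged bases.
#' @return Integer cutoff for [baseline_threshold_detector()].
#' @export
match_call_volume <- function(x, target_calls) {
  q <- unlist(x$qual, use.names = FALSE)
  h <- tabulate(q + 1L, nbins = 94L)
  calls <- c(0, cumsum(h))  # calls[c + 1] = number of bases with Q < c
  cutoff <- which.min(abs(calls - target_calls)) - 1L
  cutoff
}
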
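#' Detection parameters with their defaults
#'
#' Bundles every tunable threshold of the three-step detector.
#'
#' Step 2 calls a base correct when more than `correct_pct` of the sampled
#' scores at its position lie strictly below it (default 0.5: above the
#' positional median), and calls it an error outright when fewer than
#' `error_pct` do (default 0: never automatic). Step 3 examines the remaining
#' candidates: all usable neighbors within `neighbors` positions must dominate
#' the base by at least `1/ratio_max` (default 0.4, i.e. 2.5-fold), and must
#' themselves sit within the bottom `neighbor_pct` (default 0.3) of their own
#' positional distributions.
#'
#' @param correct_pct step-2 automatic-correct percentile, fraction in
#'   `[0, 1]` (default 0.5).
#' @param error_pct step-2 automatic-error percentile (default 0, i.e. no
#'   base is ever auto-called an error).
#' @param ratio_max step-3 upper bound on the quality ratio Q_i / Q_neighbor
#'   (default 0.4).
#' @param neighbors number of upstream and downstream neighbor positions
#'   examined (default 2).
#' @param neighbor_pct step-3 bottom-percentile bound for neighbor scores
#'   (default 0.3).
#' @param min_len minimum surviving read length in bases (default 50).
#' @param window,window_qual step-1 sliding-window length and mean-quality
#'   threshold (defaults 5 and 20); see [sliding_window_mask()].
#' @param chunk_size reads per processing chunk (default 4,000,000).
#' @param sample_cap maximum reads sampled for the profile (default
#'   10,000,000).
#' @param seed RNG seed for profile sampling (default 42).
#' @return An object of class `"detection_params"`.
#' @export
detection_params <- function(correct_pct = 0.5, error_pct = 0,
                             ratio_max = 0.4, neighbors = 2L,
                             neighbor_pct = 0.3, min_len = 50L,
                             window = 5L, window_qual = 20,
                             chunk_size = 4000000L, sample_cap = 10000000L,
                             seed = 42L) {
  stopifnot(error_pct >= 0, error_pct <= correct_pct, correct_pct <= 1,
            ratio_max > 0, neighbors >= 1L,
            neighbor_pct >= 0, neighbor_pct <= 1,
            min_len >= 1L, window >= 1L, chunk_size >= 1L, sample_cap >= 1L)
  structure(list(correct_pct = correct_pct, error_pct = error_pct,
                 ratio_max = ratio_max, neighbors = as.integer(neighbors),
                 neighbor_pct = neighbor_pct, min_len = as.integer(min_len),
                 window = as.integer(window), window_qual = window_qual,
                 chunk_size = as.integer(chunk_size),
                 sample_cap = as.integer(sample_cap), seed = as.integer(seed)),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("detection_params:\n")
  cat(sprintf("  step 1: window %d, mean-quality threshold %g\n",
              x$window, x$window_qual))
  cat(sprintf("  step 2: correct above %.0f%%, auto-error below %.0f%%\n",
              100 * x$correct_pct, 100 * x$error_pct))
  cat(sprintf("  step 3: ratio <= %g over +/-%d neighbors, all in bottom %.0f%%\n",
              x$ratio_max, x$neighbors, 100 * x$neighbor_pct))
  cat(sprintf("  min length %d bp, chunk %d reads, sample cap %d, seed %d\n",
              x$min_len, x$chunk_size, x$sample_cap, x$seed))
  invisible(x)
}

#' Step-2 classification of every base against the run profile
#'
#' Position i is `CORRECT` when `percentile_below(profile, i, Q_i)` exceeds
#' `correct_pct`, `ERROR` when it is below `error_pct`, otherwise `CANDIDATE`.
#' Comparisons are strict, so a base exactly at the median is a candidate.
#' Positions masked by step 1 are labelled `MASKED` and take no further part.
#'
#' @param x a [fastq()] object.
#' @param profile a [build_profile()] result.
#' @param params a [detection_params()] object.
#' @param masked optional list (one integer vector per read) of step-1 masked
#'   positions; `NULL` classifies every position.
#' @return A list of character vectors, one per read, each element one of
#'   `"CORRECT"`, `"ERROR"`, `"CANDIDATE"`, `"MASKED"`.
#' @export
classify_step2 <- function(x, profile, params = detection_params(),
                           masked = NULL) {
  stopifnot(inherits(x, "fastq"))
  clamped <- FALSE
  out <- vector("list", length(x))
  for (i in seq_len(length(x))) {
    q <- x$qual[[i]]
    lk <- .pb_lookup(profile, seq_along(q), q)
    clamped <- clamped || lk$clamped
    st <- rep("CANDIDATE", length(q))
    st[lk$pb > params$correct_pct] <- "CORRECT"
    st[lk$pb < params$error_pct] <- "ERROR"
    if (!is.null(masked)) st[masked[[i]]] <- "MASKED"
    out[[i]] <- st
  }
  if (clamped) {
    warning("reads longer than the profiled length; positions beyond ",
            profile$max_len, " use the last profiled position's distribution")
  }
  out
}

#' Step-3 quality-ratio criterion for one candidate position
#'
#' Passes when, for every usable neighbor within `params$neighbors` positions,
#' the ratio `Q_pos / Q_neighbor` is at most `params$ratio_max` (all neighbors
#' at least 2.5-fold higher at the default 0.4). Neighbors beyond the read
#' ends or masked in step 1 are skipped; a zero-quality neighbor fails the
#' criterion unless the examined base also has quality zero; a candidate with
#' no usable neighbor at all fails.
#'
#' @param qual integer quality vector of one read.
#' @param pos 1-based candidate position.
#' @param params a [detection_params()] object.
#' @param masked integer vector of step-1 masked positions (skipped as
#'   neighbors).
#' @return `TRUE` (pass) or `FALSE`.
#' @export
ratio_criterion <- function(qual, pos, params = detection_params(),
                            masked = integer(0)) {
  nb <- .usable_neighbors(length(qual), pos, params$neighbors, masked)
  if (!length(nb)) return(FALSE)
  qp <- qual[pos]
  qn <- qual[nb]
  all(ifelse(qn > 0L, qp / qn <= params$ratio_max, qp == 0L))
}

#' Step-3 neighbor-percentile criterion for one candidate position
#'
#' Passes when every usable neighbor's quality lies strictly within the bottom
#' `params$neighbor_pct` of the distribution at the neighbor's own position
#' (`percentile_below < neighbor_pct`). A candidate with no usable neighbor
#' fails.
#'
#' @inheritParams ratio_criterion
#' @param profile a [build_profile()] result.
#' @return `TRUE` (pass) or `FALSE`.
#' @export
neighbor_percentile_criterion <- function(qual, pos, profile,
                                          params = detection_params(),
                                          masked = integer(0)) {
  nb <- .usable_neighbors(length(qual), pos, params$neighbors, masked)
  if (!length(nb)) return(FALSE)
  pb <- .pb_lookup(profile, nb, qual[nb])$pb
  all(pb < params$neighbor_pct)
}

.usable_neighbors <- function(L, pos, n, masked) {
  nb <- pos + c(-(n:1), 1:n)
  nb <- nb[nb >= 1L & nb <= L]
  setdiff(nb, masked)
}

# Full three-step evaluation of one read. Returns per-step position sets and
# whether any position fell beyond the profiled length.
.detect_read <- function(q, profile, params) {
  L <- length(q)
  s1 <- sliding_window_mask(q, params$window, params$window_qual)
  masked <- logical(L)
  masked[s1] <- TRUE
  lk <- .pb_lookup(profile, seq_len(L), q)
  pb <- lk$pb
  state <- rep("CANDIDATE", L)
  state[pb > params$correct_pct] <- "CORRECT"
  state[pb < params$error_pct] <- "ERROR"
  state[masked] <- "MASKED"
  s2 <- which(state == "ERROR")
  cand <- state == "CANDIDATE"
  s3 <- integer(0)
  if (any(cand)) {
    idx <- seq_len(L)
    ratio_all <- rep(TRUE, L)
    pct_all <- rep(TRUE, L)
    any_nb <- rep(FALSE, L)
    for (m in c(-(params$neighbors:1), 1:params$neighbors)) {
      j <- idx + m
      ok <- j >= 1L & j <= L
      jj <- ifelse(ok, j, 1L)
      use <- ok & !masked[jj]
      qn <- q[jj]
      r_ok <- ifelse(qn > 0L, q / qn <= params$ratio_max, q == 0L)
      p_ok <- pb[jj] < params$neighbor_pct
      ratio_all <- ratio_all & (!use | r_ok)
      pct_all <- pct_all & (!use | p_ok)
      any_nb <- any_nb | use
    }
    s3 <- which(cand & any_nb & ratio_all & pct_all)
  }
  list(step1 = s1, step2 = s2, step3 = s3, clamped = lk$clamped)
}

#' Detect erroneous base positions in reads
#'
#' Runs the three sequential steps on each read: (1) sliding-window end
#' masking, (2) percentile classification of every unmasked base against the
#' run profile, (3) the quality-ratio and neighbor-percentile criteria on the
#' surviving candidates. A candidate is called an error only when it passes
#' both step-3 criteria; step-2 `CORRECT` positions are never re-examined.
#'
#' @param x a [fastq()] object.
#' @param profile a [build_profile()] result for the same run.
#' @param params a [detection_params()] object.
#' @param detail if `TRUE`, return per-step position sets per read instead of
#'   the flat union.
#' @return A list with one sorted integer vector of detected positions per
#'   read (the union of step-1 masks, step-2 auto-errors and step-3 calls),
#'   or, with `detail = TRUE`, a list of lists with components `step1`,
#'   `step2`, `step3`.
#' @export
detect_errors <- function(x, profile, params = detection_params(),
                          detail = FALSE) {
  stopifnot(inherits(x, "fastq"), inherits(profile, "quality_profile"))
  clamped <- FALSE
  out <- vector("list", length(x))
  for (i in seq_len(length(x))) {
    d <- .detect_read(x$qual[[i]], profile, params)
    clamped <- clamped || d$clamped
    out[[i]] <- if (detail) {
      d[c("step1", "step2", "step3")]
    } else {
      sort(unique(c(d$step1, d$step2, d$step3)))
    }
  }
  if (clamped) {
    warning("reads longer than the profiled length; positions beyond ",
            profile$max_len, " use the last profiled position's distribution")
  }
  out
}
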
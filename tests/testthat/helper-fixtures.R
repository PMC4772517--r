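# Shared fixtures and a naive, independent re-implementation of the
# detection rules used as an oracle. The oracle works from raw per-position
# score vectors with explicit loops -- no histograms, no vectorization -- so
# that it shares no code path with the package.

make_reads <- function(quals, seq_char = "A") {
  quals <- lapply(quals, as.integer)
  fastq(id = sprintf("r%d", seq_along(quals)),
        seq = vapply(quals, function(q) strrep(seq_char, length(q)), ""),
        qual = quals)
}

# Uniform random reads over a fixed set of quality levels.
random_level_reads <- function(n, len_range, levels, seed) {
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  make_reads(lapply(lens, function(L) sample(levels, L, replace = TRUE)))
}

# Raw per-position score lists for the oracle, from the same reads a profile
# is built from.
scores_by_position <- function(reads) {
  max_len <- max(lengths(reads$qual))
  lapply(seq_len(max_len), function(p) {
    v <- vapply(reads$qual, function(q) if (length(q) >= p) q[p] else NA_integer_,
                integer(1))
    v[!is.na(v)]
  })
}

naive_pb <- function(pos_scores, p, q) {
  s <- pos_scores[[min(p, length(pos_scores))]]
  sum(s < q) / length(s)
}

naive_end_mask <- function(qual, window, threshold, step = window) {
  scan <- function(v) {
    L <- length(v)
    w <- min(window, L)
    out <- integer(0)
    s <- 1
    while (s <= L) {
      e <- min(s + w - 1, L)
      if (sum(v[s:e]) / (e - s + 1) < threshold) {
        out <- union(out, s:e)
        s <- s + step
      } else break
    }
    out
  }
  L <- length(qual)
  sort(unique(as.integer(c(scan(qual), (L + 1) - scan(rev(qual))))))
}

# Full three-step rule evaluation for one read, written as literal loops.
naive_detect <- function(qual, pos_scores, params) {
  L <- length(qual)
  masked <- naive_end_mask(qual, params$window, params$window_qual)
  out <- integer(0)
  for (i in seq_len(L)) {
    if (i %in% masked) {
      out <- c(out, i)
      next
    }
    f <- naive_pb(pos_scores, i, qual[i])
    if (f > params$correct_pct) next
    if (f < params$error_pct) {
      out <- c(out, i)
      next
    }
    nbs <- setdiff(intersect((i - params$neighbors):(i + params$neighbors),
                             seq_len(L)),
                   c(i, masked))
    if (length(nbs) == 0) next
    ok <- TRUE
    for (j in nbs) {
      r <- if (qual[j] > 0) qual[i] / qual[j] else if (qual[i] == 0) 0 else Inf
      if (!(r <= params$ratio_max)) ok <- FALSE
      if (!(naive_pb(pos_scores, j, qual[j]) < params$neighbor_pct)) ok <- FALSE
    }
    if (ok) out <- c(out, i)
  }
  sort(unique(out))
}

write_tmp_fastq <- function(reads, name = "tmp.fastq") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  write_fastq(reads, path)
  path
}
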
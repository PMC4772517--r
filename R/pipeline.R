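#' Full run configuration
#'
#' @param input1 path to the (first) FASTQ file, plain or gzip.
#' @param input2 optional path to the synchronized mate file.
#' @param out_prefix prefix for every output file.
#' @param params a [detection_params()] object.
#' @param threads worker count for chunk processing (default 1). Results are
#'   byte-identical for any thread count.
#' @param split_at_n split reads at interior Ns, keeping the longest fragment.
#' @param keep_untrimmed emit full-length masked reads and skip trimming.
#' @param strict_len require surviving length strictly greater than
#'   `params$min_len` instead of at least it.
#' @param offset quality encoding offset, `33`, `64`, or `NULL` to
#'   auto-detect from the first 10,000 records.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input1, input2 = NULL, out_prefix,
                       params = detection_params(), threads = 1L,
                       split_at_n = FALSE, keep_untrimmed = FALSE,
                       strict_len = FALSE, offset = NULL) {
  stopifnot(threads >= 1L)
  if (!is.null(offset) && !offset %in% c(33L, 64L)) {
    stop("offset must be 33, 64 or NULL")
  }
  structure(list(input1 = input1, input2 = input2, out_prefix = out_prefix,
                 params = params, threads = as.integer(threads),
                 split_at_n = isTRUE(split_at_n),
                 keep_untrimmed = isTRUE(keep_untrimmed),
                 strict_len = isTRUE(strict_len), offset = offset),
            class = "run_config")
}

#' Split a read count into ordered chunks
#'
#' @param n total number of records (pairs count as one unit in paired mode).
#' @param chunk_size records per chunk (default 4,000,000).
#' @return A list of consecutive 1-based index vectors; the final chunk may be
#'   short; zero records give an empty list.
#' @export
chunk_dataset <- function(n, chunk_size = 4000000L) {
  stopifnot(chunk_size >= 1L)
  if (n == 0L) return(list())
  starts <- seq.int(1L, n, by = chunk_size)
  lapply(starts, function(s) seq.int(s, min(s + chunk_size - 1L, n)))
}

# Detect + mask + trim one block of reads. Returns trimmed reads, kept flags
# and per-step counters.
.process_block <- function(reads, profile, params, split_at_n, keep_untrimmed,
                           strict_len) {
  det <- suppressWarnings(detect_errors(reads, profile, params, detail = TRUE))
  s1 <- lengths(lapply(det, `[[`, "step1"))
  s2 <- lengths(lapply(det, `[[`, "step2"))
  s3 <- lengths(lapply(det, `[[`, "step3"))
  all_pos <- lapply(det, function(d) unique(c(d$step1, d$step2, d$step3)))
  masked <- apply_mask(reads, all_pos)
  if (keep_untrimmed) {
    tr <- list(reads = masked, kept = rep(TRUE, length(masked)),
               trimmed_bases = 0L)
  } else {
    tr <- trim_terminal_ns(masked, params$min_len, strict = strict_len)
    if (split_at_n) {
      sp <- split_at_internal_ns(tr$reads, params$min_len,
                                 strict = strict_len)
      kept <- tr$kept
      kept[kept] <- sp$kept
      tr <- list(reads = sp$reads, kept = kept,
                 trimmed_bases = tr$trimmed_bases + sp$trimmed_bases)
    }
  }
  list(reads = tr$reads, kept = tr$kept, trimmed_bases = tr$trimmed_bases,
       masked_step1 = sum(s1), masked_step2 = sum(s2), masked_step3 = sum(s3))
}

#' Run the full detection and trimming pipeline
#'
#' Builds the position-specific quality profile once from a global reservoir
#' sample of all input files pooled, then streams the input in chunks of
#' `params$chunk_size` reads (pairs as a unit), processing every chunk
#' against that same profile and writing outputs in input order. The result
#' is a pure function of input bytes, configuration and seed: chunk size and
#' thread count never change a single output byte.
#'
#' Outputs, for a paired run with prefix `P`: `P.1.trimmed.fastq`,
#' `P.2.trimmed.fastq`, `P.unpaired.trimmed.fastq`, `P.discarded.ids.txt`,
#' `P.stats.tsv`, `P.log`. A single-end run writes `P.trimmed.fastq` instead
#' of the first three. Output FASTQ is always Phred+33.
#'
#' @param config a [run_config()] object.
#' @return Invisibly, a list with `stats` (named counters), `profile` and
#'   `files` (output paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  paired <- !is.null(config$input2)
  prefix <- config$out_prefix
  logf <- paste0(prefix, ".log")
  cat("", file = logf)
  log_line <- function(...) cat(..., "\n", sep = "", file = logf,
                                append = TRUE)
  log_line("adeptr pipeline")
  log_line("input1: ", config$input1)
  if (paired) log_line("input2: ", config$input2)
  log_line("seed: ", p$seed)
  log_line("params: correct_pct=", p$correct_pct, " error_pct=", p$error_pct,
           " ratio_max=", p$ratio_max, " neighbors=", p$neighbors,
           " neighbor_pct=", p$neighbor_pct, " min_len=", p$min_len,
           " window=", p$window, " window_qual=", p$window_qual,
           " chunk_size=", p$chunk_size, " sample_cap=", p$sample_cap)

  offset <- config$offset
  if (is.null(offset)) {
    offset <- tryCatch(detect_quality_encoding(config$input1),
                       error = function(e) 33L)
  }
  log_line("quality encoding: Phred+", offset)

  files <- if (paired) {
    list(out1 = paste0(prefix, ".1.trimmed.fastq"),
         out2 = paste0(prefix, ".2.trimmed.fastq"),
         unpaired = paste0(prefix, ".unpaired.trimmed.fastq"),
         discarded = paste0(prefix, ".discarded.ids.txt"),
         stats = paste0(prefix, ".stats.tsv"), log = logf)
  } else {
    list(out = paste0(prefix, ".trimmed.fastq"),
         discarded = paste0(prefix, ".discarded.ids.txt"),
         stats = paste0(prefix, ".stats.tsv"), log = logf)
  }
  for (f in setdiff(unlist(files), logf)) cat("", file = f)

  inputs <- c(config$input1, if (paired) config$input2)
  profile <- tryCatch(
    sample_reads(inputs, k = p$sample_cap, seed = p$seed, offset = offset),
    error = function(e) NULL
  )
  stats <- c(reads_in = 0L, reads_paired_out = 0L, reads_unpaired_out = 0L,
             reads_discarded = 0L, bases_in = 0L, bases_out = 0L,
             bases_masked_step1 = 0L, bases_masked_step2 = 0L,
             bases_masked_step3 = 0L, bases_trimmed = 0L)
  if (is.null(profile)) {
    warning("empty input; writing empty outputs")
    log_line("empty input")
    .write_stats(stats, files$stats)
    return(invisible(list(stats = stats, profile = NULL, files = files)))
  }
  profile <- build_profile(profile)
  log_line("profile: ", profile$max_len, " positions, ", profile$n[1L],
           " reads sampled")

  st1 <- .fastq_stream(config$input1, offset)
  st2 <- if (paired) .fastq_stream(config$input2, offset)
  on.exit({
    st1$close()
    if (paired) st2$close()
  })

  process <- function(reads) {
    blocks <- chunk_dataset(length(reads),
                            max(1L, ceiling(length(reads) / config$threads)))
    res <- parallel::mclapply(blocks, function(ix) {
      .process_block(reads[ix], profile, p, config$split_at_n,
                     config$keep_untrimmed, config$strict_len)
    }, mc.cores = config$threads)
    list(reads = do.call(c, lapply(res, `[[`, "reads")),
         kept = unlist(lapply(res, `[[`, "kept")),
         trimmed_bases = sum(vapply(res, `[[`, 0L, "trimmed_bases")),
         s1 = sum(vapply(res, `[[`, 0L, "masked_step1")),
         s2 = sum(vapply(res, `[[`, 0L, "masked_step2")),
         s3 = sum(vapply(res, `[[`, 0L, "masked_step3")))
  }

  repeat {
    r1 <- st1$read(p$chunk_size)
    if (paired) {
      r2 <- st2$read(p$chunk_size)
      if (length(r1) != length(r2)) {
        stop("paired input files have unequal record counts; pairing broken ",
             "after record ", stats[["reads_in"]] + min(length(r1), length(r2)))
      }
    }
    if (!length(r1)) break
    a <- process(r1)
    stats[["reads_in"]] <- stats[["reads_in"]] + length(r1) * (1L + paired)
    stats[["bases_in"]] <- stats[["bases_in"]] + sum(nchar(r1$seq))
    stats[["bases_masked_step1"]] <- stats[["bases_masked_step1"]] + a$s1
    stats[["bases_masked_step2"]] <- stats[["bases_masked_step2"]] + a$s2
    stats[["bases_masked_step3"]] <- stats[["bases_masked_step3"]] + a$s3
    stats[["bases_trimmed"]] <- stats[["bases_trimmed"]] + a$trimmed_bases
    if (paired) {
      b <- process(r2)
      stats[["bases_in"]] <- stats[["bases_in"]] + sum(nchar(r2$seq))
      stats[["bases_masked_step1"]] <- stats[["bases_masked_step1"]] + b$s1
      stats[["bases_masked_step2"]] <- stats[["bases_masked_step2"]] + b$s2
      stats[["bases_masked_step3"]] <- stats[["bases_masked_step3"]] + b$s3
      stats[["bases_trimmed"]] <- stats[["bases_trimmed"]] + b$trimmed_bases
      route <- route_pair(a$kept, b$kept)
      pair_ok <- route == "paired"
      write_fastq(a$reads[pair_ok[a$kept]], files$out1, append = TRUE)
      write_fastq(b$reads[pair_ok[b$kept]], files$out2, append = TRUE)
      orphan1 <- a$reads[(route == "unpaired" & a$kept)[a$kept]]
      orphan2 <- b$reads[(route == "unpaired" & b$kept)[b$kept]]
      write_fastq(c(orphan1, orphan2), files$unpaired, append = TRUE)
      disc <- c(r1$id[!a$kept], r2$id[!b$kept])
      if (length(disc)) {
        cat(disc, sep = "\n", file = files$discarded, append = TRUE)
      }
      stats[["reads_paired_out"]] <- stats[["reads_paired_out"]] +
        2L * sum(pair_ok)
      stats[["reads_unpaired_out"]] <- stats[["reads_unpaired_out"]] +
        length(orphan1) + length(orphan2)
      stats[["reads_discarded"]] <- stats[["reads_discarded"]] + length(disc)
      stats[["bases_out"]] <- stats[["bases_out"]] +
        sum(nchar(a$reads$seq[pair_ok[a$kept]])) +
        sum(nchar(b$reads$seq[pair_ok[b$kept]])) +
        sum(nchar(orphan1$seq)) + sum(nchar(orphan2$seq))
    } else {
      write_fastq(a$reads, files$out, append = TRUE)
      if (any(!a$kept)) {
        cat(r1$id[!a$kept], sep = "\n", file = files$discarded, append = TRUE)
      }
      stats[["reads_paired_out"]] <- stats[["reads_paired_out"]] +
        length(a$reads)
      stats[["reads_discarded"]] <- stats[["reads_discarded"]] +
        sum(!a$kept)
      stats[["bases_out"]] <- stats[["bases_out"]] + sum(nchar(a$reads$seq))
    }
  }
  log_line("reads in: ", stats[["reads_in"]])
  log_line("masked bases step1/step2/step3: ", stats[["bases_masked_step1"]],
           "/", stats[["bases_masked_step2"]], "/",
           stats[["bases_masked_step3"]])
  log_line("reads out (paired/single): ", stats[["reads_paired_out"]],
           ", unpaired: ", stats[["reads_unpaired_out"]],
           ", discarded: ", stats[["reads_discarded"]])
  .write_stats(stats, files$stats)
  invisible(list(stats = stats, profile = profile, files = files))
}

.write_stats <- function(stats, path) {
  utils::write.table(data.frame(metric = names(stats),
                                value = as.integer(stats)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
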
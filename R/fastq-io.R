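#' Construct a set of FASTQ records
#'
#' The central read container of the package. It is columnar: identifiers and
#' sequences are character vectors, qualities a list of integer Phred score
#' vectors (one per read, already decoded, i.e. offset-free).
#'
#' @param id character vector of read identifiers, without the leading `"@"`.
#'   Identifiers are carried verbatim, including any `"/1"`/`"/2"` or comment
#'   suffix.
#' @param seq character vector of base strings.
#' @param qual list of integer vectors of Phred scores, one per read, each the
#'   same length as the corresponding sequence, every score in `[0, 93]`.
#' @param mate integer mate tag for the whole set: `NA` (unknown/single-end),
#'   `1L` or `2L`.
#' @return An object of class `"fastq"`.
#' @examples
#' fq <- fastq(c("r1", "r2"), c("ACGT", "GGA"),
#'             list(c(40L, 40L, 40L, 2L), c(30L, 30L, 30L)))
#' length(fq)
#' @export
fastq <- function(id = character(), seq = character(), qual = list(),
                  mate = NA_integer_) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (length(seq)) {
    if (any(!nzchar(seq))) {
      stop("empty sequence in record ", which(!nzchar(seq))[1L])
    }
    lens <- nchar(seq)
    qlens <- lengths(qual)
    if (any(lens != qlens)) {
      bad <- which(lens != qlens)[1L]
      stop("record ", bad, ": sequence length (", lens[bad],
           ") != number of quality scores (", qlens[bad], ")")
    }
    rng <- range(unlist(qual, use.names = FALSE))
    if (rng[1L] < 0L || rng[2L] > 93L) {
      stop("quality scores outside [0, 93]; wrong encoding offset?")
    }
  }
  structure(list(id = as.character(id), seq = toupper(as.character(seq)),
                 qual = lapply(qual, as.integer), mate = as.integer(mate)),
            class = "fastq")
}

#' @export
length.fastq <- function(x) length(x$id)

#' @export
`[.fastq` <- function(x, i) {
  structure(list(id = x$id[i], seq = x$seq[i], qual = x$qual[i],
                 mate = x$mate), class = "fastq")
}

#' @export
print.fastq <- function(x, ...) {
  cat("fastq set:", length(x), "read(s)")
  if (!is.na(x$mate)) cat(", mate", x$mate)
  cat("\n")
  if (length(x)) {
    n <- min(3L, length(x))
    for (i in seq_len(n)) {
      cat(sprintf("  @%s  %s...  [%d bp]\n", x$id[i],
                  substr(x$seq[i], 1L, 20L), nchar(x$seq[i])))
    }
    if (length(x) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Concatenate fastq sets
#' @param ... `"fastq"` objects.
#' @return A single `"fastq"` object, records in argument order.
#' @export
c.fastq <- function(...) {
  xs <- list(...)
  structure(list(id = unlist(lapply(xs, `[[`, "id"), use.names = FALSE),
                 seq = unlist(lapply(xs, `[[`, "seq"), use.names = FALSE),
                 qual = do.call(c, lapply(xs, `[[`, "qual")),
                 mate = xs[[1L]]$mate),
            class = "fastq")
}

# Parse 4-line FASTQ text into a fastq object. `first_ordinal` is the 1-based
# ordinal of the first record in the originating file, used in error messages.
.parse_fastq_lines <- function(lines, offset, first_ordinal = 1L) {
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", length(lines),
         " lines is not a multiple of 4 (around record ",
         first_ordinal + length(lines) %/% 4L, ")")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(fastq())
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qstr <- lines[seq(4L, by = 4L, length.out = n)]
  ord <- function(i) first_ordinal + i - 1L
  if (any(bad <- !startsWith(hdr, "@"))) {
    stop("malformed FASTQ record ", ord(which(bad)[1L]),
         ": header does not start with '@'")
  }
  if (any(bad <- !startsWith(plus, "+"))) {
    stop("malformed FASTQ record ", ord(which(bad)[1L]),
         ": separator line does not start with '+'")
  }
  if (any(bad <- nchar(seq) != nchar(qstr))) {
    stop("malformed FASTQ record ", ord(which(bad)[1L]),
         ": sequence and quality strings differ in length")
  }
  if (any(bad <- !nzchar(seq))) {
    stop("malformed FASTQ record ", ord(which(bad)[1L]), ": empty sequence")
  }
  qual <- lapply(qstr, function(s) utf8ToInt(s) - offset)
  fastq(substring(hdr, 2L), seq, qual)
}

#' Read a FASTQ file
#'
#' Reads a 4-line-per-record FASTQ file, plain or gzip-compressed, decoding
#' quality characters as `code point - offset`.
#'
#' @param path path to a FASTQ file (`.gz` accepted).
#' @param offset quality encoding offset, `33` or `64`; `NULL` (default)
#'   auto-detects from the first records via [detect_quality_encoding()].
#' @param n maximum number of records to read (default all).
#' @return A [fastq()] object, records in file order.
#' @seealso [write_fastq()], [read_fastq_pair()]
#' @export
read_fastq <- function(path, offset = NULL, n = Inf) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  nl <- if (is.finite(n)) 4L * n else -1L
  lines <- readLines(con, n = nl)
  if (is.null(offset)) {
    nq <- min(length(lines) %/% 4L, 10000L)
    offset <- if (nq == 0L) 33L else {
      .detect_encoding_from_strings(lines[seq(4L, by = 4L, length.out = nq)])
    }
  }
  .parse_fastq_lines(lines, offset)
}

#' Read a synchronized pair of FASTQ files
#'
#' Pairing is positional: record n of the first file is mated with record n of
#' the second. Files of unequal record count are a fatal error.
#'
#' @inheritParams read_fastq
#' @param path1,path2 paths to the R1 and R2 FASTQ files.
#' @return A list with elements `r1` and `r2`, both [fastq()] objects with
#'   `mate` set to 1 and 2.
#' @export
read_fastq_pair <- function(path1, path2, offset = NULL) {
  r1 <- read_fastq(path1, offset = offset)
  r2 <- read_fastq(path2, offset = offset)
  if (length(r1) != length(r2)) {
    stop("paired FASTQ files have unequal record counts (",
         length(r1), " vs ", length(r2), "); pairing broken after record ",
         min(length(r1), length(r2)))
  }
  r1$mate <- 1L
  r2$mate <- 2L
  list(r1 = r1, r2 = r2)
}

#' Write a FASTQ file
#'
#' Output is always Phred+33, the modern standard, regardless of the input
#' encoding.
#'
#' @param x a [fastq()] object.
#' @param path output path (plain text; a `.gz` suffix writes gzip).
#' @param append append to `path` instead of truncating.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path, append = FALSE) {
  lines <- character(4L * length(x))
  if (length(x)) {
    lines[seq(1L, by = 4L, length.out = length(x))] <- paste0("@", x$id)
    lines[seq(2L, by = 4L, length.out = length(x))] <- x$seq
    lines[seq(3L, by = 4L, length.out = length(x))] <- "+"
    lines[seq(4L, by = 4L, length.out = length(x))] <-
      vapply(x$qual, function(q) intToUtf8(q + 33L), character(1))
  }
  con <- if (grepl("\\.gz$", path)) {
    gzfile(path, if (append) "ab" else "wb")
  } else {
    file(path, if (append) "ab" else "wb")
  }
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

.detect_encoding_from_strings <- function(qstrings) {
  if (!length(qstrings) || !any(nzchar(qstrings))) {
    stop("cannot detect quality encoding from an empty stream")
  }
  codes <- utf8ToInt(paste(qstrings, collapse = ""))
  if (any(codes < 59L)) return(33L)
  if (min(codes) >= 64L && max(codes) > 74L) return(64L)
  warning("quality characters all in the ambiguous 59-74 range; ",
          "assuming Phred+33")
  33L
}

#' Detect the quality-score encoding of a FASTQ file
#'
#' Inspects the quality characters of the first records: any code point below
#' 59 implies Phred+33; all code points at or above 64 with at least one above
#' 74 implies Phred+64; an entirely ambiguous range falls back to Phred+33
#' with a warning.
#'
#' @param path path to a FASTQ file (`.gz` accepted).
#' @param n_records number of leading records to inspect (default 10000).
#' @return `33L` or `64L`.
#' @export
detect_quality_encoding <- function(path, n_records = 10000L) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, n = 4L * n_records)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count not a multiple of 4")
  }
  qlines <- lines[seq(4L, by = 4L, length.out = length(lines) %/% 4L)]
  .detect_encoding_from_strings(qlines)
}

# Streaming chunk reader over one FASTQ file. Returns a closure environment;
# $read(n) yields the next n records as a fastq object (possibly fewer at EOF,
# zero-length at exhaustion), $close() releases the connection.
.fastq_stream <- function(path, offset) {
  con <- gzfile(path, "rt")
  ordinal <- 1L
  list(
    read = function(n) {
      lines <- readLines(con, n = 4L * n)
      x <- .parse_fastq_lines(lines, offset, first_ordinal = ordinal)
      ordinal <<- ordinal + length(x)
      x
    },
    close = function() close(con)
  )
}
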
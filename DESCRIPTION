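Package: adeptr
Title: Dataset-Adaptive Error Detection and Trimming for Illumina Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects likely sequencing errors in Illumina FASTQ data by
    comparing each base's Phred quality score, and the scores of its two
    upstream and two downstream neighbors, against the position-specific
    quality-score distribution of the sequencing run itself. Flagged bases
    are masked to N, reads are end-trimmed with a sliding window, trimmed of
    terminal Ns, optionally split at interior Ns, filtered on a minimum
    length, and paired-end mates are kept synchronized with orphan routing.
    Includes a reference-free read simulator with planted substitution
    errors carrying the depressed-neighbor quality signature, and
    per-position true/false discovery evaluation of any detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
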
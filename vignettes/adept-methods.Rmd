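---
title: "Dataset-adaptive error detection: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dataset-adaptive error detection: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adeptr)
```

## The model

Illumina quality scores nominally encode the base-call error probability
`P = 10^(-Q/10)` (`phred_to_error_prob()`), but in practice they are poorly
calibrated and position-dependent: scores drift downward toward the 3' end
of the read, and large numbers of correctly called bases receive low scores.
Two empirical observations motivate a dataset-adaptive detector:

* the score distribution at a given read position is a property of the run,
  so a base should be ranked within the distribution *of its own position in
  its own run*, not against a universal cutoff;
* true sequencing errors depress not only the score of the miscalled base
  but also, more mildly, the scores of the one or two flanking cycles, so
  the local quality landscape carries signal that a single-base threshold
  cannot see.

The detector therefore works on the empirical percentile

> `pb(i, Q)` = fraction of sampled scores at position `i` strictly below `Q`

and on the neighbor ratio `R = Q_i / Q_{i±m}`. All percentile comparisons
are strict: "above the median" means `pb > 0.5`, so a base exactly at the
median does not auto-pass, and a neighbor exactly at the bottom-30 %
boundary fails the band. Ties thus always break toward *fewer* error calls,
the conservative direction that the 0 % auto-error default also signals.

## The three steps

1. **End masking** (`sliding_window_mask`). Windows of `window` bases
   (default 5) are tested inward from each end; while a window's mean
   quality is below `window_qual` (default 20) its positions are marked and
   the scan advances by one window; the first passing window stops the scan.
   Windows advance by their own length: successive failing windows tile the
   end without overlap, so the masked set is always a contiguous prefix
   and/or suffix and a single interior dip is never reached. Marked
   positions are recorded as masks (converted to `N` downstream) rather than
   physically cut, so steps 2–3 and final trimming see one unified mask set.
2. **Percentile classification** (`classify_step2`). Each unmasked base is
   `CORRECT` if `pb > correct_pct` (default 0.5), `ERROR` if
   `pb < error_pct` (default 0 — with strict comparison nothing is ever
   auto-called), else `CANDIDATE`.
3. **Neighborhood criteria** (`ratio_criterion`,
   `neighbor_percentile_criterion`). A candidate is promoted to error only
   when *every* usable neighbor within `neighbors` positions (default 2 per
   side) satisfies both `Q_i / Q_n ≤ ratio_max` (default 0.4, i.e. 2.5-fold
   dominance) and `pb(n, Q_n) < neighbor_pct` (default 0.3).

Neighbor usability at boundaries: neighbors beyond the read ends simply do
not exist, and step-1-masked neighbors are *skipped* — a masked base carries
no evidence either way, and its conceptual quality of zero would make the
ratio undefined. If one side has no usable neighbor the other side decides
alone; a candidate with no usable neighbor at all is not called (again the
conservative direction — such positions sit at read ends that step 1 already
polices). An unmasked neighbor with `Q = 0` fails the ratio criterion
(ratio treated as infinite) unless the candidate itself has `Q = 0`, in
which case all ratios are zero: a zero-quality neighbor cannot testify that
the *center* base is locally anomalous.

Relaxing any of `ratio_max`, `neighbor_pct`, `error_pct` or `correct_pct`
can only grow the detected set; the test suite checks this monotonicity
property, and checks the whole rule system against an independently written
brute-force oracle on small instances.

## The run profile

`sample_reads()` draws a uniform sample without replacement in a single
streaming pass (reservoir algorithm R), capped at `sample_cap` reads
(default 10,000,000 — in practice whole desk-scale inputs). One unified
sample feeds both the per-position summary statistics (mean, minimum,
maximum, population SD) and the detection baseline; maintaining a second,
smaller sample for the summaries would only discard data. Sampling is the
pipeline's sole source of randomness; the seed (default 42) is logged and
overridable. With paired input, both files are pooled before sampling.

`build_profile()` stores a full per-position histogram over scores 0–93, so
`percentile_below()` is an exact count, not an approximation. Positions
beyond the longest sampled read fall back to the last profiled position's
distribution, with a warning. Profiles round-trip through a tab-separated
text export (`write_profile`/`read_profile`) so profiling and detection can
run as separate steps.

## Trimming and routing

Detected positions become `N` with quality 0 (`apply_mask`). Terminal `N`
runs are then trimmed, and reads shorter than `min_len` are discarded.
`min_len` (default 50 bp) is inclusive — a read of exactly 50 bases
survives — with `strict_len` available for the exclusive reading. Optional
splitting at interior `N`s keeps the single longest fragment, the 5'-most on
ties (deterministic, and quality typically decays 3'-ward); split-mode
output contains no `N` at all, while default output keeps interior `N`s with
quality 0. For pairs, both-kept reads go to the synchronized paired outputs,
single survivors to an unpaired file, and identifiers of dropped reads to a
discard list, so `paired + unpaired + discarded` always equals the input
count per mate.

`run_pipeline()` builds the profile once, then streams the input in chunks
of `chunk_size` reads (default 4,000,000; pairs count as one unit),
processing each chunk against that same fixed profile, optionally on
several workers. Because per-read results depend only on the read and the
profile, chunk size and thread count are guaranteed not to change a single
output byte; the tests assert byte-identity. Output FASTQ is always
Phred+33; +64 input is detected automatically (any quality code point below
59 implies +33; all at/above 64 with some above 74 implies +64; a wholly
ambiguous file falls back to +33 with a warning).

## The simulator

`simulate_reads()` emulates the quality structure the detector relies on,
not a sequencing instrument. Sequences are random and reference-free —
detection never looks at base identity, so alignment adds nothing. Per-base
qualities are rounded Gaussians (SD `qual_sd`, default 4) around a mean
curve with a plateau of 37 over the first two thirds and a linear decay to
25 at the 3' end, truncated to `[2, 41]`, the usual Illumina range. Planted
substitutions (rate 0.01) lower the drawn mean by 22 at the error and by 10
at its ±1/±2 neighbors, reproducing the ordering *errors ≪ neighbors < run
average*; overlapping neighborhoods do not stack, and an error position
always takes the error drop. These values are plausible rather than fitted
to any particular instrument.

What the simulator deliberately does **not** reproduce is score
mis-calibration: correct bases essentially never receive error-like scores
here, whereas on real runs most low scores sit on correct bases (which is
why real-data false-call fractions are high for every tool in this family).
Consequently a plain quality threshold is unrealistically strong on these
simulations, and passing tests demonstrate that the rule system behaves as
specified — not that the detector will beat simpler tools on any particular
real dataset.

`evaluate_detection()` reports per-position TP/FP/FN with the three derived
fractions: TPR, false calls over all calls, and false calls over reads
covering the position (two FP denominators, selectable by column). The
benchmark comparison pits the full detector against
`baseline_threshold_detector()` — flag every base with `Q` below a cutoff —
with the cutoff chosen by `match_call_volume()` so both make the same
number of calls. The matched volume counts the model's error calls (steps
2–3) and excludes step-1 end masks: step 1 is the conventional end trimmer
that the single-threshold family also embodies, its masks are terminal by
construction and never touch the middle of reads, and including its bulk
would hand the baseline a budget measuring trimming volume rather than
detection skill. Under that comparison, the detector's TPR averaged over the
middle 50 % of positions exceeds the volume-matched baseline's, and its
mid-read calls on the default simulation are almost exclusively true errors.

## Numerical and design notes

* Positions are 1-based throughout the R interface, including truth tables.
* Per-position SD uses the population formula (divide by *n*); with the
  sample sizes involved the distinction is cosmetic.
* The step-1 window size and mean-quality threshold (5, 20) are the standard
  defaults of this trimmer genre; both are exposed because reasonable tools
  differ here.
* Quality scores are validated into `[0, 93]`, the printable Phred+33 range.
* Degenerate inputs: empty files produce empty outputs, zeroed statistics
  and a warning; a window longer than the read treats the whole read as one
  window; all-`N` reads are discarded at the length filter.
* Problem sizes in the test suite (up to 10,000 simulated read pairs of
  100 bp, 5,000 reads for the benchmark comparison, 1,000 reads for the
  percentile-semantics measurements) keep the whole suite in the
  tens-of-seconds range while leaving every estimate comfortably inside its
  tolerance; the percentile measurements use a widened, effectively tie-free
  score range (flat mean 45, SD 12, scores 2–93) because with discrete ties
  the strict-percentile fractions are only defined up to the mass of the
  boundary bin.

## Limitations

* The detector flags errors; it does not correct them, and downstream tools
  must understand `N`s with quality 0 to benefit fully.
* Thresholds adapt to the run via the profile, but the four step-2/step-3
  constants themselves are fixed defaults, not fitted per dataset.
* Pairing is positional; inputs whose mates are not index-aligned must be
  re-paired upstream.
* The simulator's Gaussian noise model cannot stand in for real
  mis-calibrated runs; conclusions about relative tool performance on real
  data require real data.
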
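# A fixed small profile used across the step-2/step-3 example tests:
# at every one of 5 positions the sampled scores are
#   one 5, five 25, four 30  ->  percentile_below(25) = 0.1,
#                                percentile_below(30) = 0.6,
#                                percentile_below(8)  = 0.1.
example_profile_reads <- function() {
  cols <- c(5L, rep(25L, 5), rep(30L, 4))
  make_reads(lapply(cols, function(q) rep(q, 5L)))
}

test_that("step 2 classifies by strict percentile comparisons", {
  prof <- build_profile(example_profile_reads())
  reads <- make_reads(list(c(30L, 25L, 5L, 26L, 30L)))
  cls <- classify_step2(reads, prof)[[1]]
  expect_equal(cls[1], "CORRECT")    # pb(30) = 0.6 > 0.5
  expect_equal(cls[2], "CANDIDATE")  # pb(25) = 0.1
  expect_equal(cls[3], "CANDIDATE")  # pb(5) = 0: never ERROR at default 0%
  # a base exactly at the median percentile stays a candidate
  p50 <- build_profile(make_reads(c(rep(list(10L), 5), rep(list(30L), 5))))
  cls2 <- classify_step2(make_reads(list(30L)), p50)[[1]]
  expect_equal(percentile_below(p50, 1, 30L), 0.5)
  expect_equal(cls2, "CANDIDATE")
  # with a 5% auto-error threshold, pb = 0 becomes ERROR
  cls3 <- classify_step2(reads, prof, detection_params(error_pct = 0.05))[[1]]
  expect_equal(cls3[3], "ERROR")
})

test_that("ratio criterion bounds every usable neighbor at ratio_max", {
  p <- detection_params()
  expect_true(ratio_criterion(c(25, 26, 10, 30, 25), 3, p))   # max = 10/25 = 0.4
  expect_false(ratio_criterion(c(24, 40, 10, 40, 40), 3, p))  # 10/24 > 0.4
  expect_true(ratio_criterion(c(25, 26, 0, 30, 25), 3, p))    # Q = 0: ratios 0
  # zero-quality neighbor fails unless the center is also zero
  expect_false(ratio_criterion(c(25, 0, 10, 30, 25), 3, p))
  expect_true(ratio_criterion(c(0, 0, 0, 0, 0), 3, p))
  # masked neighbors are skipped, not counted
  expect_true(ratio_criterion(c(5, 40, 10, 30, 25), 3, p, masked = 1L))
  # no usable neighbor at all -> fail
  expect_false(ratio_criterion(c(10), 1, p))
})

test_that("neighbor percentile criterion requires strict bottom-pct membership", {
  prof <- build_profile(example_profile_reads())
  p <- detection_params()
  # all four neighbors at pb = 0.1 < 0.3 -> pass
  expect_true(neighbor_percentile_criterion(c(25L, 25L, 8L, 25L, 25L), 3, prof, p))
  # one neighbor above its median (pb = 0.6) -> fail
  expect_false(neighbor_percentile_criterion(c(25L, 30L, 8L, 25L, 25L), 3, prof, p))
  # a neighbor exactly at the bottom-30% boundary fails the strict comparison
  p30 <- build_profile(make_reads(c(rep(list(10L), 3), rep(list(30L), 7))))
  expect_equal(percentile_below(p30, 1, 30L), 0.3)
  expect_false(neighbor_percentile_criterion(c(30L, 5L), 2, p30,
                                             detection_params(neighbors = 1L)))
})

test_that("a planted low-quality base among depressed neighbors is detected", {
  prof <- build_profile(example_profile_reads())
  reads <- make_reads(list(c(25L, 25L, 8L, 25L, 25L)))
  # window mean 22.2 >= 20: no step-1 masks; 8/25 = 0.32 <= 0.4 and all
  # neighbors at pb 0.1 < 0.3
  expect_equal(detect_errors(reads, prof)[[1]], 3L)
  # tightening the ratio to 0.2 removes the call (8/25 = 0.32 > 0.2)
  expect_equal(detect_errors(reads, prof,
                             detection_params(ratio_max = 0.2))[[1]],
               integer(0))
  # a read entirely above its positional medians yields nothing
  high <- make_reads(list(rep(30L, 5)))
  expect_equal(detect_errors(high, prof)[[1]], integer(0))
})

test_that("detect_errors matches the naive loop oracle on small instances", {
  levels <- c(0L, 5L, 12L, 25L, 40L)
  prof_reads <- random_level_reads(30, c(20, 20), levels, seed = 31)
  prof <- build_profile(prof_reads)
  raw <- scores_by_position(prof_reads)
  test_reads <- random_level_reads(250, c(1, 20), levels, seed = 32)
  param_sets <- list(
    detection_params(),
    detection_params(ratio_max = 0.2),
    detection_params(neighbor_pct = 0.5),
    detection_params(error_pct = 0.2, correct_pct = 0.6),
    detection_params(correct_pct = 0.3),
    detection_params(neighbors = 1L),
    detection_params(window = 3L, window_qual = 10)
  )
  for (p in param_sets) {
    got <- detect_errors(test_reads, prof, p)
    want <- lapply(test_reads$qual, naive_detect, pos_scores = raw, params = p)
    expect_identical(got, want)
  }
})

test_that("step-2 states partition unmasked bases and step 3 only promotes candidates", {
  reads <- random_level_reads(100, c(10, 60), 0:41, seed = 33)
  prof <- build_profile(random_level_reads(200, c(60, 60), 0:41, seed = 34))
  p <- detection_params(error_pct = 0.1)
  det <- detect_errors(reads, prof, p, detail = TRUE)
  masks <- lapply(det, `[[`, "step1")
  cls <- classify_step2(reads, prof, p, masked = masks)
  for (i in seq_along(det)) {
    L <- length(reads$qual[[i]])
    expect_true(all(cls[[i]] %in% c("CORRECT", "ERROR", "CANDIDATE", "MASKED")))
    expect_equal(which(cls[[i]] == "MASKED"), det[[i]]$step1)
    expect_equal(which(cls[[i]] == "ERROR"), det[[i]]$step2)
    # step-3 calls come only from candidates
    expect_true(all(cls[[i]][det[[i]]$step3] == "CANDIDATE"))
  }
})

test_that("the detected set grows monotonically under each relaxation", {
  reads <- random_level_reads(150, c(20, 50), 0:41, seed = 35)
  prof <- build_profile(random_level_reads(150, c(50, 50), 0:41, seed = 36))
  base <- detection_params(correct_pct = 0.5, error_pct = 0.05,
                           ratio_max = 0.4, neighbor_pct = 0.3)
  relaxed <- list(
    detection_params(correct_pct = 0.5, error_pct = 0.05, ratio_max = 0.6,
                     neighbor_pct = 0.3),
    detection_params(correct_pct = 0.5, error_pct = 0.05, ratio_max = 0.4,
                     neighbor_pct = 0.5),
    detection_params(correct_pct = 0.5, error_pct = 0.15, ratio_max = 0.4,
                     neighbor_pct = 0.3),
    detection_params(correct_pct = 0.7, error_pct = 0.05, ratio_max = 0.4,
                     neighbor_pct = 0.3)
  )
  d0 <- detect_errors(reads, prof, base)
  for (p in relaxed) {
    d1 <- detect_errors(reads, prof, p)
    expect_true(all(mapply(function(a, b) all(a %in% b), d0, d1)))
  }
})

test_that("with correct_pct = 0 only end masks are returned on clean data", {
  sim <- simulate_reads(sim_params(n_reads = 300, read_len = 80,
                                   error_rate = 0, seed = 37))
  prof <- build_profile(sim$reads)
  p0 <- detection_params(correct_pct = 0, error_pct = 0)
  det <- detect_errors(sim$reads, prof, p0, detail = TRUE)
  expect_true(all(lengths(lapply(det, `[[`, "step2")) == 0))
  expect_true(all(lengths(lapply(det, `[[`, "step3")) == 0))
})

test_that("reads longer than the profile fall back to the last position with a warning", {
  prof <- build_profile(make_reads(list(rep(30L, 5), rep(20L, 5))))
  long <- make_reads(list(rep(35L, 8)))
  expect_warning(det <- detect_errors(long, prof), "last profiled position")
  expect_equal(det[[1]], integer(0))
})
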
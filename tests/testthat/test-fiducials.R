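test_that("systolic peaks match ground truth on clean records", {
  rec <- clean_record(seed = 7)
  prep <- preprocess_record(rec)
  peaks <- detect_systolic_peaks(prep$ppg, prep$sampling_rate_hz)
  gt <- rec$ground_truth
  gt_peaks <- gt$peak_idx[gt$complete]
  expect_length(peaks, length(gt_peaks))
  expect_true(all(abs(sort(peaks) - sort(gt_peaks)) <= 2))
})

test_that("a flat signal yields no peaks, with a warning", {
  expect_warning(p <- detect_systolic_peaks(rep(0.5, 500), 125), "no systolic")
  expect_length(p, 0)
})

test_that("a two-cycle clean record yields exactly two peaks", {
  rec <- clean_record(duration_s = 2.5, heart_rate_bpm = 60, seed = 4)
  prep <- preprocess_record(rec)
  peaks <- detect_systolic_peaks(prep$ppg, prep$sampling_rate_hz)
  expect_length(peaks, 2)
})

test_that("valleys sit at the between-peak minima with earliest-tie rule", {
  v <- c(5, 4, 3, 2, 1, 2, 3, 4, 5)           # strict V between peaks 1 and 9
  expect_equal(detect_valleys(v, c(1L, 9L)), 5L)
  tie <- c(5, 1, 1, 1, 5)                      # plateau: earliest index wins
  expect_equal(detect_valleys(tie, c(1L, 5L)), 2L)
  expect_error(detect_valleys(v, 3L), "2 peaks")
  rec <- clean_record(seed = 9)
  prep <- preprocess_record(rec)
  peaks <- detect_systolic_peaks(prep$ppg, prep$sampling_rate_hz)
  valleys <- detect_valleys(prep$ppg, peaks)
  gt <- rec$ground_truth
  gt_onsets <- gt$onset_idx[gt$complete][-1]   # interior boundaries
  expect_true(all(abs(sort(valleys) - sort(gt_onsets)) <= 2))
})

test_that("slope extrema: logistic inflection and triangle limbs", {
  fs <- 100
  t <- seq(-2, 2, by = 1 / fs)
  x <- 1 / (1 + exp(-6 * t))                   # inflection at t = 0
  d <- derivatives(x, fs)
  sl <- detect_slope_extrema(d$dppg, 1L, length(x) - 1L, length(x))
  expect_lte(abs(sl$max_slope_idx - which.min(abs(t))), 1)

  tri <- c(seq(0, 1, length.out = 11), seq(0.9, 0, length.out = 10))
  dt <- derivatives(tri, 10)
  sl2 <- detect_slope_extrema(dt$dppg, 1L, 11L, 21L)
  expect_lt(sl2$max_slope_idx, 11)
  expect_gt(sl2$min_slope_idx, 11)
  expect_error(detect_slope_extrema(dt$dppg, 5L, 5L, 5L), "degenerate")
})

test_that("dicrotic notch is found on clean cycles and absent without one", {
  rec <- clean_record(seed = 15)
  dev <- fiducial_deviations(rec)
  expect_true(all(abs(dev[, "notch"]) <= 3))

  rec0 <- generate_record(synth_config(notch_relative_intensity = 0,
                                       seed = 15))
  prep0 <- preprocess_record(rec0)
  seg0 <- segment_record(prep0, criteria = abnormal_criteria(
    require_fiducials = FALSE))
  notches <- vapply(seg0$segments, function(s)
    s$fiducials$dicrotic_notch_idx, integer(1))
  expect_true(all(is.na(notches)))
})

test_that("the larger of two sdPPG local maxima is picked as the notch", {
  sd2 <- c(0, -1, -2, 1, 0, 3, 0, -1, 0)       # local maxima at 4 (1) and 6 (3)
  d1 <- c(0, 1, -1, 0.5, -0.5, 0.2, -0.2, 0.1, 0)  # has interior local maxima
  expect_equal(detect_dicrotic_notch(sd2, d1, 1L, 9L), 6L)
  expect_error(detect_dicrotic_notch(sd2, d1, 5L, 6L), "window")
})

test_that("partitioning is exhaustive and peaks are fragment maxima", {
  rec <- clean_record(seed = 25)
  prep <- preprocess_record(rec)
  seg <- segment_record(prep)
  expect_equal(length(seg$segments), length(seg$valleys) - 1)
  for (s in seg$segments) {
    expect_equal(which.max(s$ppg_fragment), s$fiducials$systolic_peak_idx)
    expect_equal(length(s$ppg_fragment),
                 s$fiducials$offset_idx - s$fiducials$onset_idx + 1L)
  }
  # fragments (minus the shared boundary sample) tile the valley span
  total <- sum(vapply(seg$segments, function(s)
    length(s$ppg_fragment) - 1L, integer(1)))
  expect_equal(total, max(seg$valleys) - min(seg$valleys))
})

test_that("fiducial ordering invariant holds for every emitted segment", {
  for (seed in c(31, 32, 33)) {
    rec <- generate_record(random_clean_config(seed))
    seg <- segment_record(preprocess_record(rec))
    for (s in seg$segments) {
      f <- s$fiducials
      idx <- c(f$onset_idx, f$max_slope_idx, f$systolic_peak_idx,
               f$dicrotic_notch_idx, f$offset_idx)
      expect_false(anyNA(idx))
      expect_true(all(diff(idx) > 0))
      expect_true(all(idx >= 1 & idx <= length(s$ppg_fragment)))
    }
  }
})

test_that("BP labels recover the mapped pressures from the ABP channel", {
  cmap <- list(sbp = c(intercept = 120, dur = 0, amp = 0, notch = 0),
               dbp = c(intercept = 80, dur = 0, amp = 0, notch = 0))
  rec <- generate_record(synth_config(bp_map_coefficients = cmap, seed = 6))
  gt <- rec$ground_truth
  i <- which(gt$complete)[3]
  lab <- extract_bp_labels(rec$abp, gt$onset_idx[i], gt$offset_idx[i])
  expect_equal(lab$sbp_mmHg, 120, tolerance = 0.5)
  expect_equal(lab$dbp_mmHg, 80, tolerance = 0.5)
  expect_error(extract_bp_labels(rep(100, 1000), 1L, 200L), "SBP must exceed")
  expect_error(extract_bp_labels(numeric(0), 1L, 10L), "no ABP")
})

test_that("abnormal-cycle screening removes exactly the violating cycles", {
  rec <- clean_record(seed = 41)
  prep <- preprocess_record(rec)
  seg <- segment_record(prep)
  res <- remove_abnormal_cycles(seg$segments)
  expect_equal(res$log$n_removed, 0)

  bad <- seg$segments
  bad[[2]]$sbp_mmHg <- 250
  res2 <- remove_abnormal_cycles(bad)
  expect_equal(res2$log$n_removed, 1)
  expect_equal(res2$log$sbp_range, 1L)
  expect_equal(length(res2$segments), length(bad) - 1)

  # a 2 s cycle violates the duration rule
  long <- bad[[3]]
  long$fiducials$offset_idx <- long$fiducials$onset_idx +
    as.integer(2.5 * long$sampling_rate_hz)
  res3 <- remove_abnormal_cycles(list(long), abnormal_criteria(
    duration_range = c(0.3, 1.5), require_fiducials = FALSE))
  expect_equal(res3$log$duration, 1L)
  expect_error(abnormal_criteria(sbp_range = c(180, 80)), "contradictory")
})

test_that("screening is order-independent: survivors satisfy every rule", {
  rec <- clean_record(seed = 43)
  seg <- segment_record(preprocess_record(rec))
  segs <- seg$segments
  segs[[1]]$sbp_mmHg <- 250
  segs[[2]]$dbp_mmHg <- 20
  crit <- abnormal_criteria()
  res <- remove_abnormal_cycles(segs, crit)
  # every rule applied singly keeps a superset; intersection = joint result
  single <- lapply(1:5, function(k) {
    c2 <- crit
    if (k != 1) c2$sbp_range <- c(-Inf, Inf)
    if (k != 2) c2$dbp_range <- c(-Inf, Inf)
    if (k != 3) c2$min_pulse_pressure <- -Inf
    if (k != 4) c2$duration_range <- c(0, Inf)
    if (k != 5) c2$require_fiducials <- FALSE
    vapply(remove_abnormal_cycles(segs, c2)$segments,
           function(s) s$start_idx, integer(1))
  })
  joint <- vapply(res$segments, function(s) s$start_idx, integer(1))
  expect_equal(sort(Reduce(intersect, single)), sort(joint))
})
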
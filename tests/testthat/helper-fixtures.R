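# shared fixtures and independent oracles used across test files

# a clean (noise-free, jitter-free) record with a well-formed dicrotic wave
clean_record <- function(duration_s = 10, heart_rate_bpm = 60, seed = 7, ...) {
  generate_record(synth_config(duration_s = duration_s,
                               heart_rate_bpm = heart_rate_bpm,
                               seed = seed, ...))
}

# random noise-free configs guaranteed to carry a genuine dicrotic dip
random_clean_config <- function(seed) {
  set.seed(seed)
  synth_config(
    duration_s = 10,
    heart_rate_bpm = runif(1, 50, 100),
    notch_relative_intensity = runif(1, 0.35, 0.6),
    notch_delay_fraction = runif(1, 0.55, 0.72),
    systolic_amplitude = runif(1, 0.8, 1.2),
    seed = seed)
}

# run preprocessing + segmentation and align detected segments with the
# generator's ground-truth cycles (matched by systolic-peak proximity);
# returns per-cycle fiducial deviations in samples (NA = fiducial missed)
fiducial_deviations <- function(record) {
  prep <- preprocess_record(record)
  seg <- segment_record(prep)
  gt <- record$ground_truth
  gtc <- gt[gt$complete, , drop = FALSE]
  if (length(seg$segments) == 0)
    return(matrix(NA_real_, nrow(gtc), 6))
  segpk <- vapply(seg$segments, function(s)
    s$start_idx + s$fiducials$systolic_peak_idx - 1L, integer(1))
  out <- matrix(NA_real_, nrow(gtc), 6,
                dimnames = list(NULL, c("onset", "max_slope", "peak",
                                        "min_slope", "notch", "offset")))
  for (i in seq_len(nrow(gtc))) {
    g <- gtc[i, ]
    s <- seg$segments[[which.min(abs(segpk - g$peak_idx))]]
    f <- s$fiducials; o0 <- s$start_idx - 1L
    out[i, ] <- c(o0 + f$onset_idx - g$onset_idx,
                  o0 + f$max_slope_idx - g$max_slope_idx,
                  o0 + f$systolic_peak_idx - g$peak_idx,
                  o0 + f$min_slope_idx - g$min_slope_idx,
                  if (is.na(g$notch_idx)) 0
                  else (o0 + f$dicrotic_notch_idx) - g$notch_idx,
                  o0 + f$offset_idx - g$offset_idx)
  }
  out
}

# build a cycle_segment by hand (fiducials are local indices)
make_segment <- function(ppg, fiducials, fs = 10,
                         dppg = NULL, sdppg = NULL,
                         sbp = NA_real_, dbp = NA_real_) {
  if (is.null(dppg)) {
    d <- derivatives(ppg, fs)
    dppg <- d$dppg; sdppg <- d$sdppg
  }
  structure(list(ppg_fragment = ppg, dppg_fragment = dppg,
                 sdppg_fragment = sdppg, fiducials = fiducials,
                 start_idx = 1L, sbp_mmHg = sbp, dbp_mmHg = dbp,
                 sampling_rate_hz = fs),
            class = "cycle_segment")
}

# the 21-sample piecewise-linear toy cycle used for hand-computed features:
# fs = 10 Hz, onset 1, max-slope 4, peak 8, notch 13, offset 21
toy_cycle <- function() {
  ppg <- c(0.10, 0.15, 0.25, 0.45, 0.70, 0.85, 0.95, 1.00,
           0.90, 0.80, 0.70, 0.62, 0.55, 0.60, 0.58, 0.50,
           0.40, 0.30, 0.22, 0.15, 0.10)
  fid <- list(onset_idx = 1L, max_slope_idx = 4L, systolic_peak_idx = 8L,
              min_slope_idx = 9L, dicrotic_notch_idx = 13L,
              offset_idx = 21L)
  make_segment(ppg, fid, fs = 10)
}

# independent oracle: band-limit by explicit DFT bin zeroing written out
# from the definition (loop over bins, symmetric conjugate halves)
oracle_bandlimit <- function(x, fs, high_cut, low_cut = 0) {
  n <- length(x)
  X <- stats::fft(x)
  for (j in seq_len(n)) {
    k <- j - 1
    f <- min(k, n - k) * fs / n
    if (f > high_cut + 1e-9 || f < low_cut - 1e-9) X[j] <- 0 + 0i
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

# independent oracle: forward pass of a fully connected ReLU network as
# explicit per-unit loops
oracle_forward <- function(W, b, x) {
  a <- x
  L <- length(W)
  for (l in seq_len(L)) {
    out <- numeric(ncol(W[[l]]))
    for (j in seq_len(ncol(W[[l]]))) {
      s <- b[[l]][j]
      for (i in seq_along(a)) s <- s + a[i] * W[[l]][i, j]
      out[j] <- if (l < L) max(s, 0) else s
    }
    a <- out
  }
  a
}

# independent oracle: every evaluation-report field recomputed with plain
# loops and textbook formulas (population sd)
oracle_eval <- function(truth, est) {
  n <- length(truth)
  err <- numeric(n)
  for (i in seq_len(n)) err[i] <- est[i] - truth[i]
  me <- sum(err) / n
  sdv <- sqrt(sum((err - me)^2) / n)
  cum <- function(thr) 100 * sum(abs(err) <= thr) / n
  mx <- sum(truth) / n; my <- sum(est) / n
  sx <- sqrt(sum((truth - mx)^2) / n); sy <- sqrt(sum((est - my)^2) / n)
  r <- sum((truth - mx) * (est - my)) / (n * sx * sy)
  lo <- me - 1.96 * sdv; hi <- me + 1.96 * sdv
  p5 <- cum(5); p10 <- cum(10); p15 <- cum(15)
  grade <- "D"
  if (p5 >= 40 && p10 >= 65 && p15 >= 85) grade <- "C"
  if (p5 >= 50 && p10 >= 75 && p15 >= 90) grade <- "B"
  if (p5 >= 60 && p10 >= 85 && p15 >= 95) grade <- "A"
  list(rmse = sqrt(sum(err^2) / n), mae = sum(abs(err)) / n,
       mean_error = me, sd_error = sdv, pearson_r = r,
       loa_low = lo, loa_high = hi,
       pct_within_loa = 100 * sum(err >= lo & err <= hi) / n,
       cum_pct_5 = p5, cum_pct_10 = p10, cum_pct_15 = p15,
       bhs_grade = grade, aami_pass = abs(me) <= 5 && sdv <= 8)
}

# the 32-feature working set published for the reference corpus
paper_selected_set <- function() {
  c("hr", "AS", "DS", "AA", "dAA", "sdAA", "DA", "dDA", "sdDA",
    "PI", "dPI", "sdPI", "dVI", "sdVI", "AID", "dAID", "sdAID",
    "dDID", "sdDID", "dRIPV", "sdRIPV", "AT", "Slope_a", "S3", "S4",
    "NI", "AI", "AI1", "RSD", "RSC", "S1", "S2")
}
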
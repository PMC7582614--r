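# rolling mean with edge padding (window w samples, centred)
.rollmean <- function(x, w) {
  w <- max(3L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  cs <- cumsum(xp)
  (cs[(w):length(xp)] - c(0, cs[seq_len(length(xp) - w)])) / w
}

#' Detect systolic peaks with a moving-average adaptive threshold
#'
#' Marks one peak per cardiac cycle: candidate regions are runs where the
#' signal exceeds its centred moving average (window `ma_window_s`), each
#' region contributes its maximum, and candidates closer together than a
#' plausibility distance are pruned keeping the taller peak. The pruning
#' distance is 0.7 times the dominant period estimated from the signal's
#' autocorrelation within the plausible heart-rate band
#' `[min_rr_s, max_rr_s]`, which suppresses secondary (dicrotic) waves
#' without rejecting genuine beats.
#'
#' @param ppg Preprocessed, normalized PPG vector.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param ma_window_s Moving-average window length in seconds (default 0.75).
#' @param min_rr_s,max_rr_s Plausible inter-beat interval bounds in seconds
#'   (defaults 0.33 and 2.0, i.e. 30-180 bpm).
#' @return Integer vector of peak sample indices (possibly empty, with a
#'   warning when no peak is found).
#' @export
detect_systolic_peaks <- function(ppg, sampling_rate_hz,
                                  ma_window_s = 0.75,
                                  min_rr_s = 0.33, max_rr_s = 2.0) {
  n <- length(ppg)
  if (n < 3) stop("signal too short for peak detection")
  ma <- .rollmean(ppg, ma_window_s * sampling_rate_hz)
  above <- ppg > ma
  if (!any(above)) {
    warning("no systolic peaks found")
    return(integer(0))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  for (j in which(runs$values)) {
    span <- starts[j]:ends[j]
    cand <- c(cand, span[which.max(ppg[span])])
  }
  if (length(cand) == 0) {
    warning("no systolic peaks found")
    return(integer(0))
  }
  # dominant-period estimate from the autocorrelation in the HR band
  min_lag <- max(2L, round(min_rr_s * sampling_rate_hz))
  max_lag <- min(round(max_rr_s * sampling_rate_hz), n - 2L)
  min_dist <- min_lag
  if (max_lag > min_lag && length(cand) >= 2) {
    ac <- stats::acf(ppg, lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf[-1]
    band <- ac[min_lag:max_lag]
    if (any(is.finite(band)) && max(band, na.rm = TRUE) > 0) {
      # smallest lag reaching 90% of the band maximum = fundamental period
      lag_hat <- min_lag - 1L + which(band >= 0.9 * max(band, na.rm = TRUE))[1]
      min_dist <- max(min_lag, round(0.7 * lag_hat))
    }
  }
  # greedy pruning: tallest first, reject anything too close to an accepted peak
  ord <- cand[order(ppg[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Detect onset/offset valleys between consecutive systolic peaks
#'
#' One valley per consecutive peak pair, placed at the minimum of the
#' strictly-between span; ties resolve to the earliest index.
#'
#' @param ppg Preprocessed PPG vector.
#' @param peaks Integer vector of at least two peak indices.
#' @return Integer vector of valley indices (length `length(peaks) - 1`).
#' @export
detect_valleys <- function(ppg, peaks) {
  if (length(peaks) < 2) stop("need at least 2 peaks to locate valleys")
  vapply(seq_len(length(peaks) - 1L), function(i) {
    span <- (peaks[i] + 1L):(peaks[i + 1L] - 1L)
    span[which.min(ppg[span])]
  }, integer(1))
}

#' Locate maximal and minimal slope within a cycle
#'
#' The maximum-slope point is the argmax of the first derivative between
#' onset and systolic peak; the minimum-slope point is the argmin between
#' peak and offset. Ties resolve to the earliest index.
#'
#' @param dppg First-derivative signal.
#' @param onset_idx,peak_idx,offset_idx Cycle fiducials (global indices,
#'   `onset < peak < offset`).
#' @return List with `max_slope_idx` and `min_slope_idx`.
#' @export
detect_slope_extrema <- function(dppg, onset_idx, peak_idx, offset_idx) {
  if (!(onset_idx < peak_idx && peak_idx < offset_idx))
    stop("degenerate cycle span: need onset < peak < offset")
  list(
    max_slope_idx = onset_idx - 1L + which.max(dppg[onset_idx:peak_idx]),
    min_slope_idx = peak_idx - 1L + which.min(dppg[peak_idx:offset_idx])
  )
}

#' Detect the dicrotic notch as the secondary peak of sdPPG
#'
#' The notch is the largest interior local maximum of the second derivative
#' strictly between the systolic peak and the offset valley (ties resolve
#' to the earliest). A notch is only reported when the first derivative has
#' a strict interior local maximum in the same window — the signature of a
#' genuine dicrotic wave; a bare single-lobe descent (no dicrotic wave)
#' always carries a positive-curvature maximum, so without this gate a
#' notch would be reported on every cycle.
#'
#' @param sdppg Second-derivative signal.
#' @param dppg First-derivative signal.
#' @param peak_idx,offset_idx Search window bounds (global indices).
#' @return Integer notch index, or `NA_integer_` when no dicrotic wave is
#'   present.
#' @export
detect_dicrotic_notch <- function(sdppg, dppg, peak_idx, offset_idx) {
  if (offset_idx - peak_idx < 3) stop("empty dicrotic search window")
  win <- peak_idx:offset_idx
  if (length(.local_maxima(dppg[win])) == 0) return(NA_integer_)
  cand <- .local_maxima(sdppg[win])
  if (length(cand) == 0) return(NA_integer_)
  vals <- sdppg[peak_idx - 1L + cand]
  peak_idx - 1L + cand[which.max(vals)]
}

#' Partition a preprocessed record into cycle segments
#'
#' Cuts the record at consecutive valley (onset) points and detects the
#' within-cycle fiducials of each fragment: systolic peak (fragment
#' maximum), slope extrema and dicrotic notch. Fragments are closed spans
#' sharing their boundary valley sample; fiducials are re-indexed to the
#' fragment (onset = 1).
#'
#' @param prep A `preprocessed_record`.
#' @param valleys Integer vector of at least two valley indices (may
#'   include record-boundary valleys).
#' @return List of `cycle_segment` objects. Each has `ppg_fragment`,
#'   `dppg_fragment`, `sdppg_fragment`, `fiducials` (local indices),
#'   `start_idx` (global index of the fragment's first sample),
#'   `sbp_mmHg`/`dbp_mmHg` (NA until labels attached), `sampling_rate_hz`.
#' @export
partition_cycles <- function(prep, valleys) {
  stopifnot(inherits(prep, "preprocessed_record"))
  if (length(valleys) < 2) stop("need at least 2 valleys to partition")
  valleys <- sort(as.integer(valleys))
  lapply(seq_len(length(valleys) - 1L), function(i) {
    on <- valleys[i]; off <- valleys[i + 1L]
    span <- on:off
    frag <- prep$ppg[span]
    peak_l <- which.max(frag)
    fid <- list(onset_idx = 1L, max_slope_idx = NA_integer_,
                systolic_peak_idx = peak_l, min_slope_idx = NA_integer_,
                dicrotic_notch_idx = NA_integer_,
                offset_idx = length(span))
    if (peak_l > 1L && peak_l < length(span)) {
      sl <- detect_slope_extrema(prep$dppg, on, on - 1L + peak_l, off)
      fid$max_slope_idx <- sl$max_slope_idx - on + 1L
      fid$min_slope_idx <- sl$min_slope_idx - on + 1L
      if (off - (on - 1L + peak_l) >= 3) {
        nt <- detect_dicrotic_notch(prep$sdppg, prep$dppg,
                                    on - 1L + peak_l, off)
        if (!is.na(nt)) fid$dicrotic_notch_idx <- nt - on + 1L
      }
    }
    structure(list(
      ppg_fragment = frag,
      dppg_fragment = prep$dppg[span],
      sdppg_fragment = prep$sdppg[span],
      fiducials = fid, start_idx = on,
      sbp_mmHg = NA_real_, dbp_mmHg = NA_real_,
      sampling_rate_hz = prep$sampling_rate_hz
    ), class = "cycle_segment")
  })
}

#' Extract per-cycle SBP/DBP labels from an aligned ABP channel
#'
#' SBP is the maximum and DBP the minimum of the arterial-pressure samples
#' over the cycle span.
#'
#' @param abp Aligned ABP vector in mmHg.
#' @param onset_idx,offset_idx Cycle span (global indices).
#' @return List with `sbp_mmHg` and `dbp_mmHg`.
#' @export
extract_bp_labels <- function(abp, onset_idx, offset_idx) {
  if (is.null(abp) || length(abp) == 0 || all(abp == 0))
    stop("no ABP channel available for label extraction")
  if (offset_idx <= onset_idx || offset_idx > length(abp))
    stop("invalid cycle span for label extraction")
  span <- onset_idx:offset_idx
  sbp <- max(abp[span]); dbp <- min(abp[span])
  if (sbp <= dbp) stop("degenerate ABP span: SBP must exceed DBP ",
                       "(constant pressure?)")
  list(sbp_mmHg = sbp, dbp_mmHg = dbp)
}

#' Default abnormal-cycle screening criteria
#'
#' Physiological plausibility bounds used by [remove_abnormal_cycles()]:
#' SBP in 80-180 mmHg, DBP in 60-130 mmHg, pulse pressure at least
#' 20 mmHg, cycle duration 0.33-2.0 s, and all six fiducials present in
#' order. All bounds are configurable.
#'
#' @param sbp_range,dbp_range Two-element numeric bounds in mmHg.
#' @param min_pulse_pressure Minimum SBP-DBP difference in mmHg.
#' @param duration_range Two-element cycle-duration bounds in seconds.
#' @param require_fiducials Require a complete, ordered fiducial set.
#' @return List of class `abnormal_criteria`.
#' @export
abnormal_criteria <- function(sbp_range = c(80, 180),
                              dbp_range = c(60, 130),
                              min_pulse_pressure = 20,
                              duration_range = c(0.33, 2.0),
                              require_fiducials = TRUE) {
  for (r in list(sbp_range, dbp_range, duration_range))
    if (length(r) != 2 || r[1] > r[2])
      stop("contradictory bounds: lower bound exceeds upper bound")
  structure(list(sbp_range = sbp_range, dbp_range = dbp_range,
                 min_pulse_pressure = min_pulse_pressure,
                 duration_range = duration_range,
                 require_fiducials = require_fiducials),
            class = "abnormal_criteria")
}

.fiducials_ordered <- function(f) {
  idx <- c(f$onset_idx, f$max_slope_idx, f$systolic_peak_idx,
           f$dicrotic_notch_idx, f$offset_idx)
  !anyNA(idx) && all(diff(idx) > 0) && !is.na(f$min_slope_idx)
}

#' Remove abnormal cycles
#'
#' Screens cycle segments against plausibility criteria; a segment survives
#' only if it violates no rule, so the surviving set does not depend on the
#' order in which rules are applied. Pressure rules are only evaluated for
#' labelled segments. Returns the survivors plus a per-rule removal log
#' (a segment violating several rules is counted under each).
#'
#' @param segments List of `cycle_segment` objects.
#' @param criteria An [abnormal_criteria()] list.
#' @return List with `segments` (survivors) and `log` (named integer
#'   vector of removal counts per rule, plus `n_removed`/`n_kept`).
#' @export
remove_abnormal_cycles <- function(segments, criteria = abnormal_criteria()) {
  stopifnot(inherits(criteria, "abnormal_criteria"))
  rules <- c("sbp_range", "dbp_range", "pulse_pressure", "duration",
             "fiducials")
  counts <- stats::setNames(integer(length(rules)), rules)
  keep <- logical(length(segments))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    dur <- (s$fiducials$offset_idx - s$fiducials$onset_idx) /
      s$sampling_rate_hz
    viol <- character(0)
    if (!is.na(s$sbp_mmHg)) {
      if (s$sbp_mmHg < criteria$sbp_range[1] ||
          s$sbp_mmHg > criteria$sbp_range[2]) viol <- c(viol, "sbp_range")
      if (!is.na(s$dbp_mmHg)) {
        if (s$dbp_mmHg < criteria$dbp_range[1] ||
            s$dbp_mmHg > criteria$dbp_range[2]) viol <- c(viol, "dbp_range")
        if (s$sbp_mmHg - s$dbp_mmHg < criteria$min_pulse_pressure)
          viol <- c(viol, "pulse_pressure")
      }
    }
    if (dur < criteria$duration_range[1] || dur > criteria$duration_range[2])
      viol <- c(viol, "duration")
    if (criteria$require_fiducials && !.fiducials_ordered(s$fiducials))
      viol <- c(viol, "fiducials")
    keep[i] <- length(viol) == 0
    counts[viol] <- counts[viol] + 1L
  }
  list(segments = segments[keep],
       log = c(as.list(counts),
               n_removed = sum(!keep), n_kept = sum(keep)))
}

#' Segment a preprocessed record into labelled cardiac cycles
#'
#' End-to-end fiducial stage: detects systolic peaks, valleys (including
#' the record-boundary valleys before the first and after the last peak),
#' partitions into cycle segments, attaches SBP/DBP labels from the ABP
#' channel when present, and removes abnormal cycles.
#'
#' @param prep A `preprocessed_record`.
#' @param criteria Screening criteria, see [abnormal_criteria()].
#' @param label_from_abp Attach per-cycle labels from the ABP channel.
#' @param ... Passed to [detect_systolic_peaks()].
#' @return List with `segments`, `removal_log`, `peaks`, `valleys`.
#' @export
segment_record <- function(prep, criteria = abnormal_criteria(),
                           label_from_abp = TRUE, ...) {
  stopifnot(inherits(prep, "preprocessed_record"))
  peaks <- detect_systolic_peaks(prep$ppg, prep$sampling_rate_hz, ...)
  if (length(peaks) < 2)
    return(list(segments = list(),
                log = list(n_removed = 0L, n_kept = 0L),
                peaks = peaks, valleys = integer(0)))
  valleys <- detect_valleys(prep$ppg, peaks)
  n <- length(prep$ppg)
  head_v <- which.min(prep$ppg[1:peaks[1]])
  tail_v <- peaks[length(peaks)] - 1L +
    which.min(prep$ppg[peaks[length(peaks)]:n])
  valleys <- unique(sort(c(head_v, valleys, tail_v)))
  segments <- partition_cycles(prep, valleys)
  has_abp <- !is.null(prep$abp) && length(prep$abp) == length(prep$ppg) &&
    !all(prep$abp == 0)
  if (label_from_abp && has_abp) {
    segments <- lapply(segments, function(s) {
      span_end <- s$start_idx + s$fiducials$offset_idx - 1L
      lab <- tryCatch(extract_bp_labels(prep$abp, s$start_idx, span_end),
                      error = function(e) NULL)
      if (!is.null(lab)) { s$sbp_mmHg <- lab$sbp_mmHg; s$dbp_mmHg <- lab$dbp_mmHg }
      s
    })
  }
  res <- remove_abnormal_cycles(segments, criteria)
  list(segments = res$segments, removal_log = res$log,
       peaks = peaks, valleys = valleys)
}
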
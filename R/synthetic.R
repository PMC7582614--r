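#' Configuration for the synthetic PPG/ABP generator
#'
#' Builds and validates the parameter set for [generate_record()]. Each
#' cardiac cycle is modelled as two positive Gaussian lobes on a shared
#' baseline: a systolic wave centred at `systolic_peak_fraction` of the cycle
#' and a dicrotic (secondary) wave centred at `notch_delay_fraction`, with
#' relative height `notch_relative_intensity`. Baseline wander (a slow
#' sinusoid below 0.5 Hz), a high-frequency sinusoid above 8 Hz and optional
#' white noise are superposed additively. Per-cycle systolic/diastolic
#' pressure labels are an affine function of the cycle's morphology
#' parameters (duration, amplitude, dicrotic intensity) plus Gaussian noise.
#'
#' @param sampling_rate_hz Sampling rate in Hz (default 125).
#' @param duration_s Record duration in seconds.
#' @param heart_rate_bpm Mean heart rate in beats per minute.
#' @param hr_jitter_sd_bpm Per-cycle heart-rate jitter standard deviation.
#' @param systolic_amplitude Height of the systolic lobe (arbitrary units).
#' @param amplitude_jitter_sd Per-cycle relative amplitude jitter sd.
#' @param systolic_peak_fraction Position of the systolic lobe centre within
#'   the cycle, as a fraction of cycle duration.
#' @param systolic_width_fraction,dicrotic_width_fraction Gaussian lobe
#'   standard deviations as fractions of cycle duration.
#' @param notch_relative_intensity Dicrotic lobe height relative to the
#'   systolic lobe, in `[0, 1)`. Zero removes the dicrotic wave entirely.
#' @param notch_delay_fraction Dicrotic lobe centre within the cycle; must
#'   lie strictly between `systolic_peak_fraction` and 1.
#' @param wander_amplitude,wander_freq_hz Baseline-wander sinusoid amplitude
#'   and frequency (frequency must be below 0.5 Hz).
#' @param noise_amplitude,noise_freq_hz High-frequency sinusoidal noise
#'   amplitude and frequency (frequency must exceed 8 Hz).
#' @param white_noise_sd Additive white Gaussian noise sd (0 disables).
#' @param bp_map_coefficients Affine morphology-to-pressure map: a list with
#'   elements `sbp` and `dbp`, each a named vector
#'   `c(intercept, dur, amp, notch)` applied to the per-cycle morphology
#'   vector (cycle duration in s, amplitude, dicrotic relative intensity).
#' @param label_noise_sd_mmHg Gaussian noise sd added to both labels (mmHg).
#' @param seed Integer seed; identical seed and config give bit-identical
#'   records.
#' @return A validated list of class `synth_config`.
#' @seealso [generate_record()], [generate_feature_dataset()]
#' @export
synth_config <- function(sampling_rate_hz = 125,
                         duration_s = 10,
                         heart_rate_bpm = 60,
                         hr_jitter_sd_bpm = 0,
                         systolic_amplitude = 1,
                         amplitude_jitter_sd = 0,
                         systolic_peak_fraction = 0.30,
                         systolic_width_fraction = 0.11,
                         dicrotic_width_fraction = 0.09,
                         notch_relative_intensity = 0.40,
                         notch_delay_fraction = 0.62,
                         wander_amplitude = 0,
                         wander_freq_hz = 0.25,
                         noise_amplitude = 0,
                         noise_freq_hz = 20,
                         white_noise_sd = 0,
                         bp_map_coefficients = default_bp_map(),
                         label_noise_sd_mmHg = 0,
                         seed = 1L) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be positive")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (!is.numeric(heart_rate_bpm) || heart_rate_bpm <= 0)
    stop("heart_rate_bpm must be positive")
  if (notch_relative_intensity < 0 || notch_relative_intensity >= 1)
    stop("notch_relative_intensity must lie in [0, 1)")
  if (notch_delay_fraction <= systolic_peak_fraction ||
      notch_delay_fraction >= 1)
    stop("notch_delay_fraction must lie strictly between ",
         "systolic_peak_fraction and 1")
  if (systolic_peak_fraction <= 0 || systolic_peak_fraction >= 1)
    stop("systolic_peak_fraction must lie in (0, 1)")
  if (wander_amplitude > 0 && wander_freq_hz >= 0.5)
    stop("wander_freq_hz must be below 0.5 Hz")
  if (noise_amplitude > 0 && noise_freq_hz <= 8)
    stop("noise_freq_hz must exceed 8 Hz")
  if (label_noise_sd_mmHg < 0) stop("label_noise_sd_mmHg must be nonnegative")
  if (hr_jitter_sd_bpm < 0 || amplitude_jitter_sd < 0 || white_noise_sd < 0)
    stop("jitter/noise standard deviations must be nonnegative")
  stopifnot(is.list(bp_map_coefficients),
            all(c("sbp", "dbp") %in% names(bp_map_coefficients)))
  structure(list(
    sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
    heart_rate_bpm = heart_rate_bpm, hr_jitter_sd_bpm = hr_jitter_sd_bpm,
    systolic_amplitude = systolic_amplitude,
    amplitude_jitter_sd = amplitude_jitter_sd,
    systolic_peak_fraction = systolic_peak_fraction,
    systolic_width_fraction = systolic_width_fraction,
    dicrotic_width_fraction = dicrotic_width_fraction,
    notch_relative_intensity = notch_relative_intensity,
    notch_delay_fraction = notch_delay_fraction,
    wander_amplitude = wander_amplitude, wander_freq_hz = wander_freq_hz,
    noise_amplitude = noise_amplitude, noise_freq_hz = noise_freq_hz,
    white_noise_sd = white_noise_sd,
    bp_map_coefficients = bp_map_coefficients,
    label_noise_sd_mmHg = label_noise_sd_mmHg,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Default affine morphology-to-pressure map
#'
#' Maps the per-cycle morphology vector (cycle duration in seconds, pulse
#' amplitude, dicrotic relative intensity) to SBP and DBP in mmHg. With the
#' generator defaults (1 s cycle, unit amplitude, dicrotic intensity 0.4)
#' the map yields roughly 122/80 mmHg.
#' @return List with named coefficient vectors `sbp` and `dbp`.
#' @export
default_bp_map <- function() {
  list(sbp = c(intercept = 145, dur = -30, amp = 15, notch = -20),
       dbp = c(intercept = 94,  dur = -15, amp = 5,  notch = -10))
}

# two-lobe pulse value and its analytic first/second time derivatives at
# phase u = (t - cycle_start)/T; vectorised over u
.pulse_value <- function(u, A, r, ps, ws, pd, wd) {
  A * (exp(-(u - ps)^2 / (2 * ws^2)) + r * exp(-(u - pd)^2 / (2 * wd^2)))
}
.pulse_d1 <- function(u, A, r, ps, ws, pd, wd, T) {
  (A / T) * (-(u - ps) / ws^2 * exp(-(u - ps)^2 / (2 * ws^2)) -
             r * (u - pd) / wd^2 * exp(-(u - pd)^2 / (2 * wd^2)))
}
.pulse_d2 <- function(u, A, r, ps, ws, pd, wd, T) {
  (A / T^2) * (((u - ps)^2 / ws^2 - 1) / ws^2 * exp(-(u - ps)^2 / (2 * ws^2)) +
               r * ((u - pd)^2 / wd^2 - 1) / wd^2 *
                 exp(-(u - pd)^2 / (2 * wd^2)))
}

# strict interior local maxima of a numeric vector (global indices)
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

#' Generate a synthetic PPG record with ground truth
#'
#' Produces a sampled PPG trace (clean two-lobe pulse train plus baseline
#' wander and noise), an aligned arterial-pressure (ABP) channel whose
#' per-cycle maximum/minimum equal the mapped SBP/DBP labels, and a
#' ground-truth table giving every complete cycle's fiducial sample indices
#' (onset, maximum-slope, systolic peak, minimum-slope, dicrotic notch,
#' offset; 1-based), morphology parameters and pressure labels. Slope and
#' notch ground truth come from the closed-form derivatives of the pulse
#' model, independent of the package's discrete detection chain.
#'
#' @param config A [synth_config()] object.
#' @return An object of class `waveform_record`: list with `ppg`, `abp`,
#'   `clean` (noise-free pulse train), `sampling_rate_hz`, `record_id`,
#'   `ground_truth` (data frame) and `config`.
#' @examples
#' rec <- generate_record(synth_config(duration_s = 10, seed = 7))
#' nrow(rec$ground_truth)  # ~ heart_rate_bpm * duration_s / 60 cycles
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate_hz

  ps <- config$systolic_peak_fraction
  ws <- config$systolic_width_fraction
  pd <- config$notch_delay_fraction
  wd <- config$dicrotic_width_fraction

  # draw whole cycles only: the record is trimmed to end exactly at the last
  # cycle boundary, so the implicit periodic extension of the FFT sees
  # near-identical values at both record edges (no wrap discontinuity)
  starts <- numeric(0); periods <- numeric(0)
  amps <- numeric(0); notches <- numeric(0)
  s <- 0
  repeat {
    hr <- config$heart_rate_bpm +
      if (config$hr_jitter_sd_bpm > 0) rnorm(1, 0, config$hr_jitter_sd_bpm) else 0
    hr <- max(hr, 20)
    Ti <- 60 / hr
    if (s + Ti > config$duration_s + 1e-9) break
    Ai <- config$systolic_amplitude *
      max(1 + if (config$amplitude_jitter_sd > 0)
        rnorm(1, 0, config$amplitude_jitter_sd) else 0, 0.1)
    ri <- config$notch_relative_intensity
    starts <- c(starts, s); periods <- c(periods, Ti)
    amps <- c(amps, Ai); notches <- c(notches, ri)
    s <- s + Ti
  }
  ncyc <- length(starts)
  if (ncyc < 2)
    stop("duration_s too short: need at least 2 full cardiac cycles")
  n <- round(s * fs)
  if (n < 2 * fs) stop("duration_s too short: need at least ~2 s of signal")
  t <- (seq_len(n) - 1) / fs

  # phantom preceding/following cycles give the record ends mid-stream tails
  ph_starts <- c(-periods[1], starts, s)
  ph_periods <- c(periods[1], periods, periods[ncyc])
  ph_amps <- c(amps[1], amps, amps[ncyc])
  ph_notches <- c(notches[1], notches, notches[ncyc])

  clean <- numeric(n); d1 <- numeric(n); d2 <- numeric(n)
  for (i in seq_along(ph_starts)) {
    u <- (t - ph_starts[i]) / ph_periods[i]
    win <- u > -0.75 & u < 1.75   # Gaussian tails beyond this are negligible
    if (!any(win)) next
    clean[win] <- clean[win] +
      .pulse_value(u[win], ph_amps[i], ph_notches[i], ps, ws, pd, wd)
    d1[win] <- d1[win] +
      .pulse_d1(u[win], ph_amps[i], ph_notches[i], ps, ws, pd, wd, ph_periods[i])
    d2[win] <- d2[win] +
      .pulse_d2(u[win], ph_amps[i], ph_notches[i], ps, ws, pd, wd, ph_periods[i])
  }

  wander <- if (config$wander_amplitude > 0)
    config$wander_amplitude *
      sin(2 * pi * config$wander_freq_hz * t + runif(1, 0, 2 * pi))
  else numeric(n)
  hfnoise <- if (config$noise_amplitude > 0)
    config$noise_amplitude *
      sin(2 * pi * config$noise_freq_hz * t + runif(1, 0, 2 * pi))
  else numeric(n)
  white <- if (config$white_noise_sd > 0) rnorm(n, 0, config$white_noise_sd)
  else numeric(n)
  ppg <- clean + wander + hfnoise + white

  # ---- ground truth per cycle ------------------------------------------
  # onset at boundary j = argmin of the clean train near the boundary time
  bnd <- c(starts, s)
  onset_of <- function(j) {
    prevT <- periods[max(j - 1L, 1L)]
    nextT <- periods[min(j, ncyc)]
    lo <- max(1, round((bnd[j] - 0.25 * prevT) * fs) + 1)
    hi <- min(n, round((bnd[j] + 0.25 * nextT) * fs) + 1)
    if (hi <= lo) return(NA_integer_)
    lo - 1L + which.min(clean[lo:hi])
  }
  gt <- vector("list", ncyc)
  sbps <- numeric(ncyc); dbps <- numeric(ncyc); floored <- logical(ncyc)
  co <- config$bp_map_coefficients
  for (i in seq_len(ncyc)) {
    m <- c(dur = periods[i], amp = amps[i], notch = notches[i])
    sbps[i] <- co$sbp[["intercept"]] + sum(co$sbp[c("dur", "amp", "notch")] * m) +
      if (config$label_noise_sd_mmHg > 0) rnorm(1, 0, config$label_noise_sd_mmHg) else 0
    dbps[i] <- co$dbp[["intercept"]] + sum(co$dbp[c("dur", "amp", "notch")] * m) +
      if (config$label_noise_sd_mmHg > 0) rnorm(1, 0, config$label_noise_sd_mmHg) else 0
    if (sbps[i] - dbps[i] < 5) { dbps[i] <- sbps[i] - 5; floored[i] <- TRUE }
  }
  for (i in seq_len(ncyc)) {
    onset <- onset_of(i)
    offset <- onset_of(i + 1L)
    complete <- !is.na(onset) && !is.na(offset) && offset <= n
    peak <- maxsl <- minsl <- notch <- NA_integer_
    if (complete && offset - onset >= 4) {
      span <- onset:offset
      peak <- onset - 1L + which.max(clean[span])
      if (peak > onset && peak < offset) {
        maxsl <- onset - 1L + which.max(d1[onset:peak])
        minsl <- peak - 1L + which.min(d1[peak:offset])
        # notch present only if the analytic slope has an interior local
        # maximum between peak and offset (signature of a dicrotic wave)
        rel <- .local_maxima(d1[peak:offset])
        if (length(rel) > 0) {
          cand <- .local_maxima(d2[peak:offset])
          if (length(cand) > 0) {
            vals <- d2[peak - 1L + cand]
            notch <- peak - 1L + cand[which.max(vals)]
          }
        }
      } else complete <- FALSE
    } else complete <- FALSE
    gt[[i]] <- data.frame(
      cycle = i, complete = complete, onset_idx = onset,
      max_slope_idx = maxsl, peak_idx = peak, min_slope_idx = minsl,
      notch_idx = notch, offset_idx = offset,
      duration_s = periods[i], amplitude = amps[i],
      notch_intensity = notches[i],
      sbp_mmHg = sbps[i], dbp_mmHg = dbps[i], pp_floored = floored[i])
  }
  gt <- do.call(rbind, gt)

  # ---- ABP channel: clean train rescaled per cycle to [DBP, SBP] -------
  abp <- numeric(n)
  bounds <- c(gt$onset_idx[gt$complete], gt$offset_idx[utils::tail(which(gt$complete), 1)])
  cyc_ids <- which(gt$complete)
  if (length(cyc_ids) > 0) {
    first_on <- gt$onset_idx[cyc_ids[1]]
    last_off <- gt$offset_idx[cyc_ids[length(cyc_ids)]]
    for (j in seq_along(cyc_ids)) {
      i <- cyc_ids[j]
      span <- gt$onset_idx[i]:gt$offset_idx[i]
      cmin <- min(clean[span]); cmax <- max(clean[span])
      abp[span] <- gt$dbp_mmHg[i] +
        (gt$sbp_mmHg[i] - gt$dbp_mmHg[i]) * (clean[span] - cmin) / (cmax - cmin)
    }
    if (first_on > 1) abp[1:(first_on - 1)] <- abp[first_on]
    if (last_off < n) abp[(last_off + 1):n] <- abp[last_off]
  }

  structure(list(
    ppg = ppg, abp = abp, clean = clean,
    sampling_rate_hz = fs,
    record_id = sprintf("synth-seed%d", config$seed),
    ground_truth = gt, config = config
  ), class = "waveform_record")
}

#' Generate a tabular feature/label dataset with a known affine map
#'
#' Draws feature rows from correlated standard Gaussians and produces
#' SBP/DBP labels as an exactly affine function of the features plus
#' Gaussian noise — a controlled task on which the regressor's ability to
#' recover a known mapping can be measured against the noise floor.
#'
#' @param n_cycles Number of rows (>= 1).
#' @param n_features Number of feature columns (default 32).
#' @param bp_map_coefficients List with `sbp_intercept`, `sbp_slopes`,
#'   `dbp_intercept`, `dbp_slopes` (slope vectors of length `n_features`).
#'   Default: intercepts 120/80 with a few nonzero leading slopes.
#' @param label_noise_sd Gaussian label noise sd in mmHg (0 = noiseless).
#' @param feature_cor Pairwise correlation of the Gaussian features.
#' @param seed Integer seed.
#' @return List with `features` (n x p matrix), `labels` (n x 2 matrix,
#'   columns SBP/DBP) and the map used.
#' @examples
#' d <- generate_feature_dataset(100, label_noise_sd = 0, seed = 1)
#' # labels are exactly affine in the features:
#' max(abs(stats::lm.fit(cbind(1, d$features), d$labels)$residuals)) < 1e-9
#' @export
generate_feature_dataset <- function(n_cycles,
                                     n_features = 32,
                                     bp_map_coefficients = NULL,
                                     label_noise_sd = 0,
                                     feature_cor = 0.3,
                                     seed = 1L) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (label_noise_sd < 0) stop("label_noise_sd must be nonnegative")
  if (feature_cor < 0 || feature_cor >= 1) stop("feature_cor must be in [0, 1)")
  set.seed(as.integer(seed))
  p <- n_features
  if (is.null(bp_map_coefficients)) {
    sb <- numeric(p); sb[seq_len(min(3, p))] <- c(10, -5, 3)[seq_len(min(3, p))]
    db <- numeric(p); db[seq_len(min(4, p))] <- c(6, -3, 0, 2)[seq_len(min(4, p))]
    bp_map_coefficients <- list(sbp_intercept = 120, sbp_slopes = sb,
                                dbp_intercept = 80, dbp_slopes = db)
  }
  stopifnot(length(bp_map_coefficients$sbp_slopes) == p,
            length(bp_map_coefficients$dbp_slopes) == p)
  sigma <- matrix(feature_cor, p, p); diag(sigma) <- 1
  X <- matrix(rnorm(n_cycles * p), n_cycles, p) %*% chol(sigma)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  sbp <- bp_map_coefficients$sbp_intercept +
    drop(X %*% bp_map_coefficients$sbp_slopes)
  dbp <- bp_map_coefficients$dbp_intercept +
    drop(X %*% bp_map_coefficients$dbp_slopes)
  if (label_noise_sd > 0) {
    sbp <- sbp + rnorm(n_cycles, 0, label_noise_sd)
    dbp <- dbp + rnorm(n_cycles, 0, label_noise_sd)
  }
  list(features = X, labels = cbind(SBP = sbp, DBP = dbp),
       bp_map_coefficients = bp_map_coefficients,
       label_noise_sd = label_noise_sd)
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %s: %d samples @ %g Hz (%.1f s), %d complete cycles\n",
              x$record_id, length(x$ppg), x$sampling_rate_hz,
              length(x$ppg) / x$sampling_rate_hz, sum(x$ground_truth$complete)))
  invisible(x)
}
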
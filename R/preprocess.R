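#' Band-limit a signal by zeroing DFT bins
#'
#' Transforms the signal with the FFT, zeroes every frequency bin whose
#' frequency lies outside `[low_cut_hz, high_cut_hz]` (inclusive bounds;
#' bins are zeroed symmetrically in both conjugate halves so the inverse
#' transform is real), and restores the signal with the inverse FFT. With
#' the defaults this removes high-frequency noise above 8 Hz while keeping
#' the DC component and everything below, the standard denoising step for
#' pulse waveforms. The operation is idempotent.
#'
#' @param x Numeric signal (length >= 2).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param high_cut_hz Upper passband edge in Hz (default 8); must be below
#'   the Nyquist frequency.
#' @param low_cut_hz Lower passband edge in Hz (default 0, i.e. no
#'   high-pass).
#' @return Real numeric vector of the same length.
#' @examples
#' fs <- 125; t <- (0:999) / fs
#' x <- sin(2 * pi * 1 * t) + sin(2 * pi * 25 * t)
#' y <- bandlimit(x, fs)            # the 25 Hz component is removed
#' max(abs(y - sin(2 * pi * 1 * t))) < 1e-9
#' @export
bandlimit <- function(x, sampling_rate_hz, high_cut_hz = 8, low_cut_hz = 0) {
  if (length(x) < 2) stop("signal must have at least 2 samples")
  if (!is.numeric(x) || anyNA(x)) stop("signal must be numeric without NAs")
  nyq <- sampling_rate_hz / 2
  if (high_cut_hz >= nyq) stop("high_cut_hz must be below the Nyquist frequency (",
                               nyq, " Hz)")
  if (low_cut_hz < 0 || low_cut_hz >= high_cut_hz)
    stop("low_cut_hz must be in [0, high_cut_hz)")
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * sampling_rate_hz / n  # folded bin frequency
  tol <- 1e-9
  keep <- freq <= high_cut_hz + tol & freq >= low_cut_hz - tol
  Re(stats::fft(X * keep, inverse = TRUE)) / n
}

#' Min-max normalize a segment to [0, 1]
#'
#' Applies `(x - min) / (max - min)`. The minimum of the output is 0 and
#' the maximum 1; the map is order-preserving.
#'
#' @param x Numeric vector (length >= 2) with `max(x) > min(x)`.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2) stop("segment must have at least 2 samples")
  lo <- min(x); hi <- max(x)
  if (hi == lo) stop("degenerate segment: max equals min, range is zero")
  (x - lo) / (hi - lo)
}

#' First and second discrete derivatives of a signal
#'
#' Central differences on interior points, one-sided differences at the
#' ends, scaled by the sampling interval. The second derivative applies the
#' same scheme to the first.
#'
#' @param x Numeric signal (length >= 3).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return List with `dppg` and `sdppg`, each the same length as `x`.
#' @export
derivatives <- function(x, sampling_rate_hz) {
  n <- length(x)
  if (n < 3) stop("signal must have at least 3 samples")
  deriv1 <- function(v) {
    n <- length(v)
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * sampling_rate_hz / 2
    d[1] <- (v[2] - v[1]) * sampling_rate_hz
    d[n] <- (v[n] - v[n - 1]) * sampling_rate_hz
    d
  }
  dppg <- deriv1(x)
  list(dppg = dppg, sdppg = deriv1(dppg))
}

#' Preprocess a waveform record
#'
#' Runs the standard chain: band-limit the raw PPG to `[low_cut_hz,
#' high_cut_hz]`, min-max normalize the whole segment to `[0, 1]`, and
#' compute first (dPPG) and second (sdPPG) discrete derivatives. An ABP
#' channel, when present, is carried through untouched.
#'
#' @param record A `waveform_record` (from [generate_record()] or
#'   [read_waveform()]).
#' @param high_cut_hz,low_cut_hz Passband edges passed to [bandlimit()].
#' @return Object of class `preprocessed_record`: list with `ppg` (in
#'   `[0, 1]`), `dppg`, `sdppg`, `abp`, `sampling_rate_hz`, `record_id`.
#' @export
preprocess_record <- function(record, high_cut_hz = 8, low_cut_hz = 0) {
  stopifnot(inherits(record, "waveform_record"))
  if (length(record$ppg) < 2 * record$sampling_rate_hz)
    stop("record too short: need at least ~2 s of signal")
  filt <- bandlimit(record$ppg, record$sampling_rate_hz,
                    high_cut_hz = high_cut_hz, low_cut_hz = low_cut_hz)
  ppg <- minmax_normalize(filt)
  d <- derivatives(ppg, record$sampling_rate_hz)
  structure(list(
    ppg = ppg, dppg = d$dppg, sdppg = d$sdppg,
    abp = record$abp, sampling_rate_hz = record$sampling_rate_hz,
    record_id = record$record_id
  ), class = "preprocessed_record")
}

#' @export
print.preprocessed_record <- function(x, ...) {
  cat(sprintf("<preprocessed_record> %s: %d samples @ %g Hz, ppg in [%.3f, %.3f]\n",
              x$record_id, length(x$ppg), x$sampling_rate_hz,
              min(x$ppg), max(x$ppg)))
  invisible(x)
}
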
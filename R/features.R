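#' Canonical names of the 59 morphological features
#'
#' Feature families: heart rate (`hr`); sub-cycle durations `t1`-`t8`;
#' ascending/descending slopes of PPG, dPPG and sdPPG (`AS`/`dAS`/`sdAS`,
#' `DS`/`dDS`/`sdDS`); areas `S1`-`S4`, `AA`/`DA` families and their
#' ratios; peak/valley/notch intensities; intensity differences and
#' ratios; timing intervals; the notch slope `Slope_a`; augmentation
#' indices `AI`/`AI1`; and duration ratios `RSD`/`RSC`/`RDC`. A `d`/`sd`
#' prefix means the analogous quantity read from the first/second
#' derivative signal using that signal's own cycle-local landmarks.
#'
#' @return Character vector of length 59.
#' @export
ppg_feature_names <- function() {
  c("hr", "t1", "t2", "t3", "t4", "t5", "t6", "t7", "t8",
    "AS", "dAS", "sdAS", "DS", "dDS", "sdDS",
    "S1", "S2", "AA", "dAA", "sdAA", "DA", "dDA", "sdDA",
    "RAAD", "dRAAD", "sdRAAD",
    "PI", "dPI", "sdPI", "dVI", "sdVI",
    "AID", "dAID", "sdAID", "dDID", "sdDID",
    "PIR", "dPIR", "sdPIR", "dRIPV", "sdRIPV",
    "AT", "dAT", "sdAT", "DT", "dDT", "sdDT",
    "dTVO", "sdTVO",
    "Slope_a", "S3", "S4", "RtArea",
    "NI", "AI", "AI1", "RSD", "RSC", "RDC")
}

# NA-safe ratio and slope helpers
.safe_div <- function(num, den) {
  if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
}
.slope <- function(y2, y1, i2, i1, fs) {
  if (anyNA(c(i1, i2)) || i2 == i1) return(NA_real_)
  (y2 - y1) / ((i2 - i1) / fs)
}

#' Compute the 59 morphological features of one cycle
#'
#' Time features are fiducial index differences divided by the sampling
#' rate; areas are trapezoidal integrals of the named signal between the
#' named fiducials (normalized intensity times seconds); slopes are
#' intensity differences over time differences; intensity features read the
#' named signal at the named fiducial; ratios are composed from these.
#' Derivative-signal features (`d`/`sd` prefix) use the fragment's own peak
#' (argmax) and valley (argmin) as landmarks. When the dicrotic notch is
#' absent, notch-dependent features (`t3`, `t4`, `S3`, `S4`, `Slope_a`,
#' `RtArea`, `NI`, `AI`, `AI1`, `RSD`, `RSC`, `RDC`) are `NA`, as is any
#' feature with a zero denominator.
#'
#' @param segment A `cycle_segment`.
#' @return Named numeric vector of length 59 (see [ppg_feature_names()]).
#' @export
compute_features <- function(segment) {
  stopifnot(inherits(segment, "cycle_segment"))
  f <- segment$fiducials
  fs <- segment$sampling_rate_hz
  p <- segment$ppg_fragment
  d <- segment$dppg_fragment
  s <- segment$sdppg_fragment
  n <- length(p)
  o <- f$onset_idx; pk <- f$systolic_peak_idx
  ms <- f$max_slope_idx; nt <- f$dicrotic_notch_idx; off <- f$offset_idx
  dt <- 1 / fs

  dpk <- which.max(d); dvl <- which.min(d)
  spk <- which.max(s); svl <- which.min(s)

  out <- stats::setNames(rep(NA_real_, 59), ppg_feature_names())
  dur <- (off - o) / fs
  out["hr"] <- 60 / dur

  has_ms <- !is.na(ms); has_nt <- !is.na(nt)
  if (has_ms) out["t1"] <- (ms - o) / fs
  if (has_ms) out["t2"] <- (pk - ms) / fs
  if (has_nt) out["t3"] <- (nt - pk) / fs
  if (has_nt) out["t4"] <- (off - nt) / fs
  out["t5"] <- (dpk - o) / fs        # dPPG ascending duration
  out["t6"] <- (off - dpk) / fs      # dPPG descending duration
  out["t7"] <- (spk - o) / fs        # sdPPG ascending duration
  out["t8"] <- (off - spk) / fs      # sdPPG descending duration

  out["AS"] <- .slope(p[pk], p[o], pk, o, fs)
  out["dAS"] <- .slope(d[dpk], d[o], dpk, o, fs)
  out["sdAS"] <- .slope(s[spk], s[o], spk, o, fs)
  out["DS"] <- .slope(p[off], p[pk], off, pk, fs)
  out["dDS"] <- .slope(d[off], d[dpk], off, dpk, fs)
  out["sdDS"] <- .slope(s[off], s[spk], off, spk, fs)

  if (has_ms) {
    out["S1"] <- trapz(p[o:ms], dt)
    out["S2"] <- trapz(p[ms:pk], dt)
  }
  out["AA"] <- trapz(p[o:pk], dt)
  out["dAA"] <- trapz(d[o:dpk], dt)
  out["sdAA"] <- trapz(s[o:spk], dt)
  out["DA"] <- trapz(p[pk:off], dt)
  out["dDA"] <- trapz(d[dpk:off], dt)
  out["sdDA"] <- trapz(s[spk:off], dt)
  out["RAAD"] <- .safe_div(out[["AA"]], out[["DA"]])
  out["dRAAD"] <- .safe_div(out[["dAA"]], out[["dDA"]])
  out["sdRAAD"] <- .safe_div(out[["sdAA"]], out[["sdDA"]])

  out["PI"] <- p[pk]; out["dPI"] <- d[dpk]; out["sdPI"] <- s[spk]
  out["dVI"] <- d[dvl]; out["sdVI"] <- s[svl]
  out["AID"] <- p[pk] - p[o]
  out["dAID"] <- d[dpk] - d[o]
  out["sdAID"] <- s[spk] - s[o]
  out["dDID"] <- d[off] - d[dpk]
  out["sdDID"] <- s[off] - s[spk]
  out["PIR"] <- .safe_div(p[pk], p[o])
  out["dPIR"] <- .safe_div(d[dpk], d[o])
  out["sdPIR"] <- .safe_div(s[spk], s[o])
  out["dRIPV"] <- .safe_div(d[dpk], d[dvl])
  out["sdRIPV"] <- .safe_div(s[spk], s[svl])

  out["AT"] <- (pk - o) / fs
  out["dAT"] <- (dpk - o) / fs
  out["sdAT"] <- (spk - o) / fs
  out["DT"] <- (off - pk) / fs
  out["dDT"] <- (off - dpk) / fs
  out["sdDT"] <- (off - spk) / fs
  out["dTVO"] <- (off - dvl) / fs
  out["sdTVO"] <- (off - svl) / fs

  if (has_nt) {
    out["Slope_a"] <- .slope(p[nt], p[pk], nt, pk, fs)
    out["S3"] <- trapz(p[pk:nt], dt)
    out["S4"] <- trapz(p[nt:off], dt)
    if (has_ms)
      out["RtArea"] <- .safe_div(out[["S1"]] + out[["S2"]] + out[["S3"]],
                                 out[["S4"]])
    out["NI"] <- p[nt]
    out["AI"] <- .safe_div(p[nt], p[pk])
    out["AI1"] <- .safe_div(p[pk] - p[nt], p[pk])
    if (has_ms) {
      syst <- out[["t1"]] + out[["t2"]] + out[["t3"]]
      out["RSD"] <- .safe_div(syst, out[["t4"]])
      out["RSC"] <- .safe_div(out[["t4"]], syst + out[["t4"]])
      out["RDC"] <- .safe_div(syst, syst + out[["t4"]])
    }
  }
  out
}

#' Feature matrix and labels for a list of cycle segments
#'
#' @param segments List of `cycle_segment` objects.
#' @return List with `features` (n x 59 matrix, columns named per
#'   [ppg_feature_names()]), `sbp` and `dbp` label vectors (NA when
#'   unlabelled).
#' @export
compute_feature_matrix <- function(segments) {
  if (length(segments) == 0) stop("no segments supplied")
  X <- t(vapply(segments, compute_features, numeric(59)))
  colnames(X) <- ppg_feature_names()
  list(features = X,
       sbp = vapply(segments, function(s) s$sbp_mmHg, numeric(1)),
       dbp = vapply(segments, function(s) s$dbp_mmHg, numeric(1)))
}

#' Z-score standardize a feature matrix
#'
#' Each column is centred by its mean and divided by its standard
#' deviation (population convention by default), giving columns with mean
#' 0 and sd 1. The per-feature parameters are retained so the transform
#' can be inverted or re-applied to new data at prediction time. `NA`
#' entries are ignored when estimating the parameters and propagate
#' through the transform.
#'
#' @param x Numeric matrix (>= 2 rows) with named columns.
#' @param center,scale Optional stored parameters to re-apply; computed
#'   from `x` when `NULL`.
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return Object of class `standardized_features`: list with `x`
#'   (standardized matrix), `center`, `scale`, `sd_type`.
#' @export
standardize_features <- function(x, center = NULL, scale = NULL,
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to standardize")
  if (is.null(center) || is.null(scale)) {
    center <- apply(x, 2, function(col) mean(col[is.finite(col)]))
    scale <- apply(x, 2, function(col) sd_of(col[is.finite(col)], sd_type))
    bad <- which(!is.finite(scale) | scale == 0)
    if (length(bad) > 0)
      stop("zero-variance feature(s): ",
           paste(colnames(x)[bad], collapse = ", "))
  }
  z <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  structure(list(x = z, center = center, scale = scale, sd_type = sd_type),
            class = "standardized_features")
}

#' Invert a standardization
#'
#' @param std A `standardized_features` object.
#' @param z Optional standardized matrix to invert (defaults to `std$x`).
#' @return Matrix on the original scale.
#' @export
unstandardize_features <- function(std, z = std$x) {
  stopifnot(inherits(std, "standardized_features"))
  sweep(sweep(z, 2, std$scale, "*"), 2, std$center, "+")
}
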
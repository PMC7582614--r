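#' Distribution-similarity index gamma for one standardized feature
#'
#' Measures how closely a standardized feature's empirical distribution
#' matches the standard normal: the feature values are rounded to `k`
#' decimal places (half away from zero), giving an empirical probability
#' mass on the grid `v = -C, -C + 10^-k, ..., +C`; gamma is the mean over
#' the `2*C*10^k + 1` grid points of the absolute difference between the
#' empirical mass at `v` and the standard-normal mass of the bin
#' `[v, v + 10^-k)`. Mass outside the `mu +/- C sigma` window is ignored.
#' A smaller gamma means a more normal-shaped feature; gamma is 0 exactly
#' when the empirical bin masses equal the normal bin masses on the grid.
#'
#' @param x Standardized numeric vector (mean approximately 0, sd
#'   approximately 1); `NA`s are dropped.
#' @param k Decimal precision of the grid (default 1).
#' @param C Half-width of the window in sd multiples (default 3).
#' @param check_standardized Error if `|mean| > 0.05` or `|sd - 1| > 0.05`
#'   (population sd). Set `FALSE` for diagnostic use on shifted columns.
#' @return Nonnegative scalar gamma.
#' @examples
#' set.seed(1)
#' gamma_index(scale(rnorm(1e4))[, 1])   # small: sample is normal
#' @export
gamma_index <- function(x, k = 1, C = 3, check_standardized = TRUE) {
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  if (C < 1 || C != round(C)) stop("C must be a positive integer")
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite values")
  if (check_standardized) {
    if (abs(mean(x)) > 0.05 || abs(sd_of(x, "population") - 1) > 0.05)
      stop("input does not look standardized (|mean| > 0.05 or |sd - 1| > 0.05)")
  }
  p <- as.integer(10^k)
  grid <- seq.int(-C * p, C * p)           # integer grid, labels grid / p
  xi <- as.integer(round(round_half_away(x, k) * p))
  emp <- tabulate(match(xi, grid), nbins = length(grid)) / length(x)
  gamma_from_masses(emp, k = k, C = C)
}

#' Gamma index from precomputed empirical bin masses
#'
#' The grid-level core of [gamma_index()]: given the empirical probability
#' mass at each grid point `v = -C, -C + 10^-k, ..., +C`, returns the mean
#' absolute difference from the standard-normal mass of each bin
#' `[v, v + 10^-k)`. Zero exactly when the masses coincide.
#'
#' @param emp_mass Numeric vector of length `2*C*10^k + 1`: empirical mass
#'   per grid point (need not sum to 1; mass outside the window is simply
#'   absent).
#' @param k,C Grid parameters as in [gamma_index()].
#' @return Nonnegative scalar gamma.
#' @export
gamma_from_masses <- function(emp_mass, k = 1, C = 3) {
  p <- as.integer(10^k)
  grid <- seq.int(-C * p, C * p)
  if (length(emp_mass) != length(grid))
    stop("emp_mass must have length ", length(grid))
  normal_mass <- stats::pnorm((grid + 1) / p) - stats::pnorm(grid / p)
  mean(abs(emp_mass - normal_mass))
}

#' Gamma index for every column of a standardized feature matrix
#'
#' @param std A `standardized_features` object or a standardized matrix.
#' @param k,C Grid parameters, see [gamma_index()].
#' @return Named numeric vector of gamma values (NA for columns with fewer
#'   than 2 finite values).
#' @export
gamma_indices <- function(std, k = 1, C = 3) {
  x <- if (inherits(std, "standardized_features")) std$x else as.matrix(std)
  vapply(colnames(x), function(nm) {
    tryCatch(gamma_index(x[, nm], k = k, C = C),
             error = function(e) NA_real_)
  }, numeric(1))
}

#' Rank features by gamma and select the working set
#'
#' Ranks the finite-gamma features ascending (ties broken by feature name)
#' and assembles a selected set of size `n_lowest`: forced inclusions
#' first, then the lowest-gamma features, skipping forced exclusions,
#' until the set is full. Features with non-finite gamma are never
#' auto-selected. The default overrides swap `S1`/`S2` in for
#' `sdAS`/`sdDS`: the area features are classical pressure correlates,
#' and regressors fed `sdAS`/`sdDS` underperform those fed `S1`/`S2`.
#'
#' @param gamma Named numeric vector of gamma values (NA = excluded).
#' @param n_lowest Size of the selected set (default 32).
#' @param force_include,force_exclude Feature name overrides.
#' @return Object of class `gamma_selection`: data frame with columns
#'   `feature`, `gamma`, `rank` (NA for non-finite gamma), `selected`,
#'   `forced_in`, `forced_out`; the selected names are in
#'   `attr(, "selected")`.
#' @export
rank_and_select <- function(gamma, n_lowest = 32,
                            force_include = c("S1", "S2"),
                            force_exclude = c("sdAS", "sdDS")) {
  if (is.null(names(gamma))) stop("gamma must be a named vector")
  if (length(intersect(force_include, force_exclude)) > 0)
    stop("force_include and force_exclude overlap")
  if (!all(force_include %in% names(gamma)))
    stop("force_include names absent from gamma")
  finite <- names(gamma)[is.finite(gamma)]
  if (length(union(finite, force_include)) < n_lowest)
    stop("n_lowest exceeds the number of selectable features")
  ord <- finite[order(gamma[finite], finite)]
  rank <- stats::setNames(rep(NA_integer_, length(gamma)), names(gamma))
  rank[ord] <- seq_along(ord)

  selected <- force_include
  for (nm in ord) {
    if (length(selected) >= n_lowest) break
    if (nm %in% selected || nm %in% force_exclude) next
    selected <- c(selected, nm)
  }
  if (length(selected) > n_lowest) selected <- selected[seq_len(n_lowest)]

  report <- data.frame(
    feature = names(gamma), gamma = unname(gamma),
    rank = unname(rank[names(gamma)]),
    selected = names(gamma) %in% selected,
    forced_in = names(gamma) %in% force_include,
    forced_out = names(gamma) %in% force_exclude,
    row.names = NULL)
  structure(report, class = c("gamma_selection", "data.frame"),
            selected = selected)
}

#' @export
print.gamma_selection <- function(x, ...) {
  sel <- attr(x, "selected")
  cat(sprintf("<gamma_selection> %d of %d features selected\n",
              length(sel), nrow(x)))
  print.data.frame(utils::head(x[order(x$rank), ], 10), row.names = FALSE)
  cat("...\n")
  invisible(x)
}

#' Selected feature names of a gamma selection
#' @param selection A `gamma_selection` object.
#' @return Character vector of selected feature names (rank order after
#'   forced inclusions).
#' @export
selected_features <- function(selection) {
  stopifnot(inherits(selection, "gamma_selection"))
  attr(selection, "selected")
}

#' Published reference gamma values for the 59 features
#'
#' Gamma values computed on a large ICU pulse-waveform corpus (about 2.18
#' million cardiac cycles), shipped with the package as the default
#' ranking for feature selection when no corpus of comparable size is
#' available. Features whose published gamma was deemed too large to
#' consider carry `NA`.
#'
#' @return Named numeric vector of length 59.
#' @export
reference_gamma <- function() {
  path <- system.file("extdata", "reference_gamma.csv", package = "ppgbp",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(d$gamma, d$feature)
}

#' Published reference performance summary
#'
#' The device-grading summary published for the reference large-corpus
#' PPG-only estimator: BHS cumulative-error percentages, AAMI mean
#' error/sd pairs, RMSE/MAE, Pearson r and Bland-Altman limits of
#' agreement for SBP and DBP. Used by the acceptance script to exercise
#' the grading operations on published inputs.
#'
#' @return Data frame with columns `target`, `metric`, `value`.
#' @export
reference_performance <- function() {
  path <- system.file("extdata", "reference_performance.csv",
                      package = "ppgbp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
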
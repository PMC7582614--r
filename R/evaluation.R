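#' Root mean square error and mean absolute error
#'
#' `bp_rmse` is `sqrt(mean((estimate - truth)^2))`; `bp_mae` is
#' `mean(|estimate - truth|)`. RMSE is always at least the MAE.
#'
#' @param truth,estimate Equal-length nonempty numeric vectors (mmHg).
#' @return Scalar in mmHg.
#' @export
bp_rmse <- function(truth, estimate) {
  .check_pair(truth, estimate)
  sqrt(mean((estimate - truth)^2))
}

#' @rdname bp_rmse
#' @export
bp_mae <- function(truth, estimate) {
  .check_pair(truth, estimate)
  mean(abs(estimate - truth))
}

.check_pair <- function(truth, estimate) {
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(estimate)) stop("length mismatch")
  invisible(TRUE)
}

#' AAMI device check
#'
#' A device passes the AAMI criterion when the absolute mean error is at
#' most 5 mmHg and the error standard deviation at most 8 mmHg. Supply
#' either an error vector (errors = estimate - truth) or a precomputed
#' mean/sd pair; the inputs are echoed in the result.
#'
#' @param errors Numeric error vector (mmHg), or `NULL` when supplying the
#'   summary pair.
#' @param mean_error,sd_error Precomputed error mean and sd (mmHg).
#' @param mean_limit,sd_limit Criterion bounds (defaults 5 and 8 mmHg).
#' @param sd_type Population or sample sd when computed from `errors`.
#' @return List with `mean_error`, `sd_error`, `pass`.
#' @examples
#' aami_check(mean_error = 3.21, sd_error = 3.35)$pass  # TRUE
#' @export
aami_check <- function(errors = NULL, mean_error = NULL, sd_error = NULL,
                       mean_limit = 5, sd_limit = 8,
                       sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!is.null(errors)) {
    if (length(errors) == 0) stop("empty error vector")
    mean_error <- mean(errors)
    sd_error <- sd_of(errors, sd_type)
  }
  if (is.null(mean_error) || is.null(sd_error))
    stop("supply errors or both mean_error and sd_error")
  list(mean_error = mean_error, sd_error = sd_error,
       pass = abs(mean_error) <= mean_limit && sd_error <= sd_limit)
}

# BHS grade thresholds: cumulative % of |error| <= 5/10/15 mmHg
.bhs_thresholds <- rbind(A = c(60, 85, 95),
                         B = c(50, 75, 90),
                         C = c(40, 65, 85))

#' BHS grade from cumulative error percentages
#'
#' Grades a device from the cumulative percentages of absolute errors at
#' or below 5, 10 and 15 mmHg. Grade A requires at least 60/85/95
#' percent, grade B 50/75/90, grade C 40/65/85; anything less is D. The
#' best grade whose three thresholds are all met is returned, along with
#' the input percentages.
#'
#' @param cum_pct_5,cum_pct_10,cum_pct_15 Percentages in `[0, 100]`,
#'   non-decreasing.
#' @return List with `grade` (`"A"`/`"B"`/`"C"`/`"D"`) and the echoed
#'   `cum_pct_5`, `cum_pct_10`, `cum_pct_15`.
#' @examples
#' bhs_grade(80.63, 95.86, 98.78)$grade  # "A"
#' @export
bhs_grade <- function(cum_pct_5, cum_pct_10, cum_pct_15) {
  p <- c(cum_pct_5, cum_pct_10, cum_pct_15)
  if (any(p < 0 | p > 100)) stop("percentages must lie in [0, 100]")
  if (is.unsorted(p)) stop("non-monotone cumulative percentages")
  grade <- "D"
  for (g in c("C", "B", "A"))
    if (all(p >= .bhs_thresholds[g, ])) grade <- g
  list(grade = grade, cum_pct_5 = cum_pct_5, cum_pct_10 = cum_pct_10,
       cum_pct_15 = cum_pct_15)
}

#' Pearson correlation coefficient
#'
#' The normalized covariance of the two vectors, in `[-1, 1]`.
#'
#' @param x,y Equal-length numeric vectors (length >= 2) with nonzero
#'   variance.
#' @return Scalar correlation.
#' @export
pearson_r <- function(x, y) {
  .check_pair(x, y)
  if (length(x) < 2) stop("need at least 2 points")
  if (sd_of(x, "population") == 0 || sd_of(y, "population") == 0)
    stop("zero variance input")
  stats::cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `estimate - truth`; the limits of agreement are the
#' mean difference plus/minus 1.96 standard deviations, and the
#' percentage of differences inside the limits is reported.
#'
#' @param truth,estimate Equal-length numeric vectors (length >= 2).
#' @param sd_type Population or sample sd of the differences.
#' @return List with `mean_diff`, `loa_low`, `loa_high`,
#'   `pct_within_loa`.
#' @export
bland_altman <- function(truth, estimate,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  .check_pair(truth, estimate)
  if (length(truth) < 2) stop("need at least 2 pairs")
  d <- estimate - truth
  md <- mean(d); s <- sd_of(d, sd_type)
  loa <- c(md - 1.96 * s, md + 1.96 * s)
  list(mean_diff = md, loa_low = loa[1], loa_high = loa[2],
       pct_within_loa = 100 * mean(d >= loa[1] & d <= loa[2]))
}

#' Cumulative percentages of absolute errors within thresholds
#'
#' @param truth,estimate Equal-length numeric vectors.
#' @param thresholds Error thresholds in mmHg (inclusive comparison).
#' @return Numeric vector of percentages.
#' @export
cumulative_error_pct <- function(truth, estimate, thresholds = c(5, 10, 15)) {
  .check_pair(truth, estimate)
  err <- abs(estimate - truth)
  vapply(thresholds, function(thr) 100 * mean(err <= thr), numeric(1))
}

#' Full evaluation report for paired SBP/DBP estimates
#'
#' Assembles, per pressure target, RMSE, MAE, mean error and error sd
#' (error = estimate - truth), the Pearson correlation with the truth,
#' Bland-Altman limits of agreement, cumulative percentages of absolute
#' errors at or below 5/10/15 mmHg (inclusive), the BHS grade and the
#' AAMI verdict.
#'
#' @param truth_sbp,truth_dbp,est_sbp,est_dbp Aligned numeric vectors in
#'   mmHg (length >= 2).
#' @param sd_type Population or sample sd convention.
#' @return Object of class `bp_eval_report`: list with elements `SBP` and
#'   `DBP`, each holding the fields above, plus `n`.
#' @export
evaluate_bp <- function(truth_sbp, truth_dbp, est_sbp, est_dbp,
                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  .check_pair(truth_sbp, est_sbp)
  .check_pair(truth_dbp, est_dbp)
  if (length(truth_sbp) < 2)
    stop("need at least 2 pairs (correlation undefined for one pair)")
  one <- function(truth, est) {
    err <- est - truth
    cp <- cumulative_error_pct(truth, est)
    ba <- bland_altman(truth, est, sd_type)
    bhs <- bhs_grade(cp[1], cp[2], cp[3])
    am <- aami_check(errors = err, sd_type = sd_type)
    list(rmse = bp_rmse(truth, est), mae = bp_mae(truth, est),
         mean_error = am$mean_error, sd_error = am$sd_error,
         pearson_r = pearson_r(truth, est),
         loa_low = ba$loa_low, loa_high = ba$loa_high,
         pct_within_loa = ba$pct_within_loa,
         cum_pct_5 = cp[1], cum_pct_10 = cp[2], cum_pct_15 = cp[3],
         bhs_grade = bhs$grade, aami_pass = am$pass)
  }
  structure(list(SBP = one(truth_sbp, est_sbp),
                 DBP = one(truth_dbp, est_dbp),
                 n = length(truth_sbp)),
            class = "bp_eval_report")
}

#' @export
print.bp_eval_report <- function(x, ...) {
  cat(sprintf("<bp_eval_report> n = %d\n", x$n))
  for (tg in c("SBP", "DBP")) {
    r <- x[[tg]]
    cat(sprintf(
      "  %s: RMSE %.3f  MAE %.3f  ME %.3f  SD %.3f mmHg | r %.3f | LOA [%.2f, %.2f] | <=5/10/15: %.1f/%.1f/%.1f%% | BHS %s | AAMI %s\n",
      tg, r$rmse, r$mae, r$mean_error, r$sd_error, r$pearson_r,
      r$loa_low, r$loa_high, r$cum_pct_5, r$cum_pct_10, r$cum_pct_15,
      r$bhs_grade, if (r$aami_pass) "pass" else "fail"))
  }
  invisible(x)
}

#' Flatten an evaluation report to a data frame
#' @param report A `bp_eval_report`.
#' @return Data frame with one row per target.
#' @export
eval_report_table <- function(report) {
  stopifnot(inherits(report, "bp_eval_report"))
  do.call(rbind, lapply(c("SBP", "DBP"), function(tg) {
    r <- report[[tg]]
    data.frame(target = tg, rmse = r$rmse, mae = r$mae,
               mean_error = r$mean_error, sd_error = r$sd_error,
               pearson_r = r$pearson_r, loa_low = r$loa_low,
               loa_high = r$loa_high, cum_pct_5 = r$cum_pct_5,
               cum_pct_10 = r$cum_pct_10, cum_pct_15 = r$cum_pct_15,
               bhs_grade = r$bhs_grade, aami_pass = r$aami_pass)
  }))
}
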
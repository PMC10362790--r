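# Metrics and device-standard compliance: MAE/RMSE/ME/SD/r2, Bland-Altman
# agreement data, the AAMI accuracy criterion and BHS cumulative-error
# grading, plus subgroup reporting.

#' Paired predictions container
#'
#' @param y Ground-truth labels (mmHg or percent).
#' @param yhat Model predictions, same length.
#' @param subject_id Subject identifier per pair.
#' @param target Target name (e.g. `"ASBP"`).
#' @return A data.frame of class `paired_predictions`.
#' @export
paired_predictions <- function(y, yhat, subject_id = "all",
                               target = "ASBP") {
  if (length(y) != length(yhat)) stop_field("y/yhat", "must have equal length")
  if (any(!is.finite(y)) || any(!is.finite(yhat))) {
    stop_field("y/yhat", "values must be finite")
  }
  structure(data.frame(y = as.numeric(y), yhat = as.numeric(yhat),
                       subject_id = rep_len(as.character(subject_id), length(y)),
                       target = rep_len(target, length(y)),
                       stringsAsFactors = FALSE),
            class = c("paired_predictions", "data.frame"))
}

#' Error metrics for paired predictions
#'
#' `mae` is the mean absolute error, `rmse` the root mean squared error,
#' `me_sd` the signed mean error and the (n-1) sample standard deviation of
#' the signed errors, and `r2` the squared Pearson correlation between
#' prediction and truth.
#'
#' @param p A [paired_predictions()] object.
#' @return `mae`, `rmse`, `r2`: a scalar; `me_sd`: a list with `me`, `sd`.
#' @export
mae <- function(p) mean(abs(p$yhat - p$y))

#' @rdname mae
#' @export
rmse <- function(p) sqrt(mean((p$yhat - p$y)^2))

#' @rdname mae
#' @export
me_sd <- function(p) {
  e <- p$yhat - p$y
  list(me = mean(e), sd = stats::sd(e))
}

#' @rdname mae
#' @export
r2 <- function(p) {
  if (nrow(p) < 2 || stats::sd(p$y) == 0 || stats::sd(p$yhat) == 0) {
    stop("r2 undefined: need n >= 2 and nonzero variance in both series",
         call. = FALSE)
  }
  stats::cor(p$y, p$yhat)^2
}

#' Bland-Altman agreement data
#'
#' For each pair, the abscissa is the mean of prediction and truth and the
#' ordinate their difference; the limits of agreement are the bias plus or
#' minus 1.96 standard deviations of the differences.
#'
#' @param p A [paired_predictions()] object with at least 2 pairs.
#' @return A list of class `bland_altman`: `points` (data.frame `mean`,
#'   `difference`), `bias`, `loa_lower`, `loa_upper`.
#' @export
bland_altman <- function(p) {
  stopifnot(nrow(p) >= 2)
  d <- p$yhat - p$y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(points = data.frame(mean = (p$yhat + p$y) / 2,
                                     difference = d),
                 bias = bias, loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s),
            class = "bland_altman")
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$points$mean, x$points$difference,
                 xlab = "(prediction + truth) / 2",
                 ylab = "prediction - truth", pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = "grey30")
  invisible(x)
}

#' AAMI accuracy criterion
#'
#' Pass iff the cohort has more than 85 subjects, the absolute mean error
#' is below 5 mmHg, and the error standard deviation is below 8 mmHg
#' (strict inequalities).
#'
#' @param report A `compliance_report`, or the subject count `n_subjects`
#'   when `me` and `sd` are given explicitly.
#' @param me,sd Signed mean error and error SD (mmHg).
#' @return Logical.
#' @export
aami_check <- function(report, me = NULL, sd = NULL) {
  if (inherits(report, "compliance_report")) {
    n <- report$n_subjects; me <- report$me; sd <- report$sd
  } else n <- report
  n > 85 && abs(me) < 5 && sd < 8
}

#' BHS cumulative-error grading
#'
#' Computes the percentage of absolute errors within 5, 10 and 15 mmHg and
#' grades them: A requires at least (60, 85, 95), B (50, 75, 90),
#' C (40, 65, 85); anything less fails. Threshold comparisons on the error
#' magnitudes use `<=` by default (the standard's tabulated form); set
#' `strict = TRUE` for strict `<`.
#'
#' @param abs_errors Nonempty vector of absolute errors in mmHg (signed
#'   errors are accepted and folded).
#' @param strict Use strict `<` against the mmHg thresholds.
#' @return List with `cum5`, `cum10`, `cum15` (percentages) and `grade`
#'   (`"A"`, `"B"`, `"C"` or `"fail"`).
#' @export
bhs_grade <- function(abs_errors, strict = FALSE) {
  stopifnot(length(abs_errors) >= 1)
  e <- abs(abs_errors)
  cum <- if (strict) {
    100 * c(mean(e < 5), mean(e < 10), mean(e < 15))
  } else {
    100 * c(mean(e <= 5), mean(e <= 10), mean(e <= 15))
  }
  grade_of <- function(cum) {
    if (all(cum >= c(60, 85, 95))) "A"
    else if (all(cum >= c(50, 75, 90))) "B"
    else if (all(cum >= c(40, 65, 85))) "C"
    else "fail"
  }
  list(cum5 = cum[1], cum10 = cum[2], cum15 = cum[3], grade = grade_of(cum))
}

# Grade from already-computed cumulative percentages (used when reproducing
# published tables).
#' Grade precomputed BHS cumulative percentages
#'
#' @param cum5,cum10,cum15 Cumulative percentages of absolute errors within
#'   5, 10, 15 mmHg.
#' @return `"A"`, `"B"`, `"C"` or `"fail"` (inclusive thresholds).
#' @export
bhs_grade_from_cum <- function(cum5, cum10, cum15) {
  cum <- c(cum5, cum10, cum15)
  if (all(cum >= c(60, 85, 95))) "A"
  else if (all(cum >= c(50, 75, 90))) "B"
  else if (all(cum >= c(40, 65, 85))) "C"
  else "fail"
}

#' Full compliance report for one target
#'
#' Aggregates MAE, RMSE, signed mean error, error SD, squared Pearson
#' correlation, BHS cumulative percentages and grade, and the AAMI verdict
#' over the pooled per-slice error distribution.
#'
#' @param p A [paired_predictions()] object.
#' @return An object of class `compliance_report`.
#' @export
compliance_report <- function(p) {
  ms <- me_sd(p)
  bhs <- bhs_grade(p$yhat - p$y)
  r2v <- tryCatch(r2(p), error = function(e) NA_real_)
  structure(list(target = p$target[1],
                 n_subjects = length(unique(p$subject_id)),
                 n_pairs = nrow(p),
                 mae = mae(p), rmse = rmse(p), me = ms$me, sd = ms$sd,
                 r2 = r2v,
                 bhs_cum = c(cum5 = bhs$cum5, cum10 = bhs$cum10,
                             cum15 = bhs$cum15),
                 bhs_grade = bhs$grade,
                 aami_pass = length(unique(p$subject_id)) > 85 &&
                   abs(ms$me) < 5 && ms$sd < 8),
            class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report> %s: %d subjects, %d pairs\n",
              x$target, x$n_subjects, x$n_pairs))
  cat(sprintf("  MAE %.3f  RMSE %.3f  ME %+.3f  SD %.3f  r2 %s\n",
              x$mae, x$rmse, x$me, x$sd,
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2))))
  cat(sprintf("  BHS: %.2f%% / %.2f%% / %.2f%% within 5/10/15 mmHg -> grade %s\n",
              x$bhs_cum[1], x$bhs_cum[2], x$bhs_cum[3], x$bhs_grade))
  cat(sprintf("  AAMI (>85 subjects, |ME|<5, SD<8): %s\n",
              ifelse(x$aami_pass, "pass", "fail")))
  invisible(x)
}

#' Per-subgroup compliance reports
#'
#' Computes a [compliance_report()] per group of subjects (e.g. gender, age
#' bin). Groups smaller than `min_n` pairs are flagged, never silently
#' dropped.
#'
#' @param p A [paired_predictions()] object.
#' @param attributes Named character vector (or single-column mapping)
#'   subject_id -> group label; every subject in `p` must be present.
#' @param min_n Minimum pair count below which a group is flagged.
#' @return Named list of `compliance_report`s; each carries attribute
#'   `"flagged_small"`.
#' @export
subgroup_report <- function(p, attributes, min_n = 10) {
  missing_subj <- setdiff(unique(p$subject_id), names(attributes))
  if (length(missing_subj) > 0) {
    stop("missing attribute for subject(s): ",
         paste(missing_subj, collapse = ", "), call. = FALSE)
  }
  groups <- split(seq_len(nrow(p)), attributes[p$subject_id])
  lapply(groups, function(idx) {
    rep <- compliance_report(structure(p[idx, , drop = FALSE],
                                       class = c("paired_predictions",
                                                 "data.frame")))
    attr(rep, "flagged_small") <- length(idx) < min_n
    rep
  })
}
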
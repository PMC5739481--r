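#' Confusion counts at a score threshold
#'
#' A lesion is called malignant iff its score is greater than or equal to the
#' threshold, so that the threshold equal to the lowest malignant score
#' deterministically achieves sensitivity 1. `malignant` is the positive
#' class: TP and FN partition the melanomas, TN and FP the benign lesions.
#'
#' @param cohort A [scored_cohort()].
#' @param t Threshold on the malignancy score.
#' @return Object of class `"confusion_counts"`: list with integer `TP`, `FP`,
#'   `TN`, `FN` and derived `sensitivity` (= recall = TP/(TP+FN)),
#'   `specificity` (= TN/(TN+FP)) and `precision` (= TP/(TP+FP), `NaN` when
#'   nothing is called malignant).
#' @export
confusion_at_threshold <- function(cohort, t) {
  stopifnot(inherits(cohort, "scored_cohort"), is.numeric(t), length(t) == 1L)
  y <- label01(cohort)
  pred <- cohort$score >= t
  TP <- sum(pred & y == 1L)
  FP <- sum(pred & y == 0L)
  FN <- sum(!pred & y == 1L)
  TN <- sum(!pred & y == 0L)
  structure(list(
    TP = TP, FP = FP, TN = TN, FN = FN, threshold = t,
    sensitivity = if (TP + FN > 0L) TP / (TP + FN) else NaN,
    specificity = if (TN + FP > 0L) TN / (TN + FP) else NaN,
    precision = if (TP + FP > 0L) TP / (TP + FP) else NaN),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion at threshold %.4g: TP=%d FP=%d TN=%d FN=%d\n",
              x$threshold, x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  SE=%.4f SP=%.4f precision=%.4f\n",
              x$sensitivity, x$specificity, x$precision))
  invisible(x)
}

#' Empirical ROC curve
#'
#' Sweeps the threshold over the distinct score values in descending order.
#' Records sharing a score move between confusion cells together (one step per
#' distinct value), which is the only coherent convention under the
#' score-greater-or-equal decision rule. The point \eqn{(0,0)} (threshold
#' \eqn{+\infty}) is attached; \eqn{(1,1)} arises at the minimum score.
#'
#' @param cohort A [scored_cohort()] with both classes present.
#' @return Object of class `"operating_curve"`: data frame with columns
#'   `threshold`, `fpr` (1 - specificity) and `tpr` (sensitivity), both
#'   non-decreasing down the rows.
#' @export
roc_curve <- function(cohort) {
  assert_two_class(cohort)
  ord <- order(cohort$score, decreasing = TRUE)
  s <- cohort$score[ord]
  y <- label01(cohort)[ord]
  n <- length(s)
  # index of the last record in each tie group
  last <- which(c(s[-1L] != s[-n], TRUE))
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  structure(
    data.frame(threshold = c(Inf, s[last]),
               fpr = c(0, fp / n_neg(cohort)),
               tpr = c(0, tp / n_pos(cohort))),
    n_pos = n_pos(cohort), n_neg = n_neg(cohort),
    class = c("operating_curve", "data.frame"))
}

#' Precision-recall curve
#'
#' Same threshold sweep and tie convention as [roc_curve()]; each tie group
#' contributes one point carrying the block-end precision.
#'
#' @inheritParams roc_curve
#' @return Data frame with columns `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(cohort) {
  assert_two_class(cohort)
  ord <- order(cohort$score, decreasing = TRUE)
  s <- cohort$score[ord]
  y <- label01(cohort)[ord]
  n <- length(s)
  last <- which(c(s[-1L] != s[-n], TRUE))
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  data.frame(threshold = s[last],
             recall = tp / n_pos(cohort),
             precision = tp / (tp + fp))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the empirical ROC. With the grouped-tie convention
#' this equals the Mann-Whitney statistic: the probability that a random
#' melanoma outscores a random benign lesion, ties counting one half.
#'
#' @param x A [scored_cohort()] or an `"operating_curve"`.
#' @return AUC in \eqn{[0,1]}.
#' @export
auc_roc <- function(x) {
  curve <- as_operating_curve(x)
  f <- curve$fpr
  t <- curve$tpr
  sum(diff(f) * (t[-length(t)] + t[-1L]) / 2)
}

#' Average precision (area under the precision-recall curve)
#'
#' The uninterpolated step-sum \eqn{AP = \sum_k (R_k - R_{k-1}) P_k} over the
#' descending-score rank positions, with tie groups processed as blocks using
#' the block-end precision. No 11-point or max-interpolated variants.
#'
#' @param cohort A [scored_cohort()] with at least one melanoma.
#' @return AP in \eqn{[0,1]}.
#' @export
average_precision <- function(cohort) {
  stopifnot(inherits(cohort, "scored_cohort"))
  if (n_pos(cohort) < 1L) stop("no malignant records", call. = FALSE)
  pr <- if (n_neg(cohort) >= 1L) pr_curve(cohort) else {
    data.frame(recall = 1, precision = 1)
  }
  sum(diff(c(0, pr$recall)) * pr$precision)
}

#' Specificity at a fixed high sensitivity
#'
#' The operating points of the empirical ROC are scanned and the maximum
#' specificity among points whose sensitivity meets the target is returned
#' ("best specificity subject to SE >= target"). An answer always exists:
#' the all-malignant threshold gives sensitivity 1. The achieved sensitivity
#' and the realising threshold are reported alongside.
#'
#' With `interpolate = "linear"` the specificity is instead read off the
#' piecewise-linear interpolation of the ROC at exactly the target
#' sensitivity; this variant is optimistic between attainable points and is
#' provided for comparison only.
#'
#' @param cohort A [scored_cohort()].
#' @param target_se Target sensitivity in \eqn{(0, 1]}; the challenge used
#'   0.95, 0.98 and 0.99.
#' @param interpolate `"none"` (default, empirical rule) or `"linear"`.
#' @return List with `specificity`, `sensitivity` (achieved), `threshold`.
#' @export
specificity_at_sensitivity <- function(cohort, target_se,
                                       interpolate = c("none", "linear")) {
  interpolate <- match.arg(interpolate)
  stopifnot(is.numeric(target_se), length(target_se) == 1L,
            target_se > 0, target_se <= 1)
  curve <- roc_curve(cohort)
  if (interpolate == "linear") {
    fpr_at <- stats::approx(curve$tpr, curve$fpr, xout = target_se,
                            ties = min, rule = 2)$y
    return(list(specificity = 1 - fpr_at, sensitivity = target_se,
                threshold = NA_real_))
  }
  ok <- which(curve$tpr >= target_se)
  # fpr is non-decreasing down the curve, so the first qualifying point has
  # the best specificity
  i <- ok[1L]
  list(specificity = 1 - curve$fpr[i],
       sensitivity = curve$tpr[i],
       threshold = curve$threshold[i])
}

#' Partial AUC over the high-sensitivity band
#'
#' Area between the ROC curve and the sensitivity axis restricted to
#' sensitivity in \eqn{[se_{lo}, 1]}: the integrand is the specificity
#' \eqn{1 - fpr} as a function of sensitivity, so a perfect classifier attains
#' the maximum \eqn{1 - se_{lo}}. The empirical curve is treated as piecewise
#' linear in sensitivity (vertical ROC segments contribute full-width
#' specificity, horizontal segments contribute nothing, tie segments are
#' linear), with linear interpolation at the cut \eqn{se_{lo}}.
#'
#' @param x A [scored_cohort()] or `"operating_curve"`.
#' @param se_lo Lower sensitivity bound in \eqn{(0,1)}; default 0.95.
#' @return List with `raw` (in \eqn{[0, 1-se_{lo}]}) and `normalized`
#'   (`raw / (1 - se_lo)`, in \eqn{[0,1]}).
#' @export
partial_auc_roc <- function(x, se_lo = 0.95) {
  stopifnot(is.numeric(se_lo), length(se_lo) == 1L, se_lo > 0, se_lo < 1)
  curve <- as_operating_curve(x)
  f <- curve$fpr
  t <- curve$tpr
  raw <- 0
  for (i in seq_len(nrow(curve) - 1L)) {
    t1 <- t[i]; t2 <- t[i + 1L]
    if (t2 <= se_lo || t2 == t1) next
    f1 <- f[i]; f2 <- f[i + 1L]
    lo <- max(t1, se_lo)
    # interpolate fpr at the clipped lower end
    f_lo <- if (t2 > t1) f1 + (f2 - f1) * (lo - t1) / (t2 - t1) else f1
    raw <- raw + (t2 - lo) * (1 - (f_lo + f2) / 2)
  }
  list(raw = raw, normalized = raw / (1 - se_lo))
}

#' The full challenge measure panel
#'
#' Computes the five challenge measures — average precision, AUC of the ROC,
#' and specificity at 95/98/99 percent sensitivity — plus the partial AUC over
#' the \eqn{[0.95, 1]} sensitivity band (raw and normalised by the band
#' width), all under one consistent tie convention.
#'
#' @param cohort A [scored_cohort()].
#' @param se_targets Sensitivity targets for the high-sensitivity measures.
#' @param pauc_lo Lower sensitivity bound of the partial AUC band.
#' @param interpolate Operating-point convention passed to
#'   [specificity_at_sensitivity()].
#' @return Object of class `"measure_panel"`: named list with elements
#'   `average_precision`, `auc_roc`, `spec_at_se95`, `spec_at_se98`,
#'   `spec_at_se99` (names follow `se_targets`), `pauc_se95_100_raw`,
#'   `pauc_se95_100_norm`.
#' @examples
#' co <- scored_cohort(paste0("L", 1:4), c(0.9, 0.7, 0.6, 0.3),
#'                     c("malignant", "benign", "malignant", "benign"))
#' unlist(measure_panel(co))
#' @export
measure_panel <- function(cohort, se_targets = c(0.95, 0.98, 0.99),
                          pauc_lo = 0.95,
                          interpolate = c("none", "linear")) {
  interpolate <- match.arg(interpolate)
  assert_two_class(cohort)
  curve <- roc_curve(cohort)
  spec <- vapply(se_targets, function(se) {
    specificity_at_sensitivity(cohort, se, interpolate = interpolate)$specificity
  }, numeric(1L))
  names(spec) <- paste0("spec_at_se", round(100 * se_targets))
  pa <- partial_auc_roc(curve, se_lo = pauc_lo)
  out <- c(list(average_precision = average_precision(cohort),
                auc_roc = auc_roc(curve)),
           as.list(spec),
           list(pauc_se95_100_raw = pa$raw,
                pauc_se95_100_norm = pa$normalized))
  structure(out, se_targets = se_targets, pauc_lo = pauc_lo,
            class = "measure_panel")
}

#' @export
print.measure_panel <- function(x, digits = 4, ...) {
  cat("Measure panel:\n")
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("  %-20s %.*f\n", nm, digits, v[nm]))
  invisible(x)
}

#' Names of the measures in a panel
#' @param panel A `"measure_panel"`.
#' @return Character vector of measure names.
#' @export
panel_measures <- function(panel) names(unlist(panel))

as_operating_curve <- function(x) {
  if (inherits(x, "operating_curve")) return(x)
  if (inherits(x, "scored_cohort")) return(roc_curve(x))
  stop("expected a scored_cohort or an operating_curve", call. = FALSE)
}
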
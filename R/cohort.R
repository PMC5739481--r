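#' Construct a scored cohort
#'
#' A scored cohort is the universal input of the accuracy measures: one record
#' per lesion with a malignancy score in \eqn{[0,1]} and the true class label.
#' `malignant` is the positive class throughout.
#'
#' @param lesion_id Character identifiers, unique and non-empty.
#' @param score Numeric scores in \eqn{[0,1]}.
#' @param label Class labels (`benign`/`malignant` or 0/1).
#' @return An object of class `"scored_cohort"`: a data frame with columns
#'   `lesion_id`, `score`, `label` and attributes `n_pos` (malignant count)
#'   and `n_neg` (benign count).
#' @examples
#' co <- scored_cohort(c("a", "b", "c", "d"),
#'                     c(0.9, 0.7, 0.6, 0.3),
#'                     c(1, 0, 1, 0))
#' auc_roc(co)
#' @export
scored_cohort <- function(lesion_id, score, label) {
  lesion_id <- as.character(lesion_id)
  check_ids(lesion_id, "scored_cohort")
  score <- as.numeric(score)
  if (anyNA(score) || any(score < 0 | score > 1)) {
    stop("scores must be numeric in [0, 1]", call. = FALSE)
  }
  label <- canonical_label(label)
  if (anyNA(label)) stop("unrecognised class label", call. = FALSE)
  n_pos <- sum(label == "malignant")
  n_neg <- sum(label == "benign")
  structure(
    data.frame(lesion_id = lesion_id, score = score, label = label,
               stringsAsFactors = FALSE),
    n_pos = n_pos, n_neg = n_neg,
    class = c("scored_cohort", "data.frame"))
}

#' Join a submission with its ground truth
#'
#' Inner-joins the two tables on `lesion_id` and requires a perfect 1:1 match:
#' every truth id must appear in the submission and vice versa (a challenge
#' submission covering only part of the test set is not scoreable). The result
#' is independent of the input row order; records are returned in truth order.
#'
#' @param submission Data frame with `lesion_id`, `score`
#'   (see [read_submission()]).
#' @param truth Data frame with `lesion_id`, `label` (see [read_truth()]).
#' @return A [scored_cohort()].
#' @export
join_cohort <- function(submission, truth) {
  if (is.null(submission) || nrow(submission) == 0L) {
    stop("submission is empty", call. = FALSE)
  }
  if (is.null(truth) || nrow(truth) == 0L) {
    stop("ground truth is empty", call. = FALSE)
  }
  missing_sub <- setdiff(truth$lesion_id, submission$lesion_id)
  missing_tru <- setdiff(submission$lesion_id, truth$lesion_id)
  if (length(missing_sub) || length(missing_tru)) {
    msg <- c(
      if (length(missing_sub))
        sprintf("truth ids missing from submission: %s",
                paste(missing_sub, collapse = ", ")),
      if (length(missing_tru))
        sprintf("submission ids missing from truth: %s",
                paste(missing_tru, collapse = ", ")))
    stop(paste(msg, collapse = "; "), call. = FALSE)
  }
  idx <- match(truth$lesion_id, submission$lesion_id)
  scored_cohort(truth$lesion_id, submission$score[idx], truth$label)
}

#' @export
print.scored_cohort <- function(x, ...) {
  cat(sprintf("Scored cohort: %d lesions (%d malignant, %d benign)\n",
              nrow(x), attr(x, "n_pos"), attr(x, "n_neg")))
  cat(sprintf("  score range [%.4g, %.4g]\n", min(x$score), max(x$score)))
  invisible(x)
}

# 0/1 view of the labels (1 = malignant)
label01 <- function(cohort) as.integer(cohort$label == "malignant")

n_pos <- function(cohort) attr(cohort, "n_pos")
n_neg <- function(cohort) attr(cohort, "n_neg")

assert_two_class <- function(cohort) {
  if (n_pos(cohort) < 1L || n_neg(cohort) < 1L) {
    stop("cohort must contain at least one malignant and one benign record",
         call. = FALSE)
  }
  invisible(cohort)
}
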
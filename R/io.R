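#' Read a challenge submission file
#'
#' A submission is a two-column delimited text file with one record per lesion
#' image: a lesion identifier and a posterior probability of malignancy in
#' \eqn{[0, 1]}. A header row is auto-detected (the second field of the first
#' line is non-numeric). Files are comma-separated, decimal point, UTF-8.
#'
#' Scores of exactly 0 or 1 are legal but reported via [message()] as
#' "saturated": a posterior pinned at the boundary carries no ordering
#' information among the records sharing it, which matters for the
#' high-sensitivity measures (see [prior_sweep()] for the remedy).
#'
#' @param path Path to the submission CSV.
#' @return A data frame with columns `lesion_id` (character) and `score`
#'   (numeric in \eqn{[0,1]}), in file order.
#' @seealso [read_truth()], [join_cohort()]
#' @export
read_submission <- function(path) {
  rows <- read_delim_rows(path, n_fields = 2L, what = "submission")
  ids <- rows$fields[[1L]]
  score_raw <- rows$fields[[2L]]
  score <- suppressWarnings(as.numeric(score_raw))
  bad <- which(is.na(score))
  if (length(bad)) {
    stop(sprintf("submission '%s': non-numeric score on line %d ('%s')",
                 path, rows$line[bad[1L]], score_raw[bad[1L]]), call. = FALSE)
  }
  out_of_range <- which(score < 0 | score > 1)
  if (length(out_of_range)) {
    stop(sprintf(
      "submission '%s': score %s on line %d outside [0, 1]",
      path, format(score[out_of_range[1L]]), rows$line[out_of_range[1L]]),
      call. = FALSE)
  }
  check_ids(ids, path)
  n_sat <- sum(score == 0 | score == 1)
  if (n_sat > 0L) {
    message(sprintf("read_submission: %d saturated score(s) (exactly 0 or 1) in '%s'",
                    n_sat, path))
  }
  data.frame(lesion_id = ids, score = score, stringsAsFactors = FALSE)
}

#' Read a ground-truth label file
#'
#' Two columns: lesion identifier and class label. Labels are accepted as
#' `benign`/`malignant` (case-insensitive) or `0`/`1` and stored canonically
#' as `"benign"`/`"malignant"`.
#'
#' @param path Path to the ground-truth CSV (header auto-detected).
#' @return A data frame with columns `lesion_id` and `label`
#'   (`"benign"`/`"malignant"`).
#' @export
read_truth <- function(path) {
  rows <- read_delim_rows(path, n_fields = 2L, what = "ground truth")
  ids <- rows$fields[[1L]]
  label <- canonical_label(rows$fields[[2L]])
  bad <- which(is.na(label))
  if (length(bad)) {
    stop(sprintf("ground truth '%s': unrecognised label '%s' on line %d",
                 path, rows$fields[[2L]][bad[1L]], rows$line[bad[1L]]),
         call. = FALSE)
  }
  check_ids(ids, path)
  data.frame(lesion_id = ids, label = label, stringsAsFactors = FALSE)
}

#' Write submission / ground-truth files
#'
#' Plain CSV writers matching [read_submission()] and [read_truth()]; scores
#' are written with 10 decimal digits so that identical seeds give
#' byte-identical files across platforms.
#'
#' @param x Data frame as returned by the corresponding reader.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_submission <- function(x, path) {
  stopifnot(all(c("lesion_id", "score") %in% names(x)))
  lines <- c("lesion_id,score",
             paste(x$lesion_id, format_score(x$score), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_submission
#' @export
write_truth <- function(x, path) {
  stopifnot(all(c("lesion_id", "label") %in% names(x)))
  lines <- c("lesion_id,label", paste(x$lesion_id, x$label, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Feature tables for the classifier experiments
#'
#' A feature table holds `n` lesions by `d` numeric features plus a binary
#' class label; it is the training/test substrate for [fit_gda()]. Both
#' classes must be present and no value may be missing.
#'
#' @param x Numeric matrix or data frame of features (`n x d`).
#' @param label Class labels (`benign`/`malignant`, or 0/1).
#' @param lesion_id Optional identifiers; defaults to `"X1"..."Xn"`.
#' @return A data frame of class `"feature_table"` with the feature columns,
#'   a `lesion_id` column and a canonical `label` column.
#' @export
feature_table <- function(x, label, lesion_id = NULL) {
  x <- as.data.frame(x)
  if (ncol(x) < 1L) stop("feature table needs at least one feature", call. = FALSE)
  if (!all(vapply(x, is.numeric, logical(1L)))) {
    stop("all feature columns must be numeric", call. = FALSE)
  }
  if (anyNA(x)) stop("feature table contains missing values", call. = FALSE)
  label <- canonical_label(label)
  if (anyNA(label)) stop("unrecognised class label", call. = FALSE)
  if (length(label) != nrow(x)) stop("label length does not match rows", call. = FALSE)
  if (length(unique(label)) < 2L) {
    stop("feature table must contain both classes", call. = FALSE)
  }
  if (is.null(lesion_id)) lesion_id <- paste0("X", seq_len(nrow(x)))
  out <- cbind(data.frame(lesion_id = as.character(lesion_id),
                          stringsAsFactors = FALSE),
               x,
               data.frame(label = label, stringsAsFactors = FALSE))
  structure(out, feature_names = names(x),
            class = c("feature_table", "data.frame"))
}

#' @rdname feature_table
#' @param path Path to a feature CSV (`lesion_id, f1..fd, label`; header
#'   required since it carries the feature names).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3L || names(df)[1L] != "lesion_id" ||
      names(df)[ncol(df)] != "label") {
    stop(sprintf("feature table '%s': expected columns lesion_id, f1..fd, label",
                 path), call. = FALSE)
  }
  feats <- df[, -c(1L, ncol(df)), drop = FALSE]
  feature_table(feats, df$label, lesion_id = df$lesion_id)
}

#' @rdname feature_table
#' @param ft A `feature_table`.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- as.data.frame(ft)
  feats <- attr(ft, "feature_names")
  for (f in feats) df[[f]] <- format_score(df[[f]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the feature matrix / labels from a feature table
#' @param ft A `feature_table`.
#' @return `feature_matrix()`: numeric matrix; `feature_labels()`: canonical
#'   label vector.
#' @keywords internal
feature_matrix <- function(ft) {
  as.matrix(as.data.frame(ft)[, attr(ft, "feature_names"), drop = FALSE])
}

#' @rdname feature_matrix
#' @keywords internal
feature_labels <- function(ft) as.data.frame(ft)$label

## --- internal parsing helpers -------------------------------------------

# Reads a delimited file into fields with line-number tracking, so that
# validation errors can name the offending line. Header detection: the second
# field of the first line is non-numeric and not a recognisable label.
read_delim_rows <- function(path, n_fields, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file '%s' does not exist", what, path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("%s file '%s' is empty", what, path), call. = FALSE)
  parts <- strsplit(lines, ",", fixed = TRUE)
  lens <- lengths(parts)
  bad <- which(lens != n_fields)
  if (length(bad)) {
    stop(sprintf("%s file '%s': malformed row on line %d (expected %d fields, got %d)",
                 what, path, bad[1L], n_fields, lens[bad[1L]]), call. = FALSE)
  }
  mat <- vapply(parts, function(p) trimws(p), character(n_fields))
  mat <- matrix(mat, nrow = n_fields)
  line_no <- seq_along(lines)
  second <- mat[2L, 1L]
  # a lone line is always data: a header-only file has nothing to offer and
  # misparsing it as one would swallow the validation error the caller wants
  is_header <- ncol(mat) > 1L &&
    is.na(suppressWarnings(as.numeric(second))) &&
    is.na(canonical_label(second))
  if (is_header) {
    mat <- mat[, -1L, drop = FALSE]
    line_no <- line_no[-1L]
    if (!ncol(mat)) stop(sprintf("%s file '%s' has a header but no data", what, path),
                         call. = FALSE)
  }
  list(fields = lapply(seq_len(n_fields), function(i) mat[i, ]),
       line = line_no)
}

check_ids <- function(ids, path) {
  if (any(!nzchar(ids))) {
    stop(sprintf("'%s': empty lesion_id", path), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("'%s': duplicated lesion_id(s): %s",
                 path, paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Canonical label coding: "benign"/"malignant"; accepts 0/1 and case variants.
canonical_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("benign", "0")] <- "benign"
  out[x %in% c("malignant", "melanoma", "1")] <- "malignant"
  out
}

format_score <- function(x) {
  # fixed 10-decimal rendering; keeps seeded output byte-identical
  formatC(round(x, 10), format = "f", digits = 10)
}
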